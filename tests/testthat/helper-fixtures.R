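# Shared fixtures: hand-built toy bundles with fully controlled parameters,
# random mini-worlds for oracle checks, and an exhaustive path-enumeration
# shortest-path oracle independent of the package's Dijkstra.

small_world <- function(seed = 1, n_countries = 5) {
  generate_world(world_config(n_countries = n_countries,
                              regions_per_country = c(2, 4),
                              seed = seed))
}

# Uniform transport parameter table.
flat_params <- function(countries,
                        dc = 0.05, hc = 0, w = 0, vfft = 0, b = 0) {
  tidyr::expand_grid(country = countries,
                     mode = c("road", "rail", "maritime_drybulk",
                              "maritime_container", "maritime_generalcargo")) |>
    dplyr::mutate(dc_usd_t_km = dc, hc_usd_t = hc, wait_h = w,
                  vfft_usd_t_h = vfft, border_usd_t = b)
}

# A three-country line world A -> B -> C with optional maritime shortcut:
#  regions A_R1 (node NA1), B_R1 (NB1), C_R1 (NC1); ports PA (A), PC (C).
toy_bundle <- function(params = NULL, maritime = TRUE) {
  regions <- tibble::tibble(
    region_id = c("A_R1", "B_R1", "C_R1"),
    country = c("A", "B", "C"),
    population = c(1e5, 2e5, 3e5),
    node = c("NA1", "NB1", "NC1")
  )
  nodes <- tibble::tibble(
    node_id = c("NA1", "NB1", "NC1", "PA", "PC"),
    country = c("A", "B", "C", "A", "C"),
    x = c(0, 100, 200, 0, 200), y = c(0, 0, 0, 50, 50),
    is_port = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    has_rail = FALSE
  )
  edges <- tibble::tibble(
    node_a = c("NA1", "NB1", "NA1", "NC1"),
    node_b = c("NB1", "NC1", "PA", "PC"),
    mode = "road",
    distance_km = c(100, 100, 50, 50),
    time_h = distance_km / 50
  )
  if (maritime) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      node_a = "PA", node_b = "PC", mode = "maritime_drybulk",
      distance_km = 1000, time_h = 1000 / 25))
  }
  production <- tibble::tibble(
    region_id = c("A_R1", "B_R1", "C_R1"),
    commodity = "wheat",
    production_t = c(1000, 500, 100),
    yield_t_ha = c(2, 2, 2)
  )
  input_costs <- tibble::tibble(
    country = c("A", "B", "C"), commodity = "wheat",
    fertilizer = 100, pesticides = 40, labour = 60,
    machinery = 80, diesel = 20
  )
  trade <- tibble::tibble(exporter = "A", importer = "C",
                          commodity = "wheat", tonnes = 100)
  tariffs <- tibble::tibble(exporter = "A", importer = "C",
                            commodity = "wheat", ad_valorem_rate = 0.1)
  structure(
    list(regions = regions, nodes = nodes, edges = edges,
         production = production, input_costs = input_costs,
         transport_params = params %||% flat_params(c("A", "B", "C")),
         trade = trade, tariffs = tariffs,
         config = world_config(n_countries = 3, seed = 1)),
    class = "glcm_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive shortest-path oracle: depth-first enumeration of all simple
# paths over one mode's directed edge table, pruned by the best cost found.
enumerate_min_gc <- function(graph, mode, origin, destination) {
  e <- graph$adj[[mode]]$edges
  vids <- graph$vertices$vid
  s <- match(paste0("r|", origin), vids)
  t <- match(paste0("r|", destination), vids)
  best <- Inf
  nv <- length(vids)
  visited <- logical(nv)
  dfs <- function(u, cost) {
    if (cost >= best) return()
    if (u == t) { best <<- min(best, cost); return() }
    visited[u] <<- TRUE
    out <- which(e$fi == u)
    for (i in out) {
      v <- e$ti[i]
      if (!visited[v]) dfs(v, cost + e$weight[i])
    }
    visited[u] <<- FALSE
  }
  dfs(s, 0)
  best
}

# Random mini-world: every node is its own country with one region, so all
# travel edges are border crossings; sparse connected road layer, optional
# rail layer, random parameters. <= max_nodes nodes.
random_mini_bundle <- function(seed, max_nodes = 10, rail = TRUE,
                               maritime = FALSE) {
  withr::with_seed(seed, {
    n <- sample(4:max_nodes, 1)
    countries <- sprintf("K%02d", seq_len(n))
    nodes <- tibble::tibble(
      node_id = sprintf("M%02d", seq_len(n)), country = countries,
      x = runif(n, 0, 1000), y = runif(n, 0, 1000),
      is_port = FALSE, has_rail = rail
    )
    regions <- tibble::tibble(
      region_id = sprintf("%s_R1", countries), country = countries,
      population = runif(n, 1e4, 1e6), node = nodes$node_id
    )
    # random spanning tree plus a few extra edges
    ord <- sample(n)
    tree <- tibble::tibble(
      node_a = nodes$node_id[ord[-1]],
      node_b = nodes$node_id[vapply(2:n, function(i)
        ord[sample(i - 1, 1)], integer(1))]
    )
    extra_n <- sample(0:3, 1)
    extra <- if (extra_n > 0) {
      tibble::tibble(node_a = sample(nodes$node_id, extra_n, replace = TRUE),
                     node_b = sample(nodes$node_id, extra_n, replace = TRUE))
    } else NULL
    ed <- dplyr::bind_rows(tree, extra) |>
      dplyr::filter(node_a != node_b) |>
      dplyr::mutate(a = pmin(node_a, node_b), b = pmax(node_a, node_b)) |>
      dplyr::distinct(a, b) |>
      dplyr::rename(node_a = a, node_b = b)
    road <- ed |>
      dplyr::mutate(mode = "road", distance_km = runif(dplyr::n(), 10, 500),
                    time_h = distance_km / runif(dplyr::n(), 30, 80))
    edges <- road
    if (rail && nrow(ed) >= 2) {
      sub <- ed[sample(nrow(ed), max(1, nrow(ed) %/% 2)), ]
      edges <- dplyr::bind_rows(edges, sub |>
        dplyr::mutate(mode = "rail", distance_km = runif(dplyr::n(), 10, 500),
                      time_h = distance_km / runif(dplyr::n(), 20, 60)))
    }
    if (maritime && n >= 4) {
      ports <- sample(nodes$node_id, 2)
      nodes$is_port[nodes$node_id %in% ports] <- TRUE
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        node_a = min(ports), node_b = max(ports), mode = "maritime_drybulk",
        distance_km = runif(1, 500, 3000),
        time_h = distance_km / 25))
    }
    params <- flat_params(countries) |>
      dplyr::mutate(dc_usd_t_km = runif(dplyr::n(), 0.01, 0.1),
                    hc_usd_t = runif(dplyr::n(), 0, 5),
                    wait_h = runif(dplyr::n(), 0, 24),
                    vfft_usd_t_h = runif(dplyr::n(), 0, 0.1),
                    border_usd_t = runif(dplyr::n(), 0, 15))
    production <- tibble::tibble(region_id = regions$region_id,
                                 commodity = "wheat",
                                 production_t = runif(n, 100, 1000),
                                 yield_t_ha = runif(n, 1, 5))
    structure(
      list(regions = regions, nodes = nodes, edges = edges,
           production = production,
           input_costs = tibble::tibble(country = countries,
                                        commodity = "wheat", fertilizer = 100,
                                        pesticides = 10, labour = 10,
                                        machinery = 10, diesel = 10),
           transport_params = params,
           trade = tibble::tibble(exporter = countries[1],
                                  importer = countries[n],
                                  commodity = "wheat", tonnes = 10),
           tariffs = tibble::tibble(exporter = countries[1],
                                    importer = countries[n],
                                    commodity = "wheat",
                                    ad_valorem_rate = 0),
           config = world_config(n_countries = n, seed = seed)),
      class = "glcm_bundle")
  })
}

# Full pipeline on a toy-size world, cached per test file run.
tiny_flows <- function(seed = 11, n_countries = 5) {
  b <- small_world(seed = seed, n_countries = n_countries)
  g <- build_transport_graph(b)
  pc <- production_costs(b)
  rt <- suppressWarnings(compute_routes(g, b))
  lc <- landed_costs(pc, rt, b$tariffs, b$regions, b$trade)
  fl <- suppressWarnings(allocate_flows(b, lc))
  list(bundle = b, graph = g, pc = pc, routes = rt, lc = lc, flows = fl)
}
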