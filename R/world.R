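#' Configure a synthetic trading world
#'
#' The synthetic world emulates the input schemas of the landed-cost model:
#' subnational regions with populations and network attachments, regional
#' commodity production and yields, country-level per-hectare input costs,
#' bilateral trade, ad valorem tariffs, country-by-mode transport parameters
#' and a five-layer multimodal edge list. Everything downstream of
#' [generate_world()] is testable without any external data.
#'
#' @param n_countries Number of countries (>= 2).
#' @param regions_per_country Integer range (length 2) of regions per country.
#' @param commodities Character vector of commodity codes.
#' @param network_density Probability of optional extra edges beyond the
#'   connectivity backbone, in (0, 1].
#' @param maritime_fraction Fraction of countries given a sea port; the rest
#'   are landlocked and reach maritime layers through a neighbouring
#'   country's port.
#' @param seed Integer seed; fully determines the generated bundle.
#' @param cost_dispersion Log-scale dispersion applied to generated cost,
#'   yield and population draws.
#' @return A list with class `glcm_world_config`.
#' @export
#' @examples
#' cfg <- world_config(n_countries = 4, seed = 1)
#' cfg$commodities
world_config <- function(n_countries = 20,
                         regions_per_country = c(3, 8),
                         commodities = c("maize", "wheat", "sorghum",
                                         "barley", "soybean", "rice"),
                         network_density = 0.25,
                         maritime_fraction = 0.7,
                         seed = 1L,
                         cost_dispersion = 0.35) {
  if (!is.numeric(n_countries) || n_countries < 2) {
    stop_glcm("`n_countries` must be at least 2.", "glcm_config_error")
  }
  if (length(regions_per_country) != 2L || any(regions_per_country < 1) ||
      regions_per_country[1] > regions_per_country[2]) {
    stop_glcm("`regions_per_country` must be an increasing range of counts >= 1.",
              "glcm_config_error")
  }
  if (!is.character(commodities) || length(commodities) == 0L) {
    stop_glcm("`commodities` must be a non-empty character vector.",
              "glcm_config_error")
  }
  if (!is.numeric(network_density) || network_density <= 0 || network_density > 1) {
    stop_glcm("`network_density` must lie in (0, 1].", "glcm_config_error")
  }
  if (!is.numeric(maritime_fraction) || maritime_fraction <= 0 || maritime_fraction > 1) {
    stop_glcm("`maritime_fraction` must lie in (0, 1].", "glcm_config_error")
  }
  check_positive_number(cost_dispersion, "cost_dispersion")
  structure(
    list(
      n_countries = as.integer(n_countries),
      regions_per_country = as.integer(regions_per_country),
      commodities = commodities,
      network_density = network_density,
      maritime_fraction = maritime_fraction,
      seed = as.integer(seed),
      cost_dispersion = cost_dispersion
    ),
    class = "glcm_world_config"
  )
}

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Mode-specific detour factors applied to straight-line distances, and
# nominal line-haul speeds (km/h) used to derive edge travel times.
MODE_DETOUR <- c(road = 1.3, rail = 1.2, maritime_drybulk = 1.5,
                 maritime_container = 1.5, maritime_generalcargo = 1.5)
MODE_SPEED <- c(road = 60, rail = 50, maritime_drybulk = 30,
                maritime_container = 35, maritime_generalcargo = 28)

#' Generate a complete synthetic input bundle
#'
#' Produces an internally consistent world: every trading country pair is
#' connected by at least one feasible multimodal route, every exporter has
#' producing regions, and bilateral imports never exceed global production.
#' The same seed reproduces the bundle exactly.
#'
#' @param config A [world_config()] object.
#' @return A `glcm_bundle`: a named list of tibbles `regions`, `nodes`,
#'   `edges`, `production`, `input_costs`, `transport_params`, `trade`,
#'   `tariffs`, plus the `config` used.
#' @export
#' @examples
#' bundle <- generate_world(world_config(n_countries = 4, seed = 7))
#' names(bundle)
generate_world <- function(config = world_config()) {
  if (!inherits(config, "glcm_world_config")) {
    stop_glcm("`config` must be created with world_config().",
              "glcm_config_error")
  }
  with_rng(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  n_c <- config$n_countries
  disp <- config$cost_dispersion
  countries <- sprintf("C%02d", seq_len(n_c))

  cx <- runif(n_c, 0, 5000)
  cy <- runif(n_c, 0, 5000)

  n_reg <- sample(seq(config$regions_per_country[1],
                      config$regions_per_country[2]),
                  n_c, replace = TRUE)

  regions <- map_dfr(seq_len(n_c), function(i) {
    k <- n_reg[i]
    tibble(
      region_id = sprintf("%s_R%02d", countries[i], seq_len(k)),
      country = countries[i],
      population = rlnorm(k, meanlog = log(6e5), sdlog = 0.8),
      x = cx[i] + runif(k, -250, 250),
      y = cy[i] + runif(k, -250, 250)
    )
  })
  regions$node <- sprintf("N_%s", regions$region_id)

  # Countries with a port, chosen at random; the rest are landlocked.
  n_port <- max(1L, ceiling(config$maritime_fraction * n_c))
  port_countries <- sort(sample(countries, n_port))
  rail_countries <- sort(sample(countries, max(2L, ceiling(0.6 * n_c))))

  nodes <- tibble(
    node_id = regions$node, country = regions$country,
    x = regions$x, y = regions$y,
    is_port = FALSE,
    has_rail = regions$country %in% rail_countries
  )
  ports <- tibble(
    node_id = sprintf("P_%s", port_countries),
    country = port_countries,
    x = cx[match(port_countries, countries)] + runif(n_port, -100, 100),
    y = cy[match(port_countries, countries)] + runif(n_port, -100, 100),
    is_port = TRUE,
    has_rail = port_countries %in% rail_countries
  )
  nodes <- bind_rows(nodes, ports)

  edges <- generate_edges(nodes, regions, countries, port_countries,
                          rail_countries, config$network_density)

  production <- generate_production(regions, config$commodities, disp)
  input_costs <- generate_input_costs(countries, config$commodities, disp)
  transport_params <- generate_transport_params(countries, disp)

  demand <- generate_demand(regions, production, config$commodities)
  trade <- generate_trade_matrix_impl(production, demand)
  tariffs <- trade |>
    distinct(.data$exporter, .data$importer, .data$commodity) |>
    mutate(ad_valorem_rate = if_else(runif(n()) < 0.3, 0, runif(n(), 0, 0.25)))

  structure(
    list(
      regions = select(regions, "region_id", "country", "population", "node"),
      nodes = nodes,
      edges = edges,
      production = production,
      input_costs = input_costs,
      transport_params = transport_params,
      trade = trade,
      tariffs = tariffs,
      config = config
    ),
    class = "glcm_bundle"
  )
}

edge_row <- function(nodes, a, b, mode) {
  ia <- match(a, nodes$node_id)
  ib <- match(b, nodes$node_id)
  d <- pmax(euclid(nodes$x[ia], nodes$y[ia], nodes$x[ib], nodes$y[ib]), 15) *
    MODE_DETOUR[[mode]]
  t_h <- d / MODE_SPEED[[mode]]
  tibble(node_a = pmin(a, b), node_b = pmax(a, b), mode = mode,
         distance_km = d, time_h = t_h)
}

generate_edges <- function(nodes, regions, countries, port_countries,
                           rail_countries, density) {
  edges <- list()

  # Intra-country road backbone: chain regions, then optional shortcuts.
  for (cc in countries) {
    rn <- sort(regions$node[regions$country == cc])
    if (length(rn) >= 2) {
      edges[[length(edges) + 1L]] <-
        edge_row(nodes, rn[-length(rn)], rn[-1], "road")
      if (length(rn) >= 3) {
        extra <- utils::combn(rn, 2)
        keep <- runif(ncol(extra)) < density
        if (any(keep)) {
          edges[[length(edges) + 1L]] <-
            edge_row(nodes, extra[1, keep], extra[2, keep], "road")
        }
      }
      if (cc %in% rail_countries && length(rn) >= 2) {
        edges[[length(edges) + 1L]] <-
          edge_row(nodes, rn[-length(rn)], rn[-1], "rail")
      }
    }
  }

  # Ports attach to their country's nearest region node by road (+ rail).
  for (cc in port_countries) {
    pid <- sprintf("P_%s", cc)
    rn <- regions$node[regions$country == cc]
    ip <- match(pid, nodes$node_id)
    d <- euclid(nodes$x[match(rn, nodes$node_id)],
                nodes$y[match(rn, nodes$node_id)],
                nodes$x[ip], nodes$y[ip])
    nearest <- rn[which.min(d)]
    edges[[length(edges) + 1L]] <- edge_row(nodes, pid, nearest, "road")
    if (cc %in% rail_countries) {
      edges[[length(edges) + 1L]] <- edge_row(nodes, pid, nearest, "rail")
    }
  }

  # Cross-border land links to the two nearest neighbours.
  cpos <- regions |>
    group_by(.data$country) |>
    summarise(x = mean(.data$x), y = mean(.data$y))
  for (cc in countries) {
    i <- match(cc, cpos$country)
    d <- euclid(cpos$x, cpos$y, cpos$x[i], cpos$y[i])
    d[i] <- Inf
    nb <- cpos$country[order(d)[seq_len(min(2L, length(countries) - 1L))]]
    for (nn in nb) {
      ra <- regions[regions$country == cc, ]
      rb <- regions[regions$country == nn, ]
      dd <- outer(seq_len(nrow(ra)), seq_len(nrow(rb)), function(i, j) {
        euclid(ra$x[i], ra$y[i], rb$x[j], rb$y[j])
      })
      best <- arrayInd(which.min(dd), dim(dd))
      a <- ra$node[best[1]]; b <- rb$node[best[2]]
      edges[[length(edges) + 1L]] <- edge_row(nodes, a, b, "road")
      if (cc %in% rail_countries && nn %in% rail_countries) {
        edges[[length(edges) + 1L]] <- edge_row(nodes, a, b, "rail")
      }
    }
  }

  # Landlocked countries reach the nearest foreign port by road.
  landlocked <- setdiff(countries, port_countries)
  pnodes <- nodes[nodes$is_port, ]
  for (cc in landlocked) {
    ra <- regions[regions$country == cc, ]
    dd <- outer(seq_len(nrow(ra)), seq_len(nrow(pnodes)), function(i, j) {
      euclid(ra$x[i], ra$y[i], pnodes$x[j], pnodes$y[j])
    })
    best <- arrayInd(which.min(dd), dim(dd))
    edges[[length(edges) + 1L]] <-
      edge_row(nodes, ra$node[best[1]], pnodes$node_id[best[2]], "road")
  }

  # Maritime layers: a ring over all ports guarantees connectivity, plus
  # optional direct connections drawn at the configured density.
  pid <- sort(pnodes$node_id)
  for (mode in GLCM_MODES[3:5]) {
    if (length(pid) >= 2) {
      ring_a <- pid
      ring_b <- c(pid[-1], pid[1])
      keep <- ring_a != ring_b
      edges[[length(edges) + 1L]] <-
        edge_row(nodes, ring_a[keep], ring_b[keep], mode)
      if (length(pid) >= 3) {
        extra <- utils::combn(pid, 2)
        keep <- runif(ncol(extra)) < density
        if (any(keep)) {
          edges[[length(edges) + 1L]] <-
            edge_row(nodes, extra[1, keep], extra[2, keep], mode)
        }
      }
    }
  }

  bind_rows(edges) |>
    distinct(.data$node_a, .data$node_b, .data$mode, .keep_all = TRUE) |>
    arrange(.data$mode, .data$node_a, .data$node_b)
}

# Commodity-specific yield levels (t/ha) loosely spanning cereal/oilseed
# ranges; unknown codes fall back to 3 t/ha.
commodity_yield_base <- function(commodity) {
  base <- c(maize = 5.5, wheat = 3.4, sorghum = 1.5, barley = 3.0,
            soybean = 2.8, rice = 4.6)
  out <- base[commodity]
  out[is.na(out)] <- 3.0
  unname(out)
}

generate_production <- function(regions, commodities, disp) {
  grid <- tidyr::expand_grid(region_id = regions$region_id,
                             commodity = commodities)
  grid <- grid[runif(nrow(grid)) < 0.75, , drop = FALSE]
  # Guarantee every country produces every commodity somewhere, so any
  # country can appear as an exporter.
  first_region <- regions |>
    group_by(.data$country) |>
    slice(1L) |>
    ungroup()
  must <- tidyr::expand_grid(region_id = first_region$region_id,
                             commodity = commodities)
  grid <- distinct(bind_rows(grid, must))
  grid |>
    mutate(
      yield_t_ha = commodity_yield_base(.data$commodity) *
        rlnorm(n(), 0, disp),
      area_ha = rlnorm(n(), log(2.5e4), 0.7),
      production_t = .data$yield_t_ha * .data$area_ha
    ) |>
    select("region_id", "commodity", "production_t", "yield_t_ha") |>
    arrange(.data$region_id, .data$commodity)
}

generate_input_costs <- function(countries, commodities, disp) {
  base <- c(fertilizer = 150, pesticides = 60, labour = 120,
            machinery = 100, diesel = 40)
  tidyr::expand_grid(country = countries, commodity = commodities) |>
    mutate(
      fertilizer = base[["fertilizer"]] * rlnorm(n(), 0, disp),
      pesticides = base[["pesticides"]] * rlnorm(n(), 0, disp),
      labour = base[["labour"]] * rlnorm(n(), 0, disp),
      machinery = base[["machinery"]] * rlnorm(n(), 0, disp),
      diesel = base[["diesel"]] * rlnorm(n(), 0, disp)
    )
}

generate_transport_params <- function(countries, disp) {
  base <- tibble(
    mode = GLCM_MODES,
    dc_usd_t_km = c(0.05, 0.03, 0.004, 0.006, 0.008),
    hc_usd_t = c(2, 3, 5, 6, 5.5),
    wait_h = c(2, 12, 48, 36, 48),
    vfft_usd_t_h = c(0.05, 0.03, 0.01, 0.015, 0.01),
    border_usd_t = c(8, 8, 12, 12, 12)
  )
  tidyr::expand_grid(country = countries, base) |>
    mutate(across(c("dc_usd_t_km", "hc_usd_t", "wait_h", "vfft_usd_t_h",
                    "border_usd_t"),
                  ~ .x * rlnorm(n(), 0, disp / 2)))
}

generate_demand <- function(regions, production, commodities) {
  pop <- regions |>
    group_by(country = .data$country) |>
    summarise(population = sum(.data$population))
  prod_c <- production |>
    left_join(tibble(region_id = regions$region_id,
                     country = regions$country), by = "region_id") |>
    group_by(.data$country, .data$commodity) |>
    summarise(production_t = sum(.data$production_t), .groups = "drop")
  global_prod <- prod_c |>
    group_by(.data$commodity) |>
    summarise(total = sum(.data$production_t))
  # Per-capita import appetite scaled so that global import demand stays
  # well inside global production (imports are a slice of consumption).
  tidyr::expand_grid(country = pop$country, commodity = commodities) |>
    left_join(pop, by = "country") |>
    left_join(global_prod, by = "commodity") |>
    mutate(
      appetite = runif(n(), 0.2, 1),
      import_t = .data$appetite * .data$population /
        sum(pop$population) * 0.35 * .data$total
    ) |>
    select("country", "commodity", "import_t")
}

#' Generate a bilateral trade matrix from production and demand
#'
#' Allocates each country's import demand across exporting countries with
#' exportable surplus, guaranteeing that no exporter ships more than it
#' produces and that all flows are non-negative. Domestic flows are never
#' generated.
#'
#' @param production Tibble `region_id, commodity, production_t, yield_t_ha`
#'   (a `country` column is joined from `regions` when present as attribute;
#'   alternatively pass a `country` column directly).
#' @param demand Tibble `country, commodity, import_t` of import demand.
#' @param seed Integer seed.
#' @return Tibble `exporter, importer, commodity, tonnes` with positive flows.
#' @export
generate_trade_matrix <- function(production, demand, seed = 1L) {
  if (!all(unique(demand$commodity) %in% unique(production$commodity))) {
    stop_glcm("`production` and `demand` must share commodity codes.")
  }
  with_rng(seed, generate_trade_matrix_impl(production, demand))
}

generate_trade_matrix_impl <- function(production, demand) {
  if ("country" %in% names(production)) {
    prod_c <- production |>
      group_by(.data$country, .data$commodity) |>
      summarise(production_t = sum(.data$production_t), .groups = "drop")
  } else {
    # region ids are "<country>_Rxx" by construction
    prod_c <- production |>
      mutate(country = sub("_R[0-9]+$", "", .data$region_id)) |>
      group_by(.data$country, .data$commodity) |>
      summarise(production_t = sum(.data$production_t), .groups = "drop")
  }
  demand <- filter(demand, .data$import_t > 0)
  if (nrow(demand) == 0) {
    return(tibble(exporter = character(), importer = character(),
                  commodity = character(), tonnes = double()))
  }
  tot_d <- demand |> group_by(.data$commodity) |>
    summarise(d = sum(.data$import_t))
  tot_p <- prod_c |> group_by(.data$commodity) |>
    summarise(p = sum(.data$production_t))
  chk <- left_join(tot_d, tot_p, by = "commodity")
  bad <- chk$commodity[is.na(chk$p) | chk$d > chk$p]
  if (length(bad)) {
    stop_glcm(sprintf(
      "Global import demand exceeds global production for: %s.",
      paste(bad, collapse = ", ")))
  }

  flows <- map_dfr(seq_len(nrow(demand)), function(i) {
    ic <- demand$country[i]
    g <- demand$commodity[i]
    need <- demand$import_t[i]
    cand <- prod_c |>
      filter(.data$commodity == g, .data$country != ic,
             .data$production_t > 0)
    if (nrow(cand) == 0) return(NULL)
    k <- min(nrow(cand), sample(2:5, 1))
    pick <- cand |>
      slice(sample(n(), k, prob = .data$production_t)) |>
      mutate(w = .data$production_t * runif(k, 0.3, 1))
    tibble(exporter = pick$country, importer = ic, commodity = g,
           tonnes = need * pick$w / sum(pick$w))
  })

  # Cap each exporter's shipments at its production, scaling its outgoing
  # flows proportionally when over-subscribed.
  caps <- flows |>
    group_by(.data$exporter, .data$commodity) |>
    summarise(out = sum(.data$tonnes), .groups = "drop") |>
    left_join(prod_c, by = c(exporter = "country", "commodity")) |>
    mutate(scale = pmin(1, .data$production_t / .data$out))
  flows |>
    left_join(select(caps, "exporter", "commodity", "scale"),
              by = c("exporter", "commodity")) |>
    mutate(tonnes = .data$tonnes * .data$scale) |>
    select("exporter", "importer", "commodity", "tonnes") |>
    filter(.data$tonnes > 0) |>
    arrange(.data$commodity, .data$importer, .data$exporter)
}

#' Validate a bundle's internal consistency
#'
#' Checks the structural contracts every stage relies on: positive costs,
#' yields and populations, referential integrity between tables, exporters
#' with producing regions, importers with inbound flows, exports bounded by
#' production, and mode labels restricted to the five layers.
#'
#' @param bundle A `glcm_bundle`.
#' @return Character vector of problems; `character(0)` when valid.
#' @export
validate_bundle <- function(bundle) {
  p <- character()
  req <- c("regions", "nodes", "edges", "production", "input_costs",
           "transport_params", "trade", "tariffs")
  miss <- setdiff(req, names(bundle))
  if (length(miss)) {
    return(sprintf("missing tables: %s", paste(miss, collapse = ", ")))
  }
  rg <- bundle$regions; nd <- bundle$nodes; ed <- bundle$edges
  if (any(rg$population <= 0)) p <- c(p, "non-positive region population")
  if (anyDuplicated(rg$region_id)) p <- c(p, "duplicate region ids")
  if (!all(rg$node %in% nd$node_id)) p <- c(p, "region attached to unknown node")
  if (!all(ed$node_a %in% nd$node_id) || !all(ed$node_b %in% nd$node_id)) {
    p <- c(p, "edge endpoint not in node table")
  }
  if (any(ed$distance_km <= 0)) p <- c(p, "non-positive edge distance")
  if (any(ed$time_h < 0)) p <- c(p, "negative edge time")
  if (!all(ed$mode %in% GLCM_MODES)) p <- c(p, "unknown edge mode")
  if (anyDuplicated(ed[, c("node_a", "node_b", "mode")])) {
    p <- c(p, "duplicate undirected edge")
  }
  if (any(bundle$production$production_t <= 0) ||
      any(bundle$production$yield_t_ha <= 0)) {
    p <- c(p, "non-positive production or yield")
  }
  if (!all(bundle$production$region_id %in% rg$region_id)) {
    p <- c(p, "production references unknown region")
  }
  ic <- bundle$input_costs
  if (any(as.matrix(ic[GLCM_INPUTS]) < 0)) p <- c(p, "negative input cost")
  tp <- bundle$transport_params
  if (any(as.matrix(tp[c("dc_usd_t_km", "hc_usd_t", "wait_h",
                         "vfft_usd_t_h", "border_usd_t")]) < 0)) {
    p <- c(p, "negative transport parameter")
  }
  tr <- bundle$trade
  if (any(tr$tonnes < 0)) p <- c(p, "negative trade flow")
  if (any(tr$exporter == tr$importer)) p <- c(p, "domestic trade flow present")
  cset <- unique(rg$country)
  if (!all(c(tr$exporter, tr$importer) %in% cset)) {
    p <- c(p, "trade references unknown country")
  }
  if (any(bundle$tariffs$ad_valorem_rate < 0)) p <- c(p, "negative tariff rate")

  prod_c <- bundle$production |>
    left_join(select(rg, "region_id", "country"), by = "region_id") |>
    group_by(.data$country, .data$commodity) |>
    summarise(production_t = sum(.data$production_t), .groups = "drop")
  exp_tot <- tr |>
    group_by(country = .data$exporter, .data$commodity) |>
    summarise(out = sum(.data$tonnes), .groups = "drop") |>
    left_join(prod_c, by = c("country", "commodity"))
  if (any(is.na(exp_tot$production_t)) ||
      any(exp_tot$out > exp_tot$production_t * (1 + 1e-9))) {
    p <- c(p, "exports exceed exporter production")
  }
  glob <- prod_c |> group_by(.data$commodity) |>
    summarise(p = sum(.data$production_t))
  imp <- tr |> group_by(.data$importer, .data$commodity) |>
    summarise(i = sum(.data$tonnes), .groups = "drop") |>
    left_join(glob, by = "commodity")
  if (any(imp$i > imp$p * (1 + 1e-9))) {
    p <- c(p, "country imports exceed global production")
  }
  p
}

#' @export
print.glcm_bundle <- function(x, ...) {
  cat("<glcm_bundle>\n")
  cat(sprintf("  %d countries, %d regions, %d nodes, %d edges\n",
              length(unique(x$regions$country)), nrow(x$regions),
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  %d commodities, %d bilateral flows\n",
              length(unique(x$production$commodity)), nrow(x$trade)))
  invisible(x)
}
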