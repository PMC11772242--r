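test_that("generalized cost reproduces the closed-form components", {
  expect_equal(generalized_cost(0.05, 100), 5.0)
  expect_equal(generalized_cost(0.05, 100, hc = 2, vfft = 0.1, t = 10,
                                w = 5, b = 1), 9.5)
  expect_equal(generalized_cost(0, 0), 0)
  expect_error(generalized_cost(-0.01, 100), "dc", class = "glcm_error")
})

test_that("a single road edge with zero handling gives the bare distance cost", {
  b <- toy_bundle(params = flat_params(c("A", "B", "C"), dc = 0.05),
                  maritime = FALSE)
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "B_R1", "road")
  expect_true(r$feasible)
  # 100 km at 0.05 USD/t/km; A->B crossing has zero border cost here
  expect_equal(r$transport_cost, 5)
  expect_equal(r$gc, 5)
  expect_equal(r$distance_km, 100)
})

test_that("port transfers inherit the port country's maritime handling cost", {
  p <- flat_params(c("A", "B", "C"), dc = 0.05) |>
    dplyr::mutate(hc_usd_t = ifelse(country == "A" &
                                      mode == "maritime_drybulk", 7, 0))
  b <- toy_bundle(params = p)
  # drop the land bridge so the optimum must use the sea leg
  b$edges <- b$edges[!(b$edges$node_a %in% "NA1" & b$edges$node_b == "NB1") &
                       !(b$edges$node_a == "NB1"), ]
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "C_R1", "maritime_drybulk")
  # road A->PA (50km) + transfer (7, A's port charge) + sea 1000 km +
  # transfer (0, C's port) + road PC->C (50km)
  expect_equal(r$transport_cost, 0.05 * (50 + 1000 + 50) + 7)
})

test_that("every declared edge appears exactly once per owning layer", {
  b <- small_world(seed = 2)
  g <- build_transport_graph(b)
  declared <- nrow(b$edges)
  # each undirected physical edge contributes two directed travel rows in
  # the layers that include its mode
  travel_rows <- purrr::map_int(names(g$adj), function(m) {
    e <- g$adj[[m]]$edges
    sum(e$kind == "travel" & e$mode == m)
  })
  per_mode_declared <- table(factor(b$edges$mode, levels = names(g$adj)))
  expect_equal(unname(travel_rows[match("road", names(g$adj))]),
               2L * unname(per_mode_declared[["road"]]))
  expect_equal(sum(g$adj$maritime_drybulk$edges$kind == "travel" &
                     g$adj$maritime_drybulk$edges$mode == "maritime_drybulk"),
               2L * unname(per_mode_declared[["maritime_drybulk"]]))
  expect_equal(g$n_edges_declared, declared)
})

test_that("origin equal to destination is a zero-cost route", {
  g <- build_transport_graph(toy_bundle())
  r <- least_cost_route(g, "A_R1", "A_R1", "road")
  expect_equal(r$gc, 0)
  expect_equal(r$distance_km, 0)
  expect_true(r$feasible)
})

test_that("disconnected pairs give an explicit no-route row, not an error", {
  b <- toy_bundle(maritime = FALSE)
  b$edges <- b$edges[b$edges$node_a != "NB1" & b$edges$node_b != "NB1", ]
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "C_R1", "road")
  expect_false(r$feasible)
  expect_equal(r$gc, Inf)
})

test_that("Dijkstra equals the exhaustive enumeration oracle on random mini-worlds", {
  for (s in 1:60) {
    b <- random_mini_bundle(s)
    g <- build_transport_graph(b)
    n <- nrow(b$regions)
    o <- b$regions$region_id[1]
    d <- b$regions$region_id[n]
    for (m in c("road", "rail")) {
      r <- least_cost_route(g, o, d, m)
      oracle <- enumerate_min_gc(g, m, o, d)
      if (r$feasible) {
        expect_equal(r$gc, oracle, tolerance = 1e-10,
                     label = sprintf("seed %d mode %s", s, m))
      } else {
        expect_identical(oracle, Inf)
      }
    }
  }
})

test_that("Dijkstra matches igraph distances on a full synthetic world", {
  skip_if_not_installed("igraph")
  b <- small_world(seed = 6)
  g <- build_transport_graph(b)
  for (m in c("road", "maritime_drybulk")) {
    e <- g$adj[[m]]$edges
    ig <- igraph::graph_from_data_frame(
      data.frame(from = e$fi, to = e$ti, weight = e$weight),
      directed = TRUE,
      vertices = data.frame(name = seq_len(nrow(g$vertices))))
    origins <- b$regions$region_id[c(1, 5, 9)]
    dests <- b$regions$region_id[c(2, 7)]
    dm <- igraph::distances(
      ig, v = as.character(match(paste0("r|", origins), g$vertices$vid)),
      to = as.character(match(paste0("r|", dests), g$vertices$vid)))
    for (i in seq_along(origins)) {
      for (j in seq_along(dests)) {
        r <- least_cost_route(g, origins[i], dests[j], m)
        expect_equal(r$gc, unname(dm[i, j]), tolerance = 1e-9)
      }
    }
  }
})

test_that("equal-cost ties resolve to the lexicographically smallest path", {
  # diamond: A -> {M1, M2} -> Z with identical costs on both arms
  regions <- tibble::tibble(region_id = c("A_R1", "Z_R1"),
                            country = c("A", "Z"),
                            population = c(1, 1), node = c("NA1", "NZ1"))
  nodes <- tibble::tibble(
    node_id = c("NA1", "NM1", "NM2", "NZ1"),
    country = c("A", "A", "A", "Z"),
    x = 0, y = 0, is_port = FALSE, has_rail = FALSE)
  edges <- tibble::tibble(
    node_a = c("NA1", "NA1", "NM1", "NM2"),
    node_b = c("NM1", "NM2", "NZ1", "NZ1"),
    mode = "road", distance_km = 100, time_h = 2)
  b <- toy_bundle(maritime = FALSE)
  b$regions <- regions; b$nodes <- nodes; b$edges <- edges
  b$transport_params <- flat_params(c("A", "Z"), dc = 0.05)
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "Z_R1", "road")
  expect_equal(r$path, "A_R1>NA1>NM1>NZ1>Z_R1")
})

test_that("mode selection is argmin with the fixed priority tie-break", {
  mk <- function(mode, gc, feasible = TRUE) {
    tibble::tibble(mode = mode, gc = gc, feasible = feasible)
  }
  expect_equal(select_mode(dplyr::bind_rows(
    mk("road", 50), mk("maritime_drybulk", 30)))$mode, "maritime_drybulk")
  expect_equal(select_mode(dplyr::bind_rows(
    mk("rail", 40), mk("road", 40)))$mode, "road")
  expect_equal(select_mode(mk("road", 12))$mode, "road")
  expect_equal(nrow(select_mode(mk("road", Inf, feasible = FALSE))), 0)
})

test_that("trade cost charges money only: TC = TrC + B", {
  rt <- tibble::tibble(transport_cost = c(40, 40), border_cost = c(5, 0))
  expect_equal(trade_cost(rt)$tc, c(45, 40))
})

test_that("route decomposition reconstructs gc and splits at the border", {
  p <- flat_params(c("A", "B", "C"), dc = 0.05, hc = 1, w = 2, vfft = 0.1,
                   b = 3)
  b <- toy_bundle(params = p, maritime = FALSE)
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "C_R1", "road")
  # edge-walk oracle: attach(1) road A-B(5) road B-C(5) attach(1) = 12 money
  expect_equal(r$transport_cost, 0.05 * 200 + 2 * 1)
  # two crossings: A|B and B|C, each 3 + 3
  expect_equal(r$border_cost, 12)
  expect_equal(r$gc, r$transport_cost + r$border_cost + r$time_cost)
  # pre-border: attach at A (1) + A-B edge (5) + B-C edge (5, enters C);
  # destination unloading excluded
  expect_equal(r$trcb, 1 + 5 + 5)
  expect_true(r$trcb >= 0 && r$trcb <= r$transport_cost)
})

test_that("maritime entry keeps the importer port handling pre-border", {
  p <- flat_params(c("A", "B", "C"), dc = 0.05) |>
    dplyr::mutate(hc_usd_t = ifelse(mode == "maritime_drybulk", 4, 0))
  b <- toy_bundle(params = p)
  b$edges <- b$edges[!(b$edges$node_a %in% "NA1" & b$edges$node_b == "NB1") &
                       !(b$edges$node_a == "NB1"), ]
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "C_R1", "maritime_drybulk")
  # pre-border: road to PA (2.5) + PA handling (4) + sea (50) + PC handling (4)
  expect_equal(r$trcb, 2.5 + 4 + 50 + 4)
  # post-border: PC->NC1 road (2.5)
  expect_equal(r$transport_cost - r$trcb, 2.5)
})

test_that("a route entirely inside the importer has zero pre-border cost", {
  b <- toy_bundle(maritime = FALSE)
  b$regions$country <- "C"
  b$nodes$country <- "C"
  b$transport_params <- flat_params("C", dc = 0.05)
  g <- build_transport_graph(b)
  r <- least_cost_route(g, "A_R1", "C_R1", "road")
  expect_equal(r$trcb, 0)
  expect_gt(r$transport_cost, 0)
})

test_that("raising any cost parameter never lowers a pair's generalized cost", {
  b <- toy_bundle()
  base <- least_cost_route(build_transport_graph(b), "A_R1", "C_R1",
                           "maritime_drybulk")
  for (col in c("dc_usd_t_km", "hc_usd_t", "wait_h", "vfft_usd_t_h",
                "border_usd_t")) {
    b2 <- b
    b2$transport_params[[col]] <- b$transport_params[[col]] + 1
    r2 <- least_cost_route(build_transport_graph(b2), "A_R1", "C_R1",
                           "maritime_drybulk")
    expect_gte(r2$gc, base$gc)
  }
})

test_that("optimal costs satisfy the waypoint triangle property", {
  b <- small_world(seed = 13)
  g <- build_transport_graph(b)
  rg <- b$regions$region_id
  withr::local_seed(7)
  for (i in 1:8) {
    abc <- sample(rg, 3)
    r_ac <- least_cost_route(g, abc[1], abc[3], "rail")
    r_ab <- least_cost_route(g, abc[1], abc[2], "rail")
    r_bc <- least_cost_route(g, abc[2], abc[3], "rail")
    if (r_ab$feasible && r_bc$feasible) {
      expect_lte(r_ac$gc, r_ab$gc + r_bc$gc + 1e-9)
    }
  }
})

test_that("pre-border cost is bounded by total transport cost on real worlds", {
  w <- tiny_flows(seed = 8)
  expect_true(all(w$routes$trcb >= -1e-12))
  expect_true(all(w$routes$trcb <= w$routes$transport_cost + 1e-9))
})
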