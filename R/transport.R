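#' Generalized cost of a freight movement
#'
#' Routing objective combining monetary and time components:
#' `GC = DC * D + HC + VFTT * (T + W) + B`, with DC the distance cost rate
#' (USD/t/km), D the distance (km), HC total handling charges (USD/t), VFTT
#' the value of freight travel time (USD/t/h), T travel time and W waiting or
#' dwell time (h), and B border compliance costs (USD/t).
#'
#' @param dc Distance cost rate, USD per tonne per km.
#' @param d Distance, km.
#' @param hc Total handling cost, USD/t.
#' @param vfft Value of freight travel time, USD per tonne per hour.
#' @param t Travel time, hours.
#' @param w Waiting/dwell time, hours.
#' @param b Border compliance cost, USD/t.
#' @return Generalized cost in USD/t (vectorised).
#' @export
#' @examples
#' generalized_cost(0.05, 100, 2, 0.1, 10, 5, 1) # 9.5
generalized_cost <- function(dc, d, hc = 0, vfft = 0, t = 0, w = 0, b = 0) {
  for (nm in c("dc", "d", "hc", "vfft", "t", "w", "b")) {
    check_nonnegative(get(nm), nm)
  }
  dc * d + hc + vfft * (t + w) + b
}

# ---- graph construction -----------------------------------------------------

param_lookup <- function(params, what) {
  key <- paste(params$country, params$mode, sep = "\r")
  setNames(params[[what]], key)
}

pget <- function(lk, country, mode, default = NA_real_) {
  v <- unname(lk[paste(country, mode, sep = "\r")])
  v[is.na(v)] <- default
  v
}

#' Build the five-layer multimodal transport graph
#'
#' Creates one routable graph per mode. The `road` graph contains region
#' attachments and road edges; the `rail` graph adds rail edges plus
#' road-rail terminal transfers; each maritime graph adds one maritime layer
#' plus port transfers, so land access legs are always available. Transfer
#' and attachment edges carry the handling cost and dwell time of the node's
#' country for the layer being entered; travel edges carry distance costs,
#' travel time, and (when they cross a border) both countries' border
#' compliance charges for that mode. Rail edges are dropped for country
#' pairs lacking rail parameters.
#'
#' @param bundle A `glcm_bundle` providing `regions`, `nodes`, `edges` and
#'   `transport_params`.
#' @return A `glcm_graph` object used by [least_cost_route()] and
#'   [compute_routes()].
#' @export
build_transport_graph <- function(bundle) {
  nodes <- bundle$nodes
  edges <- bundle$edges
  regions <- bundle$regions
  params <- bundle$transport_params

  missing_attach <- setdiff(regions$node, nodes$node_id)
  if (length(missing_attach)) {
    stop_glcm(sprintf(
      "Regions attached to unknown nodes: %s.",
      paste(regions$region_id[regions$node %in% missing_attach],
            collapse = ", ")))
  }

  node_country <- setNames(nodes$country, nodes$node_id)
  lk_dc <- param_lookup(params, "dc_usd_t_km")
  lk_hc <- param_lookup(params, "hc_usd_t")
  lk_w <- param_lookup(params, "wait_h")
  lk_vf <- param_lookup(params, "vfft_usd_t_h")
  lk_b <- param_lookup(params, "border_usd_t")

  ca <- node_country[edges$node_a]
  cb <- node_country[edges$node_b]

  # Rail edges require rail parameters on both sides.
  if (any(edges$mode == "rail")) {
    ok <- edges$mode != "rail" |
      (!is.na(pget(lk_dc, ca, "rail")) & !is.na(pget(lk_dc, cb, "rail")))
    if (any(!ok)) {
      warn(sprintf("Dropping %d rail edges lacking rail parameters.",
                   sum(!ok)))
      edges <- edges[ok, , drop = FALSE]
      ca <- ca[ok]; cb <- cb[ok]
    }
  }

  dc_e <- (pget(lk_dc, ca, edges$mode) + pget(lk_dc, cb, edges$mode)) / 2
  vf_e <- (pget(lk_vf, ca, edges$mode) + pget(lk_vf, cb, edges$mode)) / 2
  b_e <- if_else(ca == cb, 0,
                 pget(lk_b, ca, edges$mode) + pget(lk_b, cb, edges$mode))
  if (any(is.na(dc_e) | is.na(vf_e) | is.na(b_e))) {
    stop_glcm("Missing transport parameters for some edge countries/modes.")
  }

  travel <- tibble(
    from = paste(edges$mode, edges$node_a, sep = "|"),
    to = paste(edges$mode, edges$node_b, sep = "|"),
    kind = "travel",
    mode = edges$mode,
    country_a = unname(ca),
    country_b = unname(cb),
    money = dc_e * edges$distance_km,
    border = b_e,
    time_h = edges$time_h,
    dist_km = edges$distance_km,
    vfft_cost = vf_e * edges$time_h
  )

  layer_nodes <- distinct(tibble(
    node_id = c(edges$node_a, edges$node_b),
    mode = rep(edges$mode, 2)
  ))

  transfer_edges <- function(target_mode) {
    tn <- layer_nodes$node_id[layer_nodes$mode == target_mode]
    tn <- intersect(tn, layer_nodes$node_id[layer_nodes$mode == "road"])
    if (!length(tn)) return(NULL)
    cc <- node_country[tn]
    tibble(
      from = paste("road", tn, sep = "|"),
      to = paste(target_mode, tn, sep = "|"),
      kind = "transfer",
      mode = target_mode,
      country_a = unname(cc),
      country_b = unname(cc),
      money = pget(lk_hc, cc, target_mode),
      border = 0,
      time_h = pget(lk_w, cc, target_mode),
      dist_km = 0,
      vfft_cost = pget(lk_vf, cc, target_mode) * pget(lk_w, cc, target_mode)
    )
  }

  rc <- regions$country
  attach <- tibble(
    from = paste0("r|", regions$region_id),
    to = paste("road", regions$node, sep = "|"),
    kind = "attach",
    mode = "road",
    country_a = unname(rc),
    country_b = unname(rc),
    money = pget(lk_hc, rc, "road"),
    border = 0,
    time_h = pget(lk_w, rc, "road"),
    dist_km = 0,
    vfft_cost = pget(lk_vf, rc, "road") * pget(lk_w, rc, "road")
  )

  rail_transfer <- transfer_edges("rail")
  mode_edges <- list(
    road = bind_rows(attach, filter(travel, .data$mode == "road"))
  )
  land <- bind_rows(mode_edges$road,
                    filter(travel, .data$mode == "rail"), rail_transfer)
  mode_edges$rail <- land
  for (mm in GLCM_MODES[3:5]) {
    mode_edges[[mm]] <- bind_rows(
      land, filter(travel, .data$mode == mm), transfer_edges(mm))
  }

  # One shared, lexicographically sorted vertex universe: Dijkstra settles
  # equal-distance vertices in name order, which underpins the documented
  # lexicographic tie-break on equal-cost paths.
  all_vids <- sort(unique(c(
    paste0("r|", regions$region_id),
    unlist(map(mode_edges, ~ c(.x$from, .x$to)), use.names = FALSE)
  )))
  vtab <- tibble(
    vid = all_vids,
    layer = sub("\\|.*$", "", all_vids),
    name = sub("^[^|]*\\|", "", all_vids)
  )

  adj <- map(mode_edges, function(e) {
    e$weight <- e$money + e$border + e$vfft_cost
    dir <- bind_rows(
      mutate(e, fi = match(.data$from, all_vids), ti = match(.data$to, all_vids)),
      mutate(e, fi = match(.data$to, all_vids), ti = match(.data$from, all_vids))
    )
    dir <- arrange(dir, .data$fi, .data$ti)
    ptr <- c(0L, cumsum(tabulate(dir$fi, nbins = length(all_vids))))
    list(edges = dir, ptr = ptr)
  })

  structure(
    list(vertices = vtab, adj = adj,
         region_country = setNames(regions$country, regions$region_id),
         n_edges_declared = nrow(edges)),
    class = "glcm_graph"
  )
}

#' @export
print.glcm_graph <- function(x, ...) {
  cat(sprintf("<glcm_graph> %d vertices, %d declared physical edges, %d mode layers\n",
              nrow(x$vertices), x$n_edges_declared, length(x$adj)))
  invisible(x)
}

# ---- Dijkstra ---------------------------------------------------------------

# One-to-all Dijkstra over one mode graph. Vertices are settled in
# (distance, lexicographic vid) order and, on cost ties (1e-9 relative),
# the predecessor giving the lexicographically smallest node path wins.
dijkstra_sssp <- function(graph, mode, source_vid, targets = NULL) {
  adjm <- graph$adj[[mode]]
  nv <- nrow(graph$vertices)
  s <- match(source_vid, graph$vertices$vid)
  if (is.na(s)) stop_glcm(sprintf("Unknown origin vertex %s.", source_vid))
  dist <- rep(Inf, nv)
  pred <- rep(NA_integer_, nv)
  pred_edge <- rep(NA_integer_, nv)
  visited <- logical(nv)
  dist[s] <- 0
  e <- adjm$edges
  ptr <- adjm$ptr
  all_ti <- e$ti
  all_w <- e$weight
  remaining <- if (!is.null(targets)) sum(targets != s) else -1L
  is_target <- logical(nv)
  if (!is.null(targets)) {
    is_target[targets] <- TRUE
    is_target[s] <- FALSE
  }
  repeat {
    d <- dist
    d[visited] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    visited[u] <- TRUE
    if (remaining >= 0L && is_target[u]) {
      remaining <- remaining - 1L
      if (remaining == 0L) break
    }
    if (ptr[u] == ptr[u + 1L]) next
    idx <- seq.int(ptr[u] + 1L, ptr[u + 1L])
    v <- all_ti[idx]
    nd <- dist[u] + all_w[idx]
    cur <- dist[v]
    tol <- 1e-9 * pmax(1, abs(nd))
    better <- !is.finite(cur) | nd < cur - tol
    tied <- is.finite(cur) & !better & abs(nd - cur) <= tol & !visited[v]
    if (any(better)) {
      w <- v[better]
      dist[w] <- nd[better]
      pred[w] <- u
      pred_edge[w] <- idx[better]
    }
    if (any(tied)) {
      for (j in which(tied)) {
        vv <- v[j]
        cand <- c(walk_pred(pred, u), vv)
        cur <- walk_pred(pred, vv)
        if (path_less(graph$vertices$vid[cand], graph$vertices$vid[cur])) {
          pred[vv] <- u
          pred_edge[vv] <- idx[j]
        }
      }
    }
  }
  list(dist = dist, pred = pred, pred_edge = pred_edge, source = s)
}

walk_pred <- function(pred, v) {
  out <- integer(0)
  while (!is.na(v)) {
    out <- c(v, out)
    v <- pred[v]
  }
  out
}

path_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Decompose a settled path into the route record. `imp_country` is the
# importing region's country, used for the pre-border transport cost split.
decompose_path <- function(graph, mode, sp, dest_vid) {
  vtab <- graph$vertices
  t <- match(dest_vid, vtab$vid)
  if (is.na(t) || !is.finite(sp$dist[t])) return(NULL)
  vseq <- walk_pred(sp$pred, t)
  eidx <- sp$pred_edge[vseq[-1]]
  e <- graph$adj[[mode]]$edges[eidx, , drop = FALSE]
  imp_country <- unname(graph$region_country[[sub("^r\\|", "", dest_vid)]])

  trcb <- 0
  if (nrow(e)) {
    from_layer <- vtab$layer[vseq[-length(vseq)]]
    cut <- NA_integer_
    for (i in seq_len(nrow(e))) {
      if (e$kind[i] == "travel" && e$country_a[i] != e$country_b[i]) {
        # entering the importer when the traversal's head node is there
        head_cty <- edge_head_country(graph, e, i)
        if (identical(head_cty, imp_country)) { cut <- i; break }
      }
    }
    if (!is.na(cut) && grepl("^maritime", e$mode[cut])) {
      # extend through the maritime exit transfer at the port of entry so
      # that the importer port's handling charge stays on the pre-border side
      k <- cut
      while (k < nrow(e) &&
             !(e$kind[k] == "transfer" && grepl("^maritime", e$mode[k]) &&
               grepl("^maritime", from_layer[k]))) {
        k <- k + 1L
      }
      if (k <= nrow(e) && e$kind[k] == "transfer") cut <- k
    }
    if (!is.na(cut)) trcb <- sum(e$money[seq_len(cut)])
  }

  tibble(
    mode = mode,
    path = paste(rle(vtab$name[vseq])$values, collapse = ">"),
    distance_km = sum(e$dist_km),
    travel_h = sum(e$time_h[e$kind == "travel"]),
    wait_h = sum(e$time_h[e$kind != "travel"]),
    transport_cost = sum(e$money),
    border_cost = sum(e$border),
    time_cost = sum(e$vfft_cost),
    gc = sum(e$weight),
    trcb = trcb,
    feasible = TRUE
  )
}

# Country at the head ('to') vertex of traversal row i; region vertices take
# their region's country, layer vertices their node's country via the edge
# endpoints recorded at build time.
edge_head_country <- function(graph, e, i) {
  vt <- graph$vertices
  ti <- e$ti[i]
  if (vt$layer[ti] == "r") {
    return(unname(graph$region_country[[vt$name[ti]]]))
  }
  # travel rows keep country_a/country_b aligned with the undirected edge;
  # match by node name
  if (vt$name[ti] == sub("^[^|]*\\|", "", e$to[i])) e$country_b[i] else e$country_a[i]
}

#' Least-generalized-cost route between two regions for one mode
#'
#' Runs Dijkstra on the mode's reachable subgraph (road-only, rail with road
#' access, or one maritime layer with land access legs) and decomposes the
#' optimum into distance, time, monetary transport cost, border compliance
#' cost, time-equivalent cost and the pre-border transport cost `trcb`.
#' Equal-cost ties resolve to the lexicographically smallest node sequence.
#' A disconnected pair yields a row with `feasible = FALSE`, not an error.
#'
#' @param graph A `glcm_graph` from [build_transport_graph()].
#' @param origin,destination Region ids.
#' @param mode One of the five mode labels.
#' @return One-row tibble describing the route.
#' @export
least_cost_route <- function(graph, origin, destination, mode = "road") {
  if (!mode %in% names(graph$adj)) {
    stop_glcm(sprintf("Unknown mode '%s'.", mode))
  }
  if (identical(origin, destination)) {
    return(tibble(origin = origin, destination = destination, mode = mode,
                  path = origin, distance_km = 0, travel_h = 0, wait_h = 0,
                  transport_cost = 0, border_cost = 0, time_cost = 0,
                  gc = 0, trcb = 0, feasible = TRUE))
  }
  sp <- dijkstra_sssp(graph, mode, paste0("r|", origin))
  out <- decompose_path(graph, mode, sp, paste0("r|", destination))
  if (is.null(out)) {
    return(tibble(origin = origin, destination = destination, mode = mode,
                  path = NA_character_, distance_km = NA_real_,
                  travel_h = NA_real_, wait_h = NA_real_,
                  transport_cost = NA_real_, border_cost = NA_real_,
                  time_cost = NA_real_, gc = Inf, trcb = NA_real_,
                  feasible = FALSE))
  }
  bind_cols(tibble(origin = origin, destination = destination), out)
}

#' Representative mode selection
#'
#' Among feasible candidate routes for the same region pair, picks the route
#' with the lowest generalized cost; exact ties are broken by the fixed mode
#' priority road < rail < maritime_drybulk < maritime_container <
#' maritime_generalcargo.
#'
#' @param routes Tibble of candidate routes (one per mode) with columns
#'   `gc`, `mode`, `feasible`.
#' @return The selected route row, or a zero-row tibble when no candidate is
#'   feasible (the pair is unservable).
#' @export
select_mode <- function(routes) {
  cand <- filter(routes, .data$feasible)
  if (nrow(cand) == 0) return(routes[0, , drop = FALSE])
  cand <- cand[order(cand$gc, match(cand$mode, GLCM_MODES)), , drop = FALSE]
  tol <- 1e-9 * max(1, abs(cand$gc[1]))
  tied <- which(cand$gc <= cand$gc[1] + tol)
  cand[tied[which.min(match(cand$mode[tied], GLCM_MODES))], , drop = FALSE]
}

#' Charged trade cost of a route
#'
#' The trade cost actually charged per tonne is the monetary transport cost
#' plus border compliance charges, `TC = TrC + B`. Time-equivalent (VFTT)
#' terms inform route choice only and are never charged.
#'
#' @param routes Route tibble with `transport_cost` and `border_cost`.
#' @return The same tibble with a `tc` column appended.
#' @export
trade_cost <- function(routes) {
  mutate(routes, tc = .data$transport_cost + .data$border_cost)
}

#' Compute representative routes for the region pairs implied by trade
#'
#' For every exporting region of each exporting country, runs one-to-all
#' Dijkstra per mode and keeps, for each destination region of that
#' exporter's importing partner countries, the representative
#' (lowest-generalized-cost) route. Pairs with no feasible route in any mode
#' are flagged unservable and reported via a warning.
#'
#' @param graph A `glcm_graph`.
#' @param bundle The bundle providing `regions` and `trade` (used to limit
#'   the pair universe); pass `pairs` to override.
#' @param pairs Optional tibble `origin, destination` of region pairs.
#' @return Tibble of representative routes (columns as in
#'   [least_cost_route()]), plus `tc`.
#' @export
compute_routes <- function(graph, bundle = NULL, pairs = NULL) {
  if (is.null(pairs)) {
    stopifnot(!is.null(bundle))
    rg <- bundle$regions
    pairs <- bundle$trade |>
      distinct(.data$exporter, .data$importer) |>
      left_join(select(rg, origin = "region_id", exporter = "country"),
                by = "exporter", relationship = "many-to-many") |>
      left_join(select(rg, destination = "region_id", importer = "country"),
                by = "importer", relationship = "many-to-many") |>
      distinct(.data$origin, .data$destination)
  }
  origins <- unique(pairs$origin)
  res <- map_dfr(origins, function(o) {
    dests <- unique(pairs$destination[pairs$origin == o])
    dvids <- paste0("r|", dests)
    tidx <- match(dvids, graph$vertices$vid)
    sps <- map(GLCM_MODES, function(m) {
      dijkstra_sssp(graph, m, paste0("r|", o), targets = tidx)
    })
    gc_mat <- matrix(unlist(map(sps, function(sp) sp$dist[tidx])),
                     nrow = length(dests))
    map_dfr(seq_along(dests), function(j) {
      g_row <- gc_mat[j, ]
      best <- suppressWarnings(min(g_row))
      if (!is.finite(best)) return(NULL)
      # columns follow the fixed mode priority order, so the first index
      # within tolerance of the minimum implements the documented tie-break
      mi <- which(g_row <= best + 1e-9 * max(1, abs(best)))[1]
      dec <- decompose_path(graph, GLCM_MODES[mi], sps[[mi]], dvids[j])
      bind_cols(tibble(origin = o, destination = dests[j]), dec)
    })
  })
  unserved <- anti_join(pairs, res, by = c("origin", "destination"))
  if (nrow(unserved)) {
    warn(sprintf("%d region pairs are unservable (no feasible route).",
                 nrow(unserved)))
  }
  trade_cost(res)
}
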