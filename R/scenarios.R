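#' Define an input-price shock scenario
#'
#' Static pass-through multipliers on landed-cost components. The default
#' scenario mimics 2022 conditions: +80% diesel for farm machinery, +50%
#' transport, +200% chemical inputs (fertilizer and pesticides). Labour,
#' machinery, storage and border compliance are untouched. Ad valorem
#' tariffs are recomputed on the shocked at-border value by default.
#'
#' @param diesel,transport,fertilizer,pesticides Multipliers (>= 0); 1 means
#'   unchanged.
#' @param recompute_tariffs Recompute tariffs on the shocked base?
#' @return A `glcm_shock_scenario` list.
#' @export
shock_scenario <- function(diesel = 1.8, transport = 1.5,
                           fertilizer = 3.0, pesticides = 3.0,
                           recompute_tariffs = TRUE) {
  m <- c(diesel = diesel, transport = transport,
         fertilizer = fertilizer, pesticides = pesticides)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop_glcm("Shock multipliers must be non-negative.")
  }
  structure(list(multipliers = m,
                 recompute_tariffs = isTRUE(recompute_tariffs)),
            class = "glcm_shock_scenario")
}

#' Apply an input-price shock to regional flows
#'
#' Scales the fertilizer, pesticides, farm-diesel and transport components
#' by the scenario multipliers, holding quantities and sourcing fixed (pure
#' cost pass-through: no supply, trade or demand adjustment). The pre-border
#' transport cost scales with the transport component; tariffs are
#' recomputed on the shocked at-border value when the scenario says so.
#'
#' @param flows Regional flow tibble from [allocate_flows()].
#' @param scenario A [shock_scenario()].
#' @return The shocked flow tibble with the same columns; totals re-summed.
#' @export
apply_shock <- function(flows, scenario = shock_scenario()) {
  stopifnot(inherits(scenario, "glcm_shock_scenario"))
  m <- scenario$multipliers
  out <- flows |>
    mutate(
      fertilizer = .data$fertilizer * m[["fertilizer"]],
      pesticides = .data$pesticides * m[["pesticides"]],
      diesel = .data$diesel * m[["diesel"]],
      transport = .data$transport * m[["transport"]],
      trcb = .data$trcb * m[["transport"]],
      production_total = .data$fertilizer + .data$pesticides + .data$labour +
        .data$machinery + .data$diesel
    )
  if (scenario$recompute_tariffs) {
    out <- mutate(out, tariff = import_tariff(
      .data$avit, .data$production_total, .data$storage, .data$border,
      .data$trcb))
  }
  mutate(out, total = .data$production_total + .data$storage +
           .data$transport + .data$border + .data$tariff)
}

#' Attribute a shock's landed-cost increase to its drivers
#'
#' Runs the combined scenario and the three single-driver scenarios
#' (transport, diesel, chemical = fertilizer + pesticides). Any interaction
#' mass (from tariffs levied on the shocked base) is allocated
#' proportionally across the three direct contributions, so driver shares
#' sum to one wherever the combined increase is positive.
#'
#' @param flows Regional flow tibble.
#' @param scenario A [shock_scenario()].
#' @param ... Grouping columns for the per-group deltas (default `ir`).
#' @return Tibble with baseline and shocked weighted landed costs, the
#'   combined increase `delta`, and `share_transport, share_diesel,
#'   share_chemical`.
#' @export
shock_attribution <- function(flows, scenario = shock_scenario(), ...) {
  m <- scenario$multipliers
  rt <- scenario$recompute_tariffs
  single <- list(
    transport = shock_scenario(diesel = 1, transport = m[["transport"]],
                               fertilizer = 1, pesticides = 1,
                               recompute_tariffs = rt),
    diesel = shock_scenario(diesel = m[["diesel"]], transport = 1,
                            fertilizer = 1, pesticides = 1,
                            recompute_tariffs = rt),
    chemical = shock_scenario(diesel = 1, transport = 1,
                              fertilizer = m[["fertilizer"]],
                              pesticides = m[["pesticides"]],
                              recompute_tariffs = rt)
  )
  grp_avg <- function(fl) weighted_average_lc(fl, ...)$wavg_lc
  base <- weighted_average_lc(flows, ...)
  combined <- grp_avg(apply_shock(flows, scenario))
  deltas <- map(single, function(s) grp_avg(apply_shock(flows, s)) - base$wavg_lc)
  direct <- deltas$transport + deltas$diesel + deltas$chemical
  delta <- combined - base$wavg_lc
  if (any(delta <= 0 & direct > 0)) {
    warn("Some groups have a non-positive combined increase; shares set to NA.")
  }
  scale <- if_else(direct > 0, delta / direct, NA_real_)
  base |>
    rename(baseline_lc = "wavg_lc") |>
    mutate(
      shocked_lc = combined,
      delta = delta,
      delta_pct = 100 * delta / .data$baseline_lc,
      share_transport = if_else(delta > 0,
                                deltas$transport * scale / delta, NA_real_),
      share_diesel = if_else(delta > 0,
                             deltas$diesel * scale / delta, NA_real_),
      share_chemical = if_else(delta > 0,
                               deltas$chemical * scale / delta, NA_real_)
    )
}

#' Fit the average-transport-cost distance regression
#'
#' Average transport cost per tonne-km falls with distance (port-hinterland
#' legs cost more per km than maritime line-haul, and long hauls are mostly
#' maritime). The benchmark is the log-log OLS fit
#' `ln(ATC) = beta0 + beta1 * ln(D)` per coarse mode (road, rail,
#' maritime), estimated at country-pair level with `ATC = TrC / D`.
#'
#' @param flows Regional flow (or route) tibble with `transport_cost` or
#'   `transport`, `distance_km`, `mode` and, when present, exporter/importer
#'   countries for the country-pair aggregation and `tonnes` for weighting
#'   the aggregation.
#' @return A `glcm_atc_fit`: list of per-mode `lm` fits plus a coefficient
#'   table.
#' @export
fit_atc_regression <- function(flows) {
  tr <- if ("transport" %in% names(flows)) flows$transport else flows$transport_cost
  df <- tibble(
    mode = relabel_modes_coarse(flows$mode),
    trc = tr,
    d = flows$distance_km,
    w = if ("tonnes" %in% names(flows)) flows$tonnes else 1,
    ec = if ("exporter" %in% names(flows)) flows$exporter else
      flows$origin %||% NA_character_,
    ic = if ("importer" %in% names(flows)) flows$importer else
      flows$destination %||% NA_character_
  ) |>
    filter(.data$d > 0, .data$trc > 0)
  pairs <- df |>
    group_by(.data$ec, .data$ic, .data$mode) |>
    summarise(trc = sum(.data$trc * .data$w) / sum(.data$w),
              d = sum(.data$d * .data$w) / sum(.data$w),
              .groups = "drop") |>
    mutate(atc = .data$trc / .data$d)
  fits <- list()
  for (mm in unique(pairs$mode)) {
    sub <- filter(pairs, .data$mode == mm)
    if (nrow(sub) < 3) next
    if (sd(log(sub$d)) == 0) {
      stop_glcm(sprintf("Degenerate distances for mode %s: regression undefined.", mm))
    }
    fits[[mm]] <- lm(log(atc) ~ log(d), data = sub)
  }
  if (!length(fits)) stop_glcm("No mode has enough country pairs (>= 3) to fit.")
  coefs <- map_dfr(names(fits), function(mm) {
    cf <- coef(fits[[mm]])
    # exact fits trigger a harmless precision warning in summary.lm
    se <- suppressWarnings(sqrt(diag(stats::vcov(fits[[mm]]))))
    tibble(mode = mm, beta0 = cf[[1]], beta1 = cf[[2]],
           se_beta0 = se[[1]], se_beta1 = se[[2]],
           sigma = stats::sigma(fits[[mm]]),
           n = nrow(fits[[mm]]$model))
  })
  structure(list(fits = fits, coefficients = coefs, pairs = pairs),
            class = "glcm_atc_fit")
}

#' @export
print.glcm_atc_fit <- function(x, ...) {
  cat("<glcm_atc_fit> ln(ATC) = beta0 + beta1 ln(D) per mode\n")
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Cost-reduction benchmarks
#'
#' Median benchmarks for tariff rates (per commodity) and per-tonne
#' production costs (per commodity), a global median for border compliance
#' costs, and the fitted ATC regression for transport. Medians are
#' unweighted across records with positive flow by default; set
#' `weighted = TRUE` for quantity-weighted medians.
#'
#' @param flows Regional flow tibble.
#' @param atc_fit Optional [fit_atc_regression()] result; fitted from
#'   `flows` when missing.
#' @param weighted Quantity-weight the medians?
#' @return A `glcm_benchmarks` list.
#' @export
reduction_benchmarks <- function(flows, atc_fit = NULL, weighted = FALSE) {
  med <- function(x, w) {
    if (weighted) weighted_quantile(x, w, 0.5) else median(x)
  }
  tariff_med <- flows |>
    group_by(.data$commodity) |>
    summarise(tariff_rate = med(.data$avit, .data$tonnes))
  prod_med <- flows |>
    group_by(.data$commodity) |>
    summarise(production = med(.data$production_total, .data$tonnes))
  border_med <- med(flows$border, flows$tonnes)
  atc_fit <- atc_fit %||% fit_atc_regression(flows)
  structure(list(tariff = tariff_med, production = prod_med,
                 border = border_med, atc = atc_fit),
            class = "glcm_benchmarks")
}

#' Apply cost-reduction benchmarks to regional flows
#'
#' Independently caps four cost groups: production costs and tariff rates
#' at their commodity medians, border compliance at the global median, and
#' transport at the distance-regression ATC times route distance. Values
#' already below a benchmark are untouched. Tariffs are recomputed on the
#' reduced at-border value, so every record's reduced total is at most its
#' baseline total.
#'
#' @param flows Regional flow tibble.
#' @param benchmarks A [reduction_benchmarks()] object (fitted from `flows`
#'   when missing).
#' @return The reduced flow tibble with per-record savings columns
#'   `save_production, save_border, save_tariff, save_transport` and
#'   `save_total`.
#' @export
benchmark_reduction <- function(flows, benchmarks = NULL) {
  bm <- benchmarks %||% reduction_benchmarks(flows)
  cf <- bm$atc$coefficients
  out <- flows |>
    left_join(rename(bm$tariff, tariff_cap = "tariff_rate"), by = "commodity") |>
    left_join(rename(bm$production, production_cap = "production"),
              by = "commodity") |>
    mutate(mode_coarse = relabel_modes_coarse(.data$mode)) |>
    left_join(select(cf, mode_coarse = "mode", "beta0", "beta1"),
              by = "mode_coarse") |>
    mutate(
      prod_scale = if_else(.data$production_total > .data$production_cap,
                           .data$production_cap / .data$production_total, 1),
      across(dplyr::all_of(GLCM_INPUTS), ~ .x * .data$prod_scale),
      production_red = .data$production_total * .data$prod_scale,
      border_red = pmin(.data$border, bm$border),
      atc_hat = if_else(is.na(.data$beta0) | .data$distance_km <= 0,
                        NA_real_,
                        exp(.data$beta0 + .data$beta1 * log(.data$distance_km))),
      transport_red = if_else(!is.na(.data$atc_hat),
                              pmin(.data$transport,
                                   .data$atc_hat * .data$distance_km),
                              .data$transport),
      trcb_red = if_else(.data$transport > 0,
                         .data$trcb * .data$transport_red / .data$transport,
                         .data$trcb),
      rate_red = pmin(.data$avit, .data$tariff_cap),
      tariff_red = import_tariff(.data$rate_red, .data$production_red,
                                 .data$storage, .data$border_red,
                                 .data$trcb_red),
      total_red = .data$production_red + .data$storage + .data$transport_red +
        .data$border_red + .data$tariff_red,
      save_production = .data$production_total - .data$production_red,
      save_border = .data$border - .data$border_red,
      save_transport = .data$transport - .data$transport_red,
      save_tariff = .data$tariff - .data$tariff_red,
      save_total = .data$total - .data$total_red
    )
  out |>
    mutate(
      production_total = .data$production_red,
      border = .data$border_red,
      transport = .data$transport_red,
      trcb = .data$trcb_red,
      avit = .data$rate_red,
      tariff = .data$tariff_red,
      total = .data$total_red
    ) |>
    select(-dplyr::any_of(c("production_red", "border_red", "transport_red",
                            "trcb_red", "rate_red", "tariff_red", "total_red",
                            "tariff_cap", "production_cap", "prod_scale",
                            "atc_hat", "beta0", "beta1", "mode_coarse")))
}

#' Per-region savings split for clustering
#'
#' Quantity-weighted per-tonne savings of the four reduction groups per
#' importing region, with shares of the total saving.
#'
#' @param reduced Output of [benchmark_reduction()].
#' @return Tibble per `ir` with savings in USD/t and `share_*` columns.
#' @export
reduction_summary <- function(reduced) {
  reduced |>
    group_by(.data$ir) |>
    summarise(
      across(c("save_production", "save_border", "save_tariff",
               "save_transport", "save_total"),
             ~ sum(.x * .data$tonnes) / sum(.data$tonnes)),
      .groups = "drop"
    ) |>
    mutate(
      share_production = if_else(.data$save_total > 0,
                                 .data$save_production / .data$save_total, 0),
      share_border = if_else(.data$save_total > 0,
                             .data$save_border / .data$save_total, 0),
      share_tariff = if_else(.data$save_total > 0,
                             .data$save_tariff / .data$save_total, 0),
      share_transport = if_else(.data$save_total > 0,
                                .data$save_transport / .data$save_total, 0)
    )
}

#' Cluster regions into cost-reduction strategy archetypes
#'
#' k-means on the four standardized savings-share features
#' (production, border, tariff, transport), with multiple restarts under a
#' fixed seed. Cluster labels are relabelled deterministically: clusters are
#' ordered by their dominant (largest-centroid) feature in component order,
#' then by descending dominant share, so the same data and seed always give
#' the same labels.
#'
#' @param reductions Per-region table from [reduction_summary()] (needs the
#'   four `share_*` columns; regions with zero total saving are dropped).
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts.
#' @return A `glcm_clusters` object: tibble of regions with `cluster`
#'   labels, plus `centers` and the `kmeans` fit as attributes.
#' @export
cluster_regions <- function(reductions, k = 6, seed = 1L, nstart = 25L) {
  feats <- c("share_production", "share_border", "share_tariff",
             "share_transport")
  df <- filter(reductions, .data$save_total > 0)
  if (nrow(df) < k) {
    stop_glcm(sprintf("Need at least k = %d regions with positive savings, got %d.",
                      k, nrow(df)))
  }
  x <- scale(as.matrix(df[feats]))
  x[, apply(x, 2, function(col) any(!is.finite(col)))] <- 0
  km <- with_rng(seed, kmeans(x, centers = k, nstart = nstart, iter.max = 100))
  centers_raw <- vapply(seq_len(k), function(cl) {
    colMeans(df[km$cluster == cl, feats, drop = FALSE])
  }, numeric(length(feats)))
  dom_feat <- apply(centers_raw, 2, which.max)
  dom_val <- apply(centers_raw, 2, max)
  ord <- order(dom_feat, -dom_val)
  relabel <- match(seq_len(k), ord)
  out <- df |>
    mutate(cluster = relabel[km$cluster])
  centers <- tibble(cluster = relabel[seq_len(k)],
                    as_tibble(t(centers_raw))) |>
    arrange(.data$cluster)
  structure(out, centers = centers, kmeans = km, k = k,
            class = c("glcm_clusters", class(out)))
}
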