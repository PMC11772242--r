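#' Quantity-weighted average landed cost
#'
#' `sum(q * LC) / sum(q)` over the flows in each group; lies between the
#' cheapest and most expensive supplier's landed cost.
#'
#' @param flows Regional flow tibble with `tonnes` and `total`.
#' @param ... Grouping columns (tidy-select style), e.g. `ir, commodity`.
#' @return Tibble of groups with `tonnes` and `wavg_lc` (USD/t). Groups with
#'   zero quantity are flagged with `NA` and a warning.
#' @export
weighted_average_lc <- function(flows, ...) {
  out <- flows |>
    group_by(...) |>
    summarise(
      wavg_lc = if (sum(.data$tonnes) > 0) {
        sum(.data$tonnes * .data$total) / sum(.data$tonnes)
      } else NA_real_,
      tonnes = sum(.data$tonnes),
      .groups = "drop"
    )
  if (any(is.na(out$wavg_lc))) {
    warn("Some groups have zero quantity; weighted average undefined (NA).")
  }
  out
}

#' Left-continuous weighted step quantile
#'
#' The smallest cost whose cumulative weight share reaches `p`. This step
#' definition (no interpolation) matches a cumulative supply-curve reading:
#' `p = 0` gives the minimum, `p = 1` the maximum.
#'
#' @param x Costs.
#' @param w Positive weights.
#' @param p Probabilities in `[0, 1]` (vectorised).
#' @return Quantile value(s) on the scale of `x`.
#' @export
#' @examples
#' weighted_quantile(1:5, rep(1, 5), 0.5) # 3
weighted_quantile <- function(x, w, p) {
  if (length(x) == 0) stop_glcm("Empty input to weighted_quantile().")
  if (length(w) != length(x) || any(w <= 0)) {
    stop_glcm("Weights must be positive and match `x` in length.")
  }
  if (any(p < 0 | p > 1)) stop_glcm("`p` must lie in [0, 1].")
  o <- order(x)
  x <- x[o]
  cum <- cumsum(w[o]) / sum(w)
  vapply(p, function(pp) {
    if (pp == 0) return(x[1])
    x[which(cum >= pp - 1e-12)[1]]
  }, numeric(1))
}

#' Supply cost curve
#'
#' Flows sorted by ascending landed cost with cumulative quantity shares,
#' one curve per group. Steep curves mean uniform sourcing costs; flat
#' curves mean strong inequality across suppliers.
#'
#' @param flows Regional flow tibble with `tonnes` and `total`.
#' @param ... Grouping columns.
#' @return Tibble with `total` (cost), `tonnes` and `cum_share` per group,
#'   class `glcm_supply_curve`.
#' @export
supply_cost_curve <- function(flows, ...) {
  out <- flows |>
    group_by(...) |>
    arrange(.data$total, .by_group = TRUE) |>
    mutate(cum_share = cumsum(.data$tonnes) / sum(.data$tonnes)) |>
    ungroup()
  class(out) <- c("glcm_supply_curve", class(out))
  out
}

#' Inequality of sourcing costs (ISC)
#'
#' `ISC = (Q90 - Q10) / Q50` of the quantity-weighted landed-cost
#' distribution across a geography's suppliers. Zero for uniform costs;
#' invariant under rescaling all costs. Values near or above one indicate
#' that the spread between the cheapest and most expensive decile of
#' sourcing matches the median cost itself.
#'
#' @param flows Regional flow tibble with `tonnes` and `total`.
#' @param ... Grouping columns (e.g. a geography label joined beforehand).
#' @return Tibble with `q10, q50, q90, isc` per group.
#' @export
isc <- function(flows, ...) {
  out <- flows |>
    group_by(...) |>
    summarise(
      q10 = weighted_quantile(.data$total, .data$tonnes, 0.1),
      q50 = weighted_quantile(.data$total, .data$tonnes, 0.5),
      q90 = weighted_quantile(.data$total, .data$tonnes, 0.9),
      .groups = "drop"
    )
  if (any(out$q50 <= 0)) stop_glcm("ISC undefined: median landed cost is zero.")
  mutate(out, isc = (.data$q90 - .data$q10) / .data$q50)
}

#' Nine-component breakdown shares of the landed cost
#'
#' Quantity-weighted mean of each cost component divided by the weighted
#' mean total; the nine shares sum to one per group.
#'
#' @param flows Regional flow tibble with `tonnes` and the nine components.
#' @param ... Grouping columns.
#' @return Long tibble with `component` and `share` per group, plus
#'   `dominant` flagging the group's largest share.
#' @export
breakdown_shares <- function(flows, ...) {
  out <- flows |>
    group_by(...) |>
    summarise(
      across(dplyr::all_of(GLCM_COMPONENTS),
             ~ sum(.x * .data$tonnes) / sum(.data$tonnes * .data$total)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(GLCM_COMPONENTS),
                        names_to = "component", values_to = "share")
  grp <- setdiff(names(out), c("component", "share"))
  out |>
    group_by(across(dplyr::all_of(grp))) |>
    mutate(dominant = .data$share == max(.data$share)) |>
    ungroup()
}

#' Freight statistics
#'
#' Total tonne-kilometres, the quantity-weighted mean field-to-customer
#' distance, and mode shares under both tonnes and tonne-km weightings
#' (each set of shares partitions to one).
#'
#' @param flows Regional flow tibble with `tonnes`, `distance_km`, `mode`.
#' @return List with `tonne_km_total`, `mean_distance_km`, and a
#'   `mode_shares` tibble (`mode, share_tonnes, share_tonne_km`).
#' @export
freight_statistics <- function(flows) {
  tkm <- sum(flows$tonnes * flows$distance_km)
  shares <- flows |>
    group_by(.data$mode) |>
    summarise(t = sum(.data$tonnes),
              tkm = sum(.data$tonnes * .data$distance_km)) |>
    mutate(share_tonnes = .data$t / sum(.data$t),
           share_tonne_km = .data$tkm / sum(.data$tkm)) |>
    select("mode", "share_tonnes", "share_tonne_km")
  list(
    tonne_km_total = tkm,
    mean_distance_km = tkm / sum(flows$tonnes),
    mode_shares = shares
  )
}
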