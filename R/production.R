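#' Yield correction factor for per-tonne production costs
#'
#' Per-hectare input costs do not scale linearly into per-tonne costs:
#' high-yielding regions tend to spend more per hectare on inputs than
#' low-yielding regions of the same country. The default correction is a
#' power law anchored at the country median yield,
#' `CF = (yield / country_median_yield)^gamma`, so `CF = 1` at the median
#' and `CF` rises monotonically with regional yield. `gamma = 0` switches
#' the correction off. A user-supplied CF table can override this form in
#' [production_costs()].
#'
#' @param region_yield Regional commodity yield, tonnes per hectare (> 0).
#' @param country_median_yield Country-wide median yield, t/ha (> 0).
#' @param gamma Exponent in `[0, 1]`; default 0.5.
#' @return Dimensionless correction factor, vectorised over inputs.
#' @export
#' @examples
#' correction_factor(4, 2, gamma = 1) # 2
#' correction_factor(4, 4, gamma = 0.73) # 1 at the anchor
correction_factor <- function(region_yield, country_median_yield, gamma = 0.5) {
  if (any(!is.finite(region_yield)) || any(region_yield <= 0) ||
      any(!is.finite(country_median_yield)) || any(country_median_yield <= 0)) {
    stop_glcm("Yields must be positive and finite.")
  }
  if (any(gamma < 0) || any(gamma > 1)) {
    stop_glcm("`gamma` must lie in [0, 1].")
  }
  (region_yield / country_median_yield)^gamma
}

#' Convert per-hectare input costs to per-tonne costs
#'
#' Divides each of the five per-hectare input components by the regional
#' yield and applies the yield correction factor:
#' `component_usd_t = cf * component_usd_ha / yield`.
#'
#' @param costs A one-row data frame (or named list) with the five components
#'   `fertilizer, pesticides, labour, machinery, diesel` in USD/ha.
#' @param region_yield Regional yield, t/ha (> 0).
#' @param cf Correction factor (> 0).
#' @param region,commodity Optional identifiers used in error messages.
#' @return Tibble with the five components in USD/t plus their `total`.
#' @export
per_tonne_cost <- function(costs, region_yield, cf = 1,
                           region = NA_character_, commodity = NA_character_) {
  if (!is.finite(region_yield) || region_yield <= 0) {
    stop_glcm(sprintf(
      "Non-positive yield for region %s, commodity %s.", region, commodity))
  }
  if (!is.finite(cf) || cf <= 0) stop_glcm("`cf` must be positive.")
  vals <- vapply(GLCM_INPUTS, function(k) as.numeric(costs[[k]]), numeric(1))
  check_nonnegative(vals, "per-hectare cost components")
  out <- as_tibble(as.list(cf * vals / region_yield))
  out$total <- sum(cf * vals / region_yield)
  out
}

#' Pre-export storage and upcountry handling cost
#'
#' A flat per-tonne charge incurred before goods leave the exporting
#' country, applied uniformly across countries and commodities. Indicative
#' values for major exporters span roughly 11-31 USD/t; the default is
#' 20 USD/t.
#'
#' @param country,commodity Identifiers (accepted for interface symmetry;
#'   the default charge is uniform).
#' @param storage_usd_t Configured per-tonne storage cost (>= 0).
#' @return Storage cost in USD/t.
#' @export
storage_cost <- function(country = NULL, commodity = NULL, storage_usd_t = 20) {
  if (!is.numeric(storage_usd_t) || any(storage_usd_t < 0)) {
    stop_glcm("`storage_usd_t` must be non-negative.")
  }
  storage_usd_t
}

#' Regional per-tonne production cost table
#'
#' Expands country-by-commodity per-hectare input costs into region-by-
#' commodity per-tonne cost vectors using regional yields, the yield
#' correction factor and the storage charge. Regions without production of a
#' commodity get no row.
#'
#' @param bundle A `glcm_bundle` (or a list providing `regions`,
#'   `production`, `input_costs`).
#' @param gamma Correction-factor exponent, see [correction_factor()].
#' @param storage_usd_t Uniform storage cost, USD/t.
#' @param cf_table Optional tibble `region_id, commodity, cf` overriding the
#'   built-in correction-factor form.
#' @return Tibble `region_id, country, commodity`, the five input components
#'   (USD/t), `storage`, `production_total`, `yield_used`, `cf_used`.
#' @export
#' @examples
#' b <- generate_world(world_config(n_countries = 3, seed = 2))
#' pc <- production_costs(b)
#' head(pc)
production_costs <- function(bundle, gamma = 0.5, storage_usd_t = 20,
                             cf_table = NULL) {
  storage_cost(storage_usd_t = storage_usd_t)
  prod <- bundle$production |>
    left_join(select(bundle$regions, "region_id", "country"),
              by = "region_id")
  med <- prod |>
    filter(.data$production_t > 0) |>
    group_by(.data$country, .data$commodity) |>
    summarise(median_yield = median(.data$yield_t_ha), .groups = "drop")
  out <- prod |>
    left_join(med, by = c("country", "commodity")) |>
    mutate(cf_used = correction_factor(.data$yield_t_ha, .data$median_yield,
                                       gamma))
  if (!is.null(cf_table)) {
    out <- out |>
      left_join(rename(cf_table, cf_override = "cf"),
                by = c("region_id", "commodity")) |>
      mutate(cf_used = dplyr::coalesce(.data$cf_override, .data$cf_used)) |>
      select(-"cf_override")
  }
  bad <- out$yield_t_ha <= 0
  if (any(bad)) {
    stop_glcm(sprintf("Non-positive yield for region %s, commodity %s.",
                      out$region_id[which(bad)[1]],
                      out$commodity[which(bad)[1]]))
  }
  out |>
    left_join(bundle$input_costs, by = c("country", "commodity")) |>
    mutate(
      across(dplyr::all_of(GLCM_INPUTS),
             ~ .data$cf_used * .x / .data$yield_t_ha),
      storage = storage_usd_t,
      production_total = .data$fertilizer + .data$pesticides + .data$labour +
        .data$machinery + .data$diesel,
      yield_used = .data$yield_t_ha
    ) |>
    select("region_id", "country", "commodity", dplyr::all_of(GLCM_INPUTS),
           "storage", "production_total", "yield_used", "cf_used")
}
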