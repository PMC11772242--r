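#' Regional import demand from country imports
#'
#' Splits a country's commodity imports across its regions in proportion to
#' population: `C_r = I_c * Pop_r / sum(Pop_r)`, so regional demands sum
#' back to the country total.
#'
#' @param trade Bilateral trade tibble `exporter, importer, commodity,
#'   tonnes` (or a country-level import tibble `country, commodity,
#'   import_t`).
#' @param regions Region tibble `region_id, country, population`.
#' @return Tibble `region_id, country, commodity, import_t`.
#' @export
regional_import_demand <- function(trade, regions) {
  imports <- if (all(c("exporter", "importer") %in% names(trade))) {
    trade |>
      group_by(country = .data$importer, .data$commodity) |>
      summarise(import_t = sum(.data$tonnes), .groups = "drop")
  } else {
    trade
  }
  pop <- regions |>
    group_by(.data$country) |>
    mutate(pop_share = .data$population / sum(.data$population)) |>
    ungroup()
  if (any(!is.finite(pop$pop_share))) {
    stop_glcm("Zero total population in a country with positive imports.")
  }
  imports |>
    inner_join(select(pop, "region_id", "country", "pop_share"),
               by = "country", relationship = "many-to-many") |>
    mutate(import_t = .data$import_t * .data$pop_share) |>
    select("region_id", "country", "commodity", "import_t")
}

#' Ad valorem import tariff on the at-border value
#'
#' Tariffs are charged on the landed cost at the port of entry: production
#' cost, storage, border compliance charges and the pre-border transport
#' cost. `IT = avit * (PC + ST + B + TrCB)`.
#'
#' @param avit Ad valorem tariff rate (>= 0).
#' @param pc Per-tonne production cost, USD/t.
#' @param st Storage cost, USD/t.
#' @param b Border compliance cost, USD/t.
#' @param trcb Pre-border transport cost, USD/t.
#' @return Tariff in USD/t (vectorised).
#' @export
#' @examples
#' import_tariff(0.10, 100, 20, 5, 75) # 20
import_tariff <- function(avit, pc, st, b, trcb) {
  check_nonnegative(avit, "avit")
  avit * (pc + st + b + trcb)
}

#' Landed-cost records for all routed region pairs
#'
#' Assembles the nine-component landed cost for every exporter-region to
#' importer-region pair with a feasible representative route:
#' five production components, storage, transport (`TrC`), border
#' compliance (`B`) and the import tariff charged on the at-border value.
#' `total` is the component sum. Pairs without a feasible route yield no
#' record.
#'
#' @param pc Production cost table from [production_costs()].
#' @param routes Representative route table from [compute_routes()].
#' @param tariffs Tariff tibble `exporter, importer, commodity,
#'   ad_valorem_rate` (country level); missing pairs default to rate 0.
#' @param regions Region tibble (maps regions to countries).
#' @param trade Bilateral trade tibble restricting the country-pair and
#'   commodity universe.
#' @return Tibble with identifiers, the nine components, `total` and the
#'   carried route quantities (`mode`, `distance_km`, `trcb`, `avit`).
#' @export
landed_costs <- function(pc, routes, tariffs, regions, trade) {
  rcty <- setNames(regions$country, regions$region_id)
  pairs <- trade |>
    distinct(.data$exporter, .data$importer, .data$commodity)

  rt <- routes |>
    filter(.data$feasible) |>
    mutate(ec = unname(rcty[.data$origin]), ic = unname(rcty[.data$destination]))

  out <- pairs |>
    inner_join(rt, by = c(exporter = "ec", importer = "ic"),
               relationship = "many-to-many") |>
    inner_join(
      select(pc, er = "region_id", "commodity",
             dplyr::all_of(GLCM_INPUTS), "storage", "production_total"),
      by = c(origin = "er", "commodity")
    ) |>
    left_join(tariffs, by = c("exporter", "importer", "commodity")) |>
    mutate(
      avit = dplyr::coalesce(.data$ad_valorem_rate, 0),
      transport = .data$transport_cost,
      border = .data$border_cost,
      tariff = import_tariff(.data$avit, .data$production_total,
                             .data$storage, .data$border, .data$trcb),
      total = .data$production_total + .data$storage + .data$transport +
        .data$border + .data$tariff
    )
  out |>
    select(er = "origin", ir = "destination", "exporter", "importer",
           "commodity", dplyr::all_of(GLCM_COMPONENTS), "total",
           "production_total", "mode", "distance_km", "trcb", "avit")
}

#' Intervening production mass for a radiation pair
#'
#' For each exporter-region/importer-region pair, the normalized production
#' located in other regions of the same exporting country whose landed cost
#' to the importer is strictly lower than this pair's. The exporting region
#' itself is excluded; ties do not intervene.
#'
#' @param lc Landed-cost table from [landed_costs()], optionally already
#'   carrying a `p_bar` column.
#' @param weights Optional tibble `region_id, commodity, p_bar` of
#'   normalized production weights (see [radiation_weights()]), joined onto
#'   `lc` when it lacks `p_bar`.
#' @return `lc` with a `p_intervening` column.
#' @export
intervening_production <- function(lc, weights = NULL) {
  if (!is.null(weights)) {
    lc <- lc |>
      select(-dplyr::any_of("p_bar")) |>
      left_join(rename(weights, er = "region_id"), by = c("er", "commodity"))
  }
  if (!"p_bar" %in% names(lc)) {
    stop_glcm("`lc` needs a `p_bar` column or `weights` must be supplied.")
  }
  lc |>
    group_by(.data$exporter, .data$ir, .data$commodity) |>
    mutate(p_intervening = intervening_mass(.data$total,
                                            dplyr::coalesce(.data$p_bar, 0))) |>
    ungroup()
}

# Mass of strictly cheaper same-country sources for each record; the record
# itself and exact ties never intervene.
intervening_mass <- function(total, p_bar) {
  vapply(seq_along(total),
         function(i) sum(p_bar[total < total[i]]),
         numeric(1))
}

#' Country-normalized radiation weights
#'
#' Production weights normalize each exporting region's commodity production
#' by its country total; demand weights normalize each importing region's
#' import demand by its country total, keeping origin and intervening masses
#' commensurate.
#'
#' @param production Regional production tibble with `region_id, commodity,
#'   production_t`.
#' @param demand Regional demand tibble from [regional_import_demand()].
#' @param regions Region tibble.
#' @return List with `p_bar` (`region_id, commodity, p_bar`) and `c_bar`
#'   (`region_id, commodity, c_bar`).
#' @export
radiation_weights <- function(production, demand, regions) {
  p_bar <- production |>
    left_join(select(regions, "region_id", "country"), by = "region_id") |>
    group_by(.data$country, .data$commodity) |>
    mutate(p_bar = .data$production_t / sum(.data$production_t)) |>
    ungroup() |>
    select("region_id", "commodity", "p_bar")
  c_bar <- demand |>
    group_by(.data$country, .data$commodity) |>
    mutate(c_bar = .data$import_t / sum(.data$import_t)) |>
    ungroup() |>
    select("region_id", "commodity", "c_bar")
  list(p_bar = p_bar, c_bar = c_bar)
}

#' Radiation-model allocation of one bilateral flow
#'
#' Parameter-free spatial-interaction allocation: the utility of sourcing
#' from exporter region er for importer region ir is
#' `u = c_bar * p_bar / ((c_bar + p_int) * (c_bar + p_bar + p_int))`, with
#' `p_int` the intervening production mass of cheaper same-country sources.
#' Utilities are rescaled proportionally so the allocated flows sum exactly
#' to the bilateral total.
#'
#' @param total Bilateral flow to allocate, tonnes.
#' @param pairs Tibble with columns `c_bar`, `p_bar`, `p_intervening` (one
#'   row per er-ir pair of the bilateral relation).
#' @return `pairs` with `utility` and allocated `tonnes`.
#' @export
radiation_allocate <- function(total, pairs) {
  u <- pairs$c_bar * pairs$p_bar /
    ((pairs$c_bar + pairs$p_intervening) *
       (pairs$c_bar + pairs$p_bar + pairs$p_intervening))
  u[!is.finite(u)] <- 0
  if (sum(u) <= 0) {
    stop_glcm("All radiation utilities are zero for a bilateral relation.")
  }
  alloc <- total * u / sum(u)
  mutate(pairs, utility = u, tonnes = alloc)
}

#' Downscale all bilateral flows to region pairs
#'
#' Runs the radiation allocation for every bilateral relation with at least
#' one feasible routed pair, attaching the landed-cost record to each
#' regional flow. Relations with no feasible pair are dropped with a
#' warning; the attribute `completeness` records the allocated share of
#' bilateral tonnage.
#'
#' @param bundle A `glcm_bundle`.
#' @param lc Landed-cost table from [landed_costs()].
#' @return Tibble of regional flows: identifiers, `tonnes`, the nine cost
#'   components and `total`, with attribute `completeness`.
#' @export
allocate_flows <- function(bundle, lc) {
  demand <- regional_import_demand(bundle$trade, bundle$regions)
  w <- radiation_weights(bundle$production, demand, bundle$regions)
  lcw <- lc |>
    left_join(rename(w$p_bar, er = "region_id"), by = c("er", "commodity")) |>
    left_join(rename(w$c_bar, ir = "region_id"), by = c("ir", "commodity")) |>
    mutate(p_bar = dplyr::coalesce(.data$p_bar, 0),
           c_bar = dplyr::coalesce(.data$c_bar, 0)) |>
    intervening_production()

  rel <- bundle$trade |> filter(.data$tonnes > 0)
  out <- map_dfr(seq_len(nrow(rel)), function(i) {
    sub <- lcw |>
      filter(.data$exporter == rel$exporter[i],
             .data$importer == rel$importer[i],
             .data$commodity == rel$commodity[i])
    if (nrow(sub) == 0 || sum(sub$c_bar * sub$p_bar) <= 0) return(NULL)
    radiation_allocate(rel$tonnes[i], sub) |>
      filter(.data$tonnes > 0)
  })
  done <- out |>
    group_by(.data$exporter, .data$importer, .data$commodity) |>
    summarise(tonnes = sum(.data$tonnes), .groups = "drop")
  alloc <- sum(done$tonnes)
  tot <- sum(rel$tonnes)
  if (alloc < tot * (1 - 1e-9)) {
    warn(sprintf(
      "%d of %d bilateral relations dropped (no routable/weighted pair); %.1f%% of tonnage allocated.",
      nrow(rel) - nrow(done), nrow(rel), 100 * alloc / tot))
  }
  attr(out, "completeness") <- alloc / tot
  out
}
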