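# minimal hand-built flow record factory
toy_flow <- function(fertilizer = 0, pesticides = 0, labour = 0,
                     machinery = 0, diesel = 0, storage = 0, transport = 0,
                     border = 0, avit = 0, trcb = 0, tonnes = 1,
                     ir = "I_R1", er = "E_R1", commodity = "wheat",
                     mode = "road", distance_km = 100) {
  production_total <- fertilizer + pesticides + labour + machinery + diesel
  tariff <- avit * (production_total + storage + border + trcb)
  tibble::tibble(
    er = er, ir = ir, exporter = sub("_R.*$", "", er),
    importer = sub("_R.*$", "", ir), commodity = commodity,
    fertilizer = fertilizer, pesticides = pesticides, labour = labour,
    machinery = machinery, diesel = diesel, storage = storage,
    transport = transport, border = border, tariff = tariff,
    production_total = production_total,
    total = production_total + storage + transport + border + tariff,
    mode = mode, distance_km = distance_km, trcb = trcb, avit = avit,
    tonnes = tonnes)
}

test_that("identity scenario is a no-op on every record", {
  w <- tiny_flows(seed = 11)
  id <- shock_scenario(diesel = 1, transport = 1, fertilizer = 1,
                       pesticides = 1)
  out <- apply_shock(w$flows, id)
  expect_equal(out$total, w$flows$total, tolerance = 1e-12)
  expect_equal(out$tariff, w$flows$tariff, tolerance = 1e-12)
})

test_that("the default scenario carries the 2022-style multipliers", {
  s <- shock_scenario()
  expect_equal(unname(s$multipliers),
               c(1.8, 1.5, 3.0, 3.0))
  expect_equal(names(s$multipliers),
               c("diesel", "transport", "fertilizer", "pesticides"))
  expect_error(shock_scenario(diesel = -1), "non-negative",
               class = "glcm_error")
})

test_that("shock on the stated toy record raises the cost by 128 USD/t", {
  fl <- toy_flow(fertilizer = 50, diesel = 10, transport = 40)
  out <- apply_shock(fl, shock_scenario())
  expect_equal(out$total - fl$total, 50 * 2 + 10 * 0.8 + 40 * 0.5)
  expect_equal(out$total - fl$total, 128)
})

test_that("shock delta is non-decreasing in every multiplier", {
  fl <- toy_flow(fertilizer = 50, pesticides = 20, diesel = 10,
                 transport = 40, border = 5, storage = 20, avit = 0.1,
                 trcb = 30)
  base <- apply_shock(fl, shock_scenario())$total
  for (arg in c("diesel", "transport", "fertilizer", "pesticides")) {
    args <- list(diesel = 1.8, transport = 1.5, fertilizer = 3,
                 pesticides = 3)
    args[[arg]] <- args[[arg]] + 0.5
    up <- apply_shock(fl, do.call(shock_scenario, args))$total
    expect_gte(up, base)
  }
})

test_that("without tariffs single-driver deltas sum exactly to the combined", {
  w <- tiny_flows(seed = 11)
  fl <- dplyr::mutate(w$flows, avit = 0,
                      tariff = 0,
                      total = production_total + storage + transport + border)
  att <- shock_attribution(fl, shock_scenario(), ir)
  shares <- att$share_transport + att$share_diesel + att$share_chemical
  expect_equal(shares, rep(1, nrow(att)), tolerance = 1e-9)
  # linearity check done directly
  s <- shock_scenario()
  combined <- apply_shock(fl, s)$total - fl$total
  singles <- Reduce(`+`, list(
    apply_shock(fl, shock_scenario(1.8, 1, 1, 1))$total - fl$total,
    apply_shock(fl, shock_scenario(1, 1.5, 1, 1))$total - fl$total,
    apply_shock(fl, shock_scenario(1, 1, 3, 3))$total - fl$total))
  expect_equal(combined, singles, tolerance = 1e-9)
})

test_that("tariff interaction is allocated so shares still sum to one", {
  fl <- toy_flow(fertilizer = 50, pesticides = 10, diesel = 10,
                 transport = 40, storage = 20, border = 5, avit = 0.1,
                 trcb = 30)
  att <- shock_attribution(fl, shock_scenario(), ir)
  expect_equal(att$share_transport + att$share_diesel + att$share_chemical, 1,
               tolerance = 1e-12)
  # brute-force: deltas of single-driver runs rescaled to the combined delta
  s_each <- list(
    transport = shock_scenario(1, 1.5, 1, 1),
    diesel = shock_scenario(1.8, 1, 1, 1),
    chemical = shock_scenario(1, 1, 3, 3))
  d_each <- vapply(s_each, function(s) apply_shock(fl, s)$total - fl$total,
                   numeric(1))
  d_comb <- apply_shock(fl, shock_scenario())$total - fl$total
  expect_equal(att$share_transport,
               unname(d_each["transport"] / sum(d_each)), tolerance = 1e-12)
  expect_equal(att$delta, d_comb)
})

test_that("only-transport shocks attribute fully to transport", {
  fl <- toy_flow(fertilizer = 50, diesel = 10, transport = 40)
  att <- shock_attribution(fl, shock_scenario(diesel = 1, transport = 2,
                                              fertilizer = 1, pesticides = 1),
                           ir)
  expect_equal(att$share_transport, 1)
  expect_equal(att$share_diesel, 0)
})

test_that("ATC regression recovers planted coefficients exactly without noise", {
  withr::local_seed(42)
  d <- exp(runif(40, 4, 9))
  fl <- tibble::tibble(
    exporter = sprintf("E%02d", 1:40), importer = "I",
    mode = "road", distance_km = d,
    transport = exp(1 - 0.4 * log(d)) * d,  # ATC = exp(beta0) * d^beta1
    tonnes = 1)
  fit <- fit_atc_regression(fl)
  expect_equal(fit$coefficients$beta0, 1, tolerance = 1e-10)
  expect_equal(fit$coefficients$beta1, -0.4, tolerance = 1e-10)
})

test_that("ATC regression recovers coefficients within 3 SE under noise", {
  withr::local_seed(7)
  n <- 500
  d <- exp(runif(n, 4, 9))
  atc <- exp(0.5 - 0.3 * log(d) + rnorm(n, 0, 0.1))
  fl <- tibble::tibble(
    exporter = sprintf("E%03d", 1:n), importer = "I",
    mode = "rail", distance_km = d, transport = atc * d, tonnes = 1)
  fit <- fit_atc_regression(fl)
  cf <- fit$coefficients
  expect_lt(abs(cf$beta0 - 0.5), 3 * cf$se_beta0)
  expect_lt(abs(cf$beta1 + 0.3), 3 * cf$se_beta1)
  # tidy/glance accessors agree with the fit
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "log(d)"], cf$beta1)
  expect_equal(glance(fit)$nobs, n)
})

test_that("falling per-km costs yield a negative distance elasticity", {
  d <- c(100, 500, 1000, 5000, 10000)
  fl <- tibble::tibble(
    exporter = sprintf("E%d", seq_along(d)), importer = "I",
    mode = "maritime_drybulk", distance_km = d,
    transport = 20 + 0.01 * d,  # concave in distance: ATC falls
    tonnes = 1)
  fit <- fit_atc_regression(fl)
  expect_lt(fit$coefficients$beta1, 0)
  expect_equal(fit$coefficients$mode, "maritime")
})

test_that("degenerate equal distances abort the regression", {
  fl <- tibble::tibble(exporter = c("A", "B", "C"), importer = "I",
                       mode = "road", distance_km = 100,
                       transport = c(5, 6, 7), tonnes = 1)
  expect_error(fit_atc_regression(fl), "Degenerate", class = "glcm_error")
})

test_that("benchmark reduction caps components at medians and never raises totals", {
  w <- tiny_flows(seed = 11)
  red <- benchmark_reduction(w$flows)
  expect_true(all(red$save_total >= -1e-9))
  expect_true(all(red$total <= w$flows$total + 1e-9))
  # records below every benchmark are untouched
  bm <- reduction_benchmarks(w$flows)
  joined <- dplyr::left_join(
    w$flows, dplyr::rename(bm$tariff, cap = tariff_rate), by = "commodity")
  safe <- joined$avit <= joined$cap
  expect_equal(red$avit[safe], w$flows$avit[safe])
  # savings decomposition sums to the total saving (tariff absorbs the
  # base interaction)
  expect_equal(red$save_total,
               red$save_production + red$save_border + red$save_transport +
                 red$save_tariff, tolerance = 1e-9)
})

test_that("a record above the tariff median saves the rate gap times the base", {
  fl <- dplyr::bind_rows(
    toy_flow(fertilizer = 100, storage = 20, transport = 30, trcb = 20,
             avit = 0.30, er = "E1_R1", ir = "I1_R1", distance_km = 100),
    toy_flow(fertilizer = 100, storage = 20, transport = 32, trcb = 20,
             avit = 0.10, er = "E2_R1", ir = "I2_R1", distance_km = 200),
    toy_flow(fertilizer = 100, storage = 20, transport = 34, trcb = 20,
             avit = 0.05, er = "E3_R1", ir = "I3_R1", distance_km = 400))
  red <- benchmark_reduction(fl)
  # medians: tariff 0.10; record 1 capped from 0.30
  r1 <- red[red$er == "E1_R1", ]
  expect_equal(r1$avit, 0.10)
  base1 <- r1$production_total + r1$storage + r1$border + r1$trcb
  expect_equal(r1$save_tariff,
               0.30 * (fl$production_total[1] + fl$storage[1] + fl$border[1] +
                         fl$trcb[1]) - 0.10 * base1)
  # all-at-benchmark world: equal rates and production, transport exactly on
  # the fitted power law -> nothing changes anywhere
  fl2 <- dplyr::mutate(fl, avit = 0.05,
                       transport = exp(0.5 - 0.3 * log(distance_km)) *
                         distance_km,
                       trcb = transport / 2,
                       tariff = avit * (production_total + storage + border +
                                          trcb),
                       total = production_total + storage + transport +
                         border + tariff)
  same <- benchmark_reduction(fl2)
  expect_equal(same$save_total, rep(0, 3), tolerance = 1e-9)
  expect_equal(same$save_tariff, rep(0, 3), tolerance = 1e-9)
})

test_that("k-means recovers planted archetypes and is deterministic", {
  withr::local_seed(31)
  arch <- list(
    c(0.85, 0.05, 0.05, 0.05), c(0.05, 0.85, 0.05, 0.05),
    c(0.05, 0.05, 0.85, 0.05), c(0.05, 0.05, 0.05, 0.85))
  rows <- purrr::map_dfr(seq_along(arch), function(i) {
    sh <- purrr::map_dfr(1:12, function(j) {
      v <- pmax(arch[[i]] + rnorm(4, 0, 0.01), 0)
      v <- v / sum(v)
      tibble::tibble(share_production = v[1], share_border = v[2],
                     share_tariff = v[3], share_transport = v[4])
    })
    dplyr::mutate(sh, ir = sprintf("R%d_%d", i, dplyr::row_number()),
                  save_total = 10, truth = i)
  })
  cl <- cluster_regions(rows, k = 4, seed = 5)
  tab <- table(cl$truth, cl$cluster)
  # each planted archetype maps to exactly one recovered cluster
  expect_true(all(apply(tab > 0, 1, sum) == 1))
  expect_true(all(apply(tab > 0, 2, sum) == 1))
  cl2 <- cluster_regions(rows, k = 4, seed = 5)
  expect_identical(cl$cluster, cl2$cluster)
  # labels are ordered by dominant feature
  expect_equal(sort(unique(cl$cluster)), 1:4)

  one <- cluster_regions(rows, k = 1, seed = 9)
  expect_true(all(one$cluster == 1))
  expect_error(cluster_regions(rows[1:3, ], k = 4, seed = 1), "at least",
               class = "glcm_error")
})
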