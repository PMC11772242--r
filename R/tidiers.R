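#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the ATC distance regression
#'
#' One row per mode and coefficient, broom style.
#'
#' @param x A `glcm_atc_fit`.
#' @param ... Unused.
#' @return Tibble with `mode, term, estimate, std.error`.
#' @export
tidy.glcm_atc_fit <- function(x, ...) {
  x$coefficients |>
    tidyr::pivot_longer(c("beta0", "beta1"), names_to = "term",
                        values_to = "estimate") |>
    mutate(std.error = if_else(.data$term == "beta0",
                               .data$se_beta0, .data$se_beta1),
           term = if_else(.data$term == "beta0", "(Intercept)", "log(d)")) |>
    select("mode", "term", "estimate", "std.error")
}

#' Glance at the ATC distance regression
#'
#' @param x A `glcm_atc_fit`.
#' @param ... Unused.
#' @return One row per mode with `sigma`, `r.squared` and `nobs`.
#' @export
glance.glcm_atc_fit <- function(x, ...) {
  map_dfr(names(x$fits), function(mm) {
    s <- summary(x$fits[[mm]])
    tibble(mode = mm, r.squared = s$r.squared, sigma = s$sigma,
           nobs = nrow(x$fits[[mm]]$model))
  })
}

#' Tidy cluster assignments
#'
#' @param x A `glcm_clusters` object.
#' @param ... Unused.
#' @return Tibble `ir, cluster` plus the four share features.
#' @export
tidy.glcm_clusters <- function(x, ...) {
  as_tibble(x) |>
    select("ir", "cluster", dplyr::starts_with("share_"))
}

#' Glance at a clustering
#'
#' @param x A `glcm_clusters` object.
#' @param ... Unused.
#' @return One-row tibble with `k`, `tot.withinss`, `betweenss` and `nobs`.
#' @export
glance.glcm_clusters <- function(x, ...) {
  km <- attr(x, "kmeans")
  tibble(k = attr(x, "k"), tot.withinss = km$tot.withinss,
         betweenss = km$betweenss, nobs = length(km$cluster))
}
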