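#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join bind_rows bind_cols distinct rename n
#'   across pull slice row_number first if_else count
#' @importFrom purrr map map_dfr map_dbl map_chr pmap walk imap
#' @importFrom stats median quantile lm coef kmeans rlnorm runif rnorm setNames
#'   predict sd
#' @importFrom utils head tail
NULL

# Transport mode labels, in fixed priority order used for tie-breaking.
GLCM_MODES <- c("road", "rail", "maritime_drybulk", "maritime_container",
                "maritime_generalcargo")

# Five per-hectare farm input components.
GLCM_INPUTS <- c("fertilizer", "pesticides", "labour", "machinery", "diesel")

# Nine landed-cost components.
GLCM_COMPONENTS <- c(GLCM_INPUTS, "storage", "transport", "border", "tariff")

stop_glcm <- function(msg, class = "glcm_error") {
  abort(msg, class = c(class, "glcm_error"))
}

check_positive_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_glcm(sprintf("`%s` must be a single positive number.", name),
              class = "glcm_config_error")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_glcm(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

# All randomness flows through here: the caller's RNG state is untouched.
with_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

relabel_modes_coarse <- function(mode) {
  if_else(grepl("^maritime", mode), "maritime", mode)
}
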