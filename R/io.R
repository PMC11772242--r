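BUNDLE_SCHEMAS <- list(
  regions = c("region_id", "country", "population", "node"),
  nodes = c("node_id", "country", "x", "y", "is_port", "has_rail"),
  edges = c("node_a", "node_b", "mode", "distance_km", "time_h"),
  production = c("region_id", "commodity", "production_t", "yield_t_ha"),
  input_costs = c("country", "commodity", "fertilizer", "pesticides",
                  "labour", "machinery", "diesel"),
  transport_params = c("country", "mode", "dc_usd_t_km", "hc_usd_t",
                       "wait_h", "vfft_usd_t_h", "border_usd_t"),
  trade = c("exporter", "importer", "commodity", "tonnes"),
  tariffs = c("exporter", "importer", "commodity", "ad_valorem_rate")
)

#' Write an input bundle to a directory of CSV files
#'
#' One UTF-8 CSV per table, base units in column names (USD/t, tonnes, km,
#' hours), "." decimal separator.
#'
#' @param bundle A `glcm_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(BUNDLE_SCHEMAS)) {
    readr::write_csv(bundle[[nm]][BUNDLE_SCHEMAS[[nm]]],
                     file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read and validate an input bundle
#'
#' Reads the eight CSV schemas, checks column names, types, referential
#' integrity and sign constraints, and fails with file and row diagnostics.
#'
#' @param dir Directory holding the eight bundle CSVs.
#' @param validate Run [validate_bundle()] and abort on problems?
#' @return A `glcm_bundle`.
#' @export
read_bundle <- function(dir, validate = TRUE) {
  out <- list()
  for (nm in names(BUNDLE_SCHEMAS)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop_glcm(sprintf("Missing bundle file: %s.", path), "glcm_io_error")
    }
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(BUNDLE_SCHEMAS[[nm]], names(tab))
    unknown <- setdiff(names(tab), BUNDLE_SCHEMAS[[nm]])
    if (length(missing) || length(unknown)) {
      stop_glcm(sprintf(
        "%s: bad columns (missing: %s; unknown: %s).", path,
        paste(missing, collapse = ","), paste(unknown, collapse = ",")),
        "glcm_io_error")
    }
    out[[nm]] <- tab
  }
  bundle <- structure(out, class = "glcm_bundle")
  if (validate) {
    probs <- validate_bundle(bundle)
    probs <- c(probs, bundle_row_diagnostics(bundle, dir))
    if (length(probs)) {
      stop_glcm(paste(c("Invalid bundle:", probs), collapse = "\n  "),
                "glcm_io_error")
    }
  }
  bundle
}

# Row-level diagnostics pointing at the offending file and row.
bundle_row_diagnostics <- function(bundle, dir) {
  p <- character()
  cset <- unique(bundle$regions$country)
  bad <- which(!(bundle$trade$exporter %in% cset) |
                 !(bundle$trade$importer %in% cset))
  if (length(bad)) {
    p <- c(p, sprintf("%s/trade.csv row %d: unknown country", dir, bad[1]))
  }
  bad <- which(bundle$production$yield_t_ha <= 0)
  if (length(bad)) {
    p <- c(p, sprintf("%s/production.csv row %d: non-positive yield (region %s)",
                      dir, bad[1], bundle$production$region_id[bad[1]]))
  }
  p
}

digest_file <- function(path) unname(tools::md5sum(path))

#' Run the full landed-cost pipeline
#'
#' Executes the stages in dependency order: world generation (or bundle
#' reading), production costs, routing, landed costs, radiation allocation,
#' metrics, and optionally the shock and reduction scenarios. Identical
#' config and seed reproduce identical outputs; a run manifest lists every
#' output file with an md5 digest, stage timings and warnings.
#'
#' @param config A [world_config()] (ignored when `bundle_dir` is given).
#' @param out_dir Optional directory for CSV/JSON outputs and the manifest.
#' @param bundle_dir Optional directory with an existing input bundle.
#' @param scenarios Run the shock and reduction scenario stages?
#' @param gamma,storage_usd_t Production-cost parameters.
#' @param shock A [shock_scenario()].
#' @param k,cluster_seed Clustering parameters.
#' @return List with all stage outputs and the `manifest`.
#' @export
run_pipeline <- function(config = world_config(), out_dir = NULL,
                         bundle_dir = NULL, scenarios = TRUE,
                         gamma = 0.5, storage_usd_t = 20,
                         shock = shock_scenario(), k = 6,
                         cluster_seed = NULL) {
  manifest <- list(
    tool = paste0("glcm ", as.character(utils::packageVersion("glcm"))),
    seed = config$seed,
    stages = list(), warnings = character(), outputs = list()
  )
  warn_log <- character()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        warn_log <<- c(warn_log, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$warnings <<- warn_log
        manifest$failed_stage <<- name
        if (!is.null(out_dir)) {
          dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
          jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                               auto_unbox = TRUE, digits = NA, force = TRUE)
        }
        stop_glcm(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
                  "glcm_stage_error")
      }
    )
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    val
  }
  res <- list()
  res$bundle <- timed("world", {
    if (!is.null(bundle_dir)) read_bundle(bundle_dir) else generate_world(config)
  })
  res$production_costs <- timed("production_costs",
    production_costs(res$bundle, gamma = gamma,
                     storage_usd_t = storage_usd_t))
  graph <- timed("graph", build_transport_graph(res$bundle))
  res$routes <- timed("routes", compute_routes(graph, res$bundle))
  res$landed_costs <- timed("landed_costs",
    landed_costs(res$production_costs, res$routes, res$bundle$tariffs,
                 res$bundle$regions, res$bundle$trade))
  res$flows <- timed("allocate", allocate_flows(res$bundle, res$landed_costs))
  res$metrics <- timed("metrics", list(
    regional = weighted_average_lc(res$flows, .data$ir, .data$commodity),
    isc = isc(res$flows, .data$commodity),
    breakdown = breakdown_shares(res$flows, .data$commodity),
    freight = freight_statistics(res$flows)
  ))
  if (scenarios) {
    res$shock <- timed("shock",
      shock_attribution(res$flows, shock, .data$ir))
    res$reduction <- timed("reduce", {
      red <- benchmark_reduction(res$flows)
      reduction_summary(red)
    })
    res$clusters <- timed("cluster",
      cluster_regions(res$reduction, k = k,
                      seed = cluster_seed %||% config$seed))
  }
  manifest$warnings <- warn_log

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(tab, file) {
      path <- file.path(out_dir, file)
      readr::write_csv(tab, path)
      manifest$outputs[[file]] <<- digest_file(path)
    }
    wr(res$production_costs, "production_costs.csv")
    wr(res$routes, "routes.csv")
    wr(res$flows, "flows.csv")
    wr(res$metrics$regional, "regional_lc.csv")
    wr(res$metrics$isc, "isc.csv")
    wr(res$metrics$breakdown, "breakdown.csv")
    jsonlite::write_json(res$metrics$freight,
                         file.path(out_dir, "freight.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs[["freight.json"]] <-
      digest_file(file.path(out_dir, "freight.json"))
    if (scenarios) {
      wr(res$shock, "shock.csv")
      wr(res$reduction, "reduction.csv")
      wr(as_tibble(res$clusters), "clusters.csv")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res$manifest <- manifest
  res
}
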