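#' Write analysis results with a run record
#'
#' Serialises a scenario table, sensitivity-analysis table or comparison to
#' disk (CSV for tabular results, JSON for a single comparison) alongside a
#' JSON run record holding the package version, timestamp, seed and a hash
#' of the parameter set, so every results file can be traced back to its
#' inputs. EUR values are written unrounded; rounding is presentation-only.
#'
#' @param x A `scenario_table`, `dsa_table`, `strategy_comparison` or plain
#'   tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"results"`).
#' @param params Optional `parameter_set` used for the run, hashed into the
#'   run record.
#' @param seed Optional seed recorded in the run record.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, prefix = "results", params = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "strategy_comparison")) {
    path <- file.path(dir, paste0(prefix, ".json"))
    jsonlite::write_json(as.list(tidy(x)), path, auto_unbox = TRUE, digits = NA)
  } else {
    path <- file.path(dir, paste0(prefix, ".csv"))
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  record <- list(
    package = "pdl1hta",
    version = as.character(packageVersion("pdl1hta")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameter_hash = if (!is.null(params)) rlang::hash(unclass(params)) else NULL
  )
  rec_path <- file.path(dir, paste0(prefix, "_run.json"))
  jsonlite::write_json(record, rec_path, auto_unbox = TRUE, null = "null")
  invisible(c(path, rec_path))
}
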