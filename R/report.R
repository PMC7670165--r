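# Tabular result export: CSV for the measurement/match table plus a JSON
# sidecar holding the pipeline configuration and data-quality flags.

#' Write a measurement/match report
#'
#' Writes the per-subject results table as RFC 4180 CSV together with a JSON
#' sidecar (same path, `.json` extension) recording the pipeline
#' configuration and any non-finite cells (serialised as empty CSV cells).
#'
#' @param measurements Non-empty data frame of measurement and/or match rows.
#' @param path Output CSV path.
#' @param config Optional [pipeline_config()] (or any list) stored in the
#'   sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(measurements, path, config = NULL) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L) {
    rlang::abort("report table must be a non-empty data frame",
                 class = "coronoid_degenerate_error")
  }
  num <- vapply(measurements, is.numeric, logical(1))
  flagged <- lapply(measurements[num], function(col) which(!is.finite(col)))
  flagged <- flagged[lengths(flagged) > 0]
  out <- measurements
  for (nm in names(flagged)) out[[nm]][flagged[[nm]]] <- NA_real_
  tryCatch(
    readr::write_csv(out, path, na = ""),
    error = function(e) rlang::abort(sprintf("cannot write report: %s", conditionMessage(e)),
                                     class = "coronoid_io_error")
  )
  sidecar <- list(
    config = if (is.null(config)) list() else unclass(config),
    n_rows = nrow(measurements),
    non_finite_cells = lapply(flagged, as.integer)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read back a report written by [write_report()]
#'
#' @param path CSV path previously written by [write_report()].
#' @return List with `table` (tibble) and `sidecar` (list).
#' @export
read_report <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sc <- sidecar_path(path)
  sidecar <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  list(table = tbl, sidecar = sidecar)
}
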