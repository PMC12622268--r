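# Report serialization: JSON (schema-versioned) and CSV.

#' Write an analysis report
#'
#' JSON reports carry a schema version, the run configuration (verbatim), the
#' per-frame measurement table, the lesion table with risk flags, and the
#' indices of frames excluded from morphometry. Numeric fields are written at
#' full precision. CSV reports write two files, `<stem>_frames.csv` and
#' `<stem>_lesions.csv`, with identical values.
#'
#' @param frame_measurements data.frame from [measure_pullback()] (a
#'   `plaque_class` column, if present, is carried along).
#' @param lesions data.frame from [segment_lesions()], possibly augmented
#'   with `plaque_class` and flag columns.
#' @param path output file (JSON) or stem (CSV).
#' @param format `"json"` or `"csv"`.
#' @param config run configuration embedded verbatim (JSON only).
#' @param excluded_frames integer indices excluded from morphometry.
#' @return the main output path, invisibly.
#' @export
write_report <- function(frame_measurements, lesions, path,
                         format = c("json", "csv"), config = NULL,
                         excluded_frames = integer()) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(schema_version = REPORT_SCHEMA_VERSION,
                config = config,
                excluded_frames = as.integer(excluded_frames),
                frames = frame_measurements,
                lesions = lesions)
    ok <- tryCatch({
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("I/O error writing report: ", conditionMessage(ok))
    invisible(path)
  } else {
    stem <- sub("\\.csv$", "", path)
    utils::write.csv(frame_measurements, paste0(stem, "_frames.csv"),
                     row.names = FALSE)
    utils::write.csv(lesions, paste0(stem, "_lesions.csv"), row.names = FALSE)
    invisible(paste0(stem, "_frames.csv"))
  }
}

#' Read a JSON analysis report
#' @param path JSON file from [write_report()].
#' @return list with `schema_version`, `config`, `excluded_frames`, `frames`,
#'   `lesions`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
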