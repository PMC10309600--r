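# CSV readers/writers for the yield and air-quality tables and the JSON
# analysis report.  CSV dialect: UTF-8, comma-separated, mandatory header
# row, "." decimal.  The study's supplementary workbook should be exported
# one sheet per CSV file before use.

#' Read a yield dataset from CSV
#'
#' Required columns: \code{sampler_label}, \code{duration_h},
#' \code{n_sheets}, \code{total_yield_ng}; optional: \code{session_id},
#' \code{location}, \code{hour_index}.
#'
#' @param path CSV file path.
#' @return a validated [yield_dataset()].
#' @export
read_yield_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty input: ", path, call. = FALSE)
  yield_dataset(df)
}

#' Write a yield dataset to CSV
#'
#' @param df a yield dataset.
#' @param path output path.
#' @export
write_yield_csv <- function(df, path) {
  utils::write.csv(yield_dataset(df), path, row.names = FALSE)
  invisible(path)
}

#' Read an air-quality covariate table from CSV
#'
#' Required columns: the ten covariates \code{pm_0_3}, \code{pm_0_5},
#' \code{pm_1_0}, \code{pm_2_5}, \code{pm_5_0}, \code{pm_10}, \code{at},
#' \code{rh}, \code{dp}, \code{wb}, plus \code{yield_ng}; optional
#' \code{hour_index}.
#'
#' @param path CSV file path.
#' @return data frame with validated physical ranges.
#' @export
read_air_quality_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c(.aq_vars, "yield_ng")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$rh < 0 | df$rh > 100, na.rm = TRUE))
    stop("rh outside [0, 100]", call. = FALSE)
  pm_bad <- vapply(df[.aq_vars[1:6]], function(v) any(v < 0, na.rm = TRUE),
                   logical(1))
  if (any(pm_bad))
    stop("negative PM value(s) in: ",
         paste(.aq_vars[1:6][pm_bad], collapse = ", "), call. = FALSE)
  df
}

#' Assemble an analysis report
#'
#' A serialisable container for per-stage results, the resolved
#' configuration, warnings and RNG seeds, so a run is reproducible from
#' its report.
#'
#' @param config named list of resolved configuration values (thresholds,
#'   levels, simulation sizes — no silent constants).
#' @param results named list of per-stage results.
#' @param warnings character vector of warnings raised.
#' @param seed RNG seed(s) used.
#' @return list of class \code{"analysis_report"}.
#' @export
analysis_report <- function(config = list(), results = list(),
                            warnings = character(), seed = NULL) {
  structure(list(tool = "aeroyield",
                 version = as.character(utils::packageVersion("aeroyield")),
                 config = config, results = results,
                 warnings = warnings, seed = seed),
            class = "analysis_report")
}

# Recursively strip classes / replace NaN so the report serialises cleanly
.jsonify <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .jsonify))
  if (is.numeric(x) && any(is.nan(x))) {
    warning("NaN in report encoded as null")
    x[is.nan(x)] <- NA_real_
  }
  if (is.factor(x)) x <- as.character(x)
  x
}

#' Write an analysis report as JSON
#'
#' NaN values are encoded as null (with a warning); the report round-trips
#' through [read_report()] losslessly up to those encodings.
#'
#' @param report an [analysis_report()] (or any serialisable list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(.jsonify(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path JSON file path.
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
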