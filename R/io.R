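# Output serialization with provenance: every file carries the package
# version and a hash of the configuration that produced it.

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

provenance <- function(config) {
  list(package = "mrdoctwin",
       version = as.character(utils::packageVersion("mrdoctwin")),
       config_hash = config_hash(config))
}

#' Write scenario results to a tidy CSV
#'
#' One row per design cell x fitted model. Two leading `#` comment lines
#' record the package version and the configuration hash; read the file back
#' with `comment.char = "#"` (as [read_study_csv()] does).
#'
#' @param results a `study_result`.
#' @param path output file.
#' @param config list describing the run (hashed into the header).
#' @return Invisibly, `path`.
#' @export
write_study_csv <- function(results, path, config = list()) {
  prov <- provenance(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mrdoctwin %s", prov$version), con)
  writeLines(sprintf("# config_hash %s", prov$config_hash), con)
  utils::write.csv(as.data.frame(results), con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_study_csv()]
#'
#' @param path CSV path.
#' @return Data frame of per-cell results.
#' @export
read_study_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write nested results (fits, regressions) to JSON
#'
#' @param x a list, `mrdoc_fit`, `mrdoc_lrt` or `ncp_power_regression`.
#' @param path output file.
#' @param config list describing the run (hashed for provenance).
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(x, path, config = list()) {
  # named atomic vectors (estimates, coefficients) serialize as JSON
  # objects, not bare arrays
  keep_names <- function(v) {
    if (is.list(v)) lapply(v, keep_names)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else v
  }
  payload <- list(provenance = provenance(config),
                  result = keep_names(unclass(x)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
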