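# Serialization helpers: traces as CSV, parameter sets and states as
# JSON (SI-annotated), run configurations as JSON or YAML.

#' Write a trace to CSV
#'
#' Writes \code{time_ms,value} rows with the channel and units recorded
#' in comment header lines.
#'
#' @param trace an \code{\link{as_trace}} object.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "eht_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# channel: ", attr(trace, "channel")),
               paste0("# units: ", attr(trace, "units")),
               paste0("# pacing_ms: ",
                      paste(attr(trace, "pacing_ms"), collapse = " "))),
             con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' @param path CSV file written by \code{\link{write_trace}}, or any CSV
#'   with \code{time_ms,value} columns.
#' @return An \code{\link{as_trace}} object.
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  d <- utils::read.csv(path, comment.char = "#")
  pac <- get("pacing_ms", "")
  pac <- if (nzchar(pac)) as.numeric(strsplit(pac, " ")[[1]])
         else numeric()
  as_trace(d$time_ms, d$value, channel = get("channel", "ap"),
           units = get("units", "mV"), pacing_ms = pac)
}

#' Write model parameters (or a state) to JSON
#'
#' @param params a \code{\link{cm_parameters}} or \code{cm_state}.
#' @param path output JSON file.
#' @export
write_cm_json <- function(params, path) {
  kind <- if (inherits(params, "cm_parameters")) "cm_parameters"
          else if (inherits(params, "cm_state")) "cm_state"
          else stop("unsupported object", call. = FALSE)
  obj <- list(kind = kind,
              preset = attr(params, "preset"),
              units = if (kind == "cm_parameters")
                as.list(cm_parameter_units()) else NULL,
              values = as.list(stats::setNames(as.numeric(params),
                                               names(unclass(params)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read model parameters or a state from JSON
#'
#' @param path JSON file written by \code{\link{write_cm_json}}.
#' @return A \code{cm_parameters} or \code{cm_state} object.
#' @export
read_cm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- unlist(obj$values)
  if (identical(obj$kind, "cm_parameters")) {
    p <- structure(vals, class = "cm_parameters")
    validate_cm_parameters(p)
    if (!is.null(obj$preset)) attr(p, "preset") <- obj$preset
    p
  } else {
    structure(vals, class = "cm_state")
  }
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path configuration file; format chosen by extension.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::read_json(path, simplifyVector = TRUE),
         yaml = , yml = yaml::read_yaml(path),
         stop("unsupported config format: ", ext, call. = FALSE))
}
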