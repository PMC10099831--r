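# Serialization helpers. Numbers are written at 12 significant digits:
# above integrator tolerance, still diff-able.

#' Write a trajectory to CSV
#'
#' Writes the interface columns `time_h`, `temperature_C`, `B1`, `B2`,
#' `DOC`, `CO2_cum`, `theta_S`, `active_fraction` at 12 significant digits.
#'
#' @param trajectory a `cryodorm_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cryodorm_trajectory"))
  cols <- c("time_h", "temperature_C", "B1", "B2", "DOC", "CO2_cum",
            "theta_S", "active_fraction")
  out <- trajectory[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#' @param path file path.
#' @return A data.frame with the interface columns.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  utils::read.csv(path)
}

#' Write a scenario summary as JSON
#' @param summary a `cryodorm_summary` from [summarize_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cryodorm_summary"))
  jsonlite::write_json(lapply(unclass(summary), function(x)
    if (is.numeric(x)) signif(x, 12) else x),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
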