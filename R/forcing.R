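#' Piecewise-constant temperature schedule
#'
#' @param durations segment durations in hours (all > 0).
#' @param temperatures segment temperatures in deg C, same length.
#' @return An object of class `temperature_schedule`: a data.frame with
#'   columns `duration_hours`, `temperature_C` and precomputed segment end
#'   times. Evaluation beyond the final segment holds its temperature.
#' @export
#' @examples
#' sched <- temperature_schedule(c(72, 72, 72, 24), c(0.5, -3, 0.5, -3))
#' temperature_at(sched, 150)  # 0.5
temperature_schedule <- function(durations, temperatures) {
  if (length(durations) != length(temperatures) || length(durations) == 0L) {
    stop("durations and temperatures must be equal-length, non-empty")
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all segment durations must be positive and finite")
  }
  if (any(!is.finite(temperatures))) stop("non-finite temperature")
  s <- data.frame(duration_hours = as.numeric(durations),
                  temperature_C = as.numeric(temperatures))
  s$end_hours <- cumsum(s$duration_hours)
  class(s) <- c("temperature_schedule", "data.frame")
  s
}

#' Evaluate a schedule at given times
#'
#' Segment boundaries are right-continuous: a segment's temperature applies
#' from its start instant (inclusive) to its end (exclusive). Times beyond
#' the schedule hold the final temperature.
#'
#' @param schedule a [temperature_schedule()].
#' @param t time(s) in hours, all >= 0; vectorized.
#' @return Temperature(s) in deg C.
#' @export
temperature_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "temperature_schedule"))
  if (any(t < 0)) stop("time must be non-negative")
  # segment i covers [end[i-1], end[i]); findInterval with left-open
  # intervals gives the right-continuous convention
  idx <- findInterval(t, schedule$end_hours, left.open = FALSE) + 1L
  idx <- pmin(idx, nrow(schedule))
  schedule$temperature_C[idx]
}

#' Total duration of a schedule in hours
#' @param schedule a [temperature_schedule()].
#' @return Numeric scalar, hours.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "temperature_schedule"))
  schedule$end_hours[nrow(schedule)]
}

#' Read a temperature schedule from delimited text
#'
#' One row per segment with columns `duration_hours` and `temperature_C`
#' (header required; comma- or whitespace-delimited).
#'
#' @param path file path.
#' @return A [temperature_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           strip.white = TRUE)
  need <- c("duration_hours", "temperature_C")
  if (!all(need %in% names(tab))) {
    stop("schedule file must have columns: ", paste(need, collapse = ", "))
  }
  temperature_schedule(tab$duration_hours, tab$temperature_C)
}

#' Write a temperature schedule to CSV
#' @param schedule a [temperature_schedule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "temperature_schedule"))
  utils::write.csv(
    data.frame(duration_hours = schedule$duration_hours,
               temperature_C = schedule$temperature_C),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published freeze/thaw scenario presets
#'
#' Three idealized forcing scenarios for a glacier-surface microbial
#' community, each 10 days with total biomass 0.55 ug C L^-1 and
#' DOC 1200 ug C L^-1 at start:
#' \describe{
#'   \item{FREEZE}{initially fully active community, constant -3 deg C —
#'     the onset of freezing.}
#'   \item{THAW}{initially fully dormant community, constant 0.5 deg C —
#'     the onset of melting.}
#'   \item{FREEZE_THAW}{initially fully dormant; 0.5 deg C for 3 days,
#'     -3 deg C for 3 days, 0.5 deg C for 3 days, -3 deg C for 1 day.}
#' }
#'
#' @param name scenario name, case-insensitive; `"FREEZE"`, `"THAW"` or
#'   `"FREEZE_THAW"` (a hyphen is also accepted).
#' @param initial_biomass total biomass at start (ug C L^-1).
#' @param initial_DOC dissolved organic carbon at start (ug C L^-1).
#' @return An object of class `scenario_preset`: a list with `name`,
#'   `initial_state`, `schedule`, `duration_hours`.
#' @export
#' @examples
#' preset("freeze")$initial_state
preset <- function(name, initial_biomass = 0.55, initial_DOC = 1200) {
  key <- toupper(gsub("-", "_", trimws(name)))
  valid <- c("FREEZE", "THAW", "FREEZE_THAW")
  if (!key %in% valid) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  ps <- switch(key,
    FREEZE = list(
      initial_state = model_state(B1 = initial_biomass, B2 = 0,
                                  DOC = initial_DOC),
      schedule = temperature_schedule(240, -3)),
    THAW = list(
      initial_state = model_state(B1 = 0, B2 = initial_biomass,
                                  DOC = initial_DOC),
      schedule = temperature_schedule(240, 0.5)),
    FREEZE_THAW = list(
      initial_state = model_state(B1 = 0, B2 = initial_biomass,
                                  DOC = initial_DOC),
      schedule = temperature_schedule(c(72, 72, 72, 24),
                                      c(0.5, -3, 0.5, -3)))
  )
  structure(list(name = key,
                 initial_state = ps$initial_state,
                 schedule = ps$schedule,
                 duration_hours = schedule_duration(ps$schedule)),
            class = "scenario_preset")
}

#' Build a custom scenario from a schedule and initial state
#'
#' @param schedule a [temperature_schedule()].
#' @param initial_state a [model_state()].
#' @param name label for outputs.
#' @return A `scenario_preset`.
#' @export
custom_scenario <- function(schedule, initial_state, name = "CUSTOM") {
  stopifnot(inherits(schedule, "temperature_schedule"))
  initial_state <- model_state(initial_state[["B1"]], initial_state[["B2"]],
                               initial_state[["DOC"]],
                               if ("CO2_cum" %in% names(initial_state))
                                 initial_state[["CO2_cum"]] else 0)
  structure(list(name = name, initial_state = initial_state,
                 schedule = schedule,
                 duration_hours = schedule_duration(schedule)),
            class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario", x$name, "-", x$duration_hours, "h\n")
  cat(sprintf("  initial: B1=%g B2=%g DOC=%g ug C L^-1\n",
              x$initial_state[["B1"]], x$initial_state[["B2"]],
              x$initial_state[["DOC"]]))
  cat("  segments (h @ degC):",
      paste(sprintf("%g@%g", x$schedule$duration_hours,
                    x$schedule$temperature_C), collapse = ", "), "\n")
  invisible(x)
}
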