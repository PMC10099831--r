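#' Default model parameter set
#'
#' Returns the rate constants and switch parameters of the active/dormant
#' biomass model. Growth and activation rates (`v_max`, `R_SA`) are the
#' repository calibration that reproduces the published freeze/thaw scenario
#' outcomes; every value can be overridden individually or from a parameter
#' file (see [read_params()]).
#'
#' @param ... named overrides for individual parameters, e.g.
#'   `default_params(v_max = 0.01)`. Unknown names are an error.
#'
#' @return A named list of class `cryodorm_params` with elements:
#' \describe{
#'   \item{v_max}{maximum specific growth rate of active biomass (h^-1)}
#'   \item{K_v}{half-saturation constant for growth on DOC (ug C L^-1)}
#'   \item{Y}{growth yield, fraction of carbon uptake fixed as biomass (0,1]}
#'   \item{alpha_B1, alpha_B2}{mortality rate constants of active and dormant
#'     biomass (h^-1)}
#'   \item{m_B1, m_B2}{specific maintenance requirements of active and dormant
#'     biomass (h^-1, carbon cost per unit biomass)}
#'   \item{R_SD}{specific rate of deactivation, active to dormant (h^-1)}
#'   \item{R_SA}{specific rate of activation, dormant to active (h^-1)}
#'   \item{K_S}{threshold temperature for net activation/deactivation (deg C)}
#'   \item{st_S}{dimensionless steepness of the switching sigmoid}
#' }
#' @seealso [read_params()], [compute_theta()], [derivatives()]
#' @export
#' @examples
#' p <- default_params()
#' p_fast <- default_params(v_max = 0.01)
default_params <- function(...) {
  p <- list(
    v_max    = 0.00347,
    K_v      = 100,
    Y        = 0.6,
    alpha_B1 = 1e-3,
    alpha_B2 = 1e-4,
    m_B1     = 2e-3,
    m_B2     = 5e-4,
    R_SD     = 0.045,
    R_SA     = 0.0403,
    K_S      = 0.1,
    st_S     = 2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
}

#' Validate a model parameter set
#'
#' Checks completeness, non-negativity of all rates, `K_v > 0`, `0 < Y <= 1`,
#' and that the switch scale `st_S * K_S` is strictly positive (required for
#' the switching sigmoid to increase with temperature).
#'
#' @param p a named list of parameters (see [default_params()]).
#' @return `p`, invisibly classed as `cryodorm_params`.
#' @export
validate_params <- function(p) {
  required <- c("v_max", "K_v", "Y", "alpha_B1", "alpha_B2",
                "m_B1", "m_B2", "R_SD", "R_SA", "K_S", "st_S")
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  num <- vapply(p[required], function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    stop("non-numeric or non-finite parameter(s): ",
         paste(required[!num], collapse = ", "))
  }
  rates <- c("v_max", "alpha_B1", "alpha_B2", "m_B1", "m_B2", "R_SD", "R_SA")
  neg <- vapply(p[rates], function(x) x < 0, logical(1))
  if (any(neg)) {
    stop("negative rate constant(s): ", paste(rates[neg], collapse = ", "))
  }
  if (p$K_v <= 0) stop("K_v must be strictly positive")
  if (p$Y <= 0 || p$Y > 1) stop("Y must lie in (0, 1]")
  if (p$st_S * p$K_S <= 0) {
    stop("invalid switch scale: st_S * K_S must be strictly positive ",
         "(got ", p$st_S * p$K_S, ")")
  }
  p <- p[required]
  class(p) <- "cryodorm_params"
  p
}

#' Read a parameter file
#'
#' Parses a flat key-value text file (one `name = value` or `name: value` or
#' whitespace-separated pair per line; `#` starts a comment). Keys must be
#' parameter names as in [default_params()]; unknown keys are an error.
#' Missing keys fall back to the defaults, with a notice listing them.
#'
#' @param path path to the parameter file.
#' @param quiet suppress the missing-key notice.
#' @return A validated `cryodorm_params` list.
#' @export
read_params <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- default_params()
  given <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "[=:[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) {
      stop("cannot parse parameter line: '", lines[[i]], "'")
    }
    key <- parts[[1]]
    if (!key %in% names(defaults)) {
      stop("unknown parameter key '", key, "' in ", path)
    }
    val <- suppressWarnings(as.numeric(parts[[2]]))
    if (is.na(val)) stop("non-numeric value for '", key, "': ", parts[[2]])
    given[[key]] <- val
  }
  absent <- setdiff(names(defaults), names(given))
  if (length(absent) && !quiet) {
    message("parameter file ", basename(path), ": using defaults for ",
            paste(absent, collapse = ", "))
  }
  p <- unclass(defaults)
  p[names(given)] <- given
  validate_params(p)
}

#' @export
print.cryodorm_params <- function(x, ...) {
  cat("Model parameters (h^-1 unless noted):\n")
  for (nm in names(x)) {
    unit <- switch(nm, K_v = " ug C L^-1", K_S = " deg C",
                   Y = " (yield)", st_S = " (steepness)", "")
    cat(sprintf("  %-8s = %g%s\n", nm, x[[nm]], unit))
  }
  invisible(x)
}
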