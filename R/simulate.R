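#' Integrate a scenario
#'
#' Solves the active/dormant biomass system over the scenario's temperature
#' schedule with `deSolve::lsoda`. Integration restarts at every segment
#' boundary so the discontinuous forcing never straddles an internal solver
#' step. Output is on a uniform grid including t = 0 and the scenario end.
#'
#' @param scenario a [preset()] or [custom_scenario()].
#' @param params a `cryodorm_params` list; [default_params()] if missing.
#' @param output_step output grid spacing in hours (> 0), default 1.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return A data.frame of class `cryodorm_trajectory` with one row per grid
#'   point: `time_h`, `temperature_C`, `B1`, `B2`, `DOC`, `CO2_cum`,
#'   `theta_S`, `active_fraction`, and the instantaneous fluxes `V_B1`,
#'   `D_B1`, `D_B2`, `M_B1`, `M_B2`, `xi`, `eps`, `CO2_rate`. The scenario
#'   and parameters are attached as attributes.
#' @export
#' @examples
#' traj <- integrate_scenario(preset("THAW"))
#' traj[traj$time_h == 24, "active_fraction"]  # ~0.55
integrate_scenario <- function(scenario, params = default_params(),
                               output_step = 1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(scenario, "scenario_preset"))
  params <- validate_params(params)
  if (!is.numeric(output_step) || output_step <= 0) {
    stop("output_step must be positive")
  }
  duration <- scenario$duration_hours
  grid <- seq(0, duration, by = output_step)
  if (grid[length(grid)] < duration) grid <- c(grid, duration)

  rhs <- function(t, y, parms, temperature) {
    list(derivatives(y, temperature, parms)$deriv)
  }

  bounds <- c(0, scenario$schedule$end_hours)
  bounds[length(bounds)] <- max(bounds[length(bounds)], duration)
  state <- scenario$initial_state
  out <- matrix(NA_real_, nrow = length(grid), ncol = 4,
                dimnames = list(NULL, names(state)))
  out[1, ] <- state
  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    if (t1 <= t0) next
    temp <- temperature_at(scenario$schedule, t0)
    inside <- which(grid > t0 & grid <= t1)
    times <- unique(c(t0, grid[inside], t1))
    sol <- deSolve::lsoda(y = state, times = times, func = rhs,
                          parms = params, temperature = temp,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("solver failure in segment ", seg, " at t ~ ",
           signif(sol[nrow(sol), "time"], 6), " h; last state: ",
           paste(signif(sol[nrow(sol), -1], 6), collapse = ", "))
    }
    sol_states <- clamp_state(sol[, -1, drop = FALSE])
    keep <- match(grid[inside], sol[, "time"])
    out[inside, ] <- sol_states[keep, , drop = FALSE]
    state <- sol_states[nrow(sol_states), ]
    names(state) <- names(scenario$initial_state)
  }

  if (min(out[, "DOC"]) < 1e-3) {
    warning("DOC nearly exhausted (min ", signif(min(out[, "DOC"]), 3),
            " ug C L^-1): growth and maintenance are substrate-limited")
  }

  temps <- temperature_at(scenario$schedule, pmin(grid, duration - 1e-9))
  temps[1] <- temperature_at(scenario$schedule, 0)
  flux_rows <- lapply(seq_along(grid), function(i) {
    model_fluxes(out[i, ], temps[i], params)
  })
  fx <- as.data.frame(do.call(rbind, lapply(flux_rows, unlist)))
  traj <- data.frame(
    time_h = grid,
    temperature_C = temps,
    B1 = out[, "B1"], B2 = out[, "B2"],
    DOC = out[, "DOC"], CO2_cum = out[, "CO2_cum"],
    theta_S = fx$theta_S,
    active_fraction = active_fraction_vec(out[, "B1"], out[, "B2"]),
    V_B1 = fx$V_B1, D_B1 = fx$D_B1, D_B2 = fx$D_B2,
    M_B1 = fx$M_B1, M_B2 = fx$M_B2, xi = fx$xi, eps = fx$eps,
    CO2_rate = fx$CO2_rate)
  attr(traj, "scenario") <- scenario
  attr(traj, "params") <- params
  class(traj) <- c("cryodorm_trajectory", "data.frame")
  traj
}

# Integrators can undershoot zero by roundoff; clamp within tolerance,
# refuse larger excursions.
clamp_state <- function(m, tol = 1e-12) {
  neg <- m < 0
  if (any(neg)) {
    if (min(m[neg]) < -tol) {
      stop("integrator produced a negative state beyond tolerance: ",
           min(m[neg]))
    }
    m[neg] <- 0
  }
  m
}

active_fraction_vec <- function(B1, B2) {
  tot <- B1 + B2
  ifelse(tot > 0, B1 / tot, NA_real_)
}

#' Active fraction of a model state
#'
#' `B1 / (B1 + B2)`; `NA` when total biomass is zero (undefined).
#'
#' @param state a [model_state()] or any vector with named `B1`, `B2`.
#' @return Fraction in [0, 1], or `NA`.
#' @export
active_fraction <- function(state) {
  B1 <- state[["B1"]]; B2 <- state[["B2"]]
  if (B1 < 0 || B2 < 0) stop("biomass must be non-negative")
  if (B1 + B2 == 0) return(NA_real_)
  B1 / (B1 + B2)
}

#' Summarize a trajectory
#'
#' Computes the scenario-level quantities: net biomass change, net DOC
#' consumption, and the partition of cumulative catabolism into growth
#' uptake (`V_B1 / Y`) versus maintenance of each pool, by trapezoidal
#' integration of the flux series.
#'
#' @param trajectory a `cryodorm_trajectory` from [integrate_scenario()].
#' @param params the parameter set; taken from the trajectory if missing.
#' @return A list of class `cryodorm_summary`: `biomass_change`,
#'   `DOC_consumed`, `CO2_respired`, `growth_uptake`, `maintenance_B1`,
#'   `maintenance_B2`, `maintenance_share` (fraction of cumulative
#'   catabolism spent on maintenance), `active_fraction_initial`,
#'   `active_fraction_final` (all carbon quantities in ug C L^-1).
#' @export
summarize_trajectory <- function(trajectory, params = NULL) {
  stopifnot(inherits(trajectory, "cryodorm_trajectory"))
  if (nrow(trajectory) < 2L) stop("trajectory must have at least two points")
  if (is.null(params)) params <- attr(trajectory, "params")
  t <- trajectory$time_h
  trapz <- function(y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  uptake <- trapz(trajectory$V_B1 / params$Y)
  m1 <- trapz(trajectory$M_B1)
  m2 <- trapz(trajectory$M_B2)
  catabolism <- uptake + m1 + m2
  n <- nrow(trajectory)
  structure(list(
    biomass_change = (trajectory$B1[n] + trajectory$B2[n]) -
      (trajectory$B1[1] + trajectory$B2[1]),
    DOC_consumed = trajectory$DOC[1] - trajectory$DOC[n],
    CO2_respired = trajectory$CO2_cum[n] - trajectory$CO2_cum[1],
    growth_uptake = uptake,
    maintenance_B1 = m1,
    maintenance_B2 = m2,
    maintenance_share = if (catabolism > 0) (m1 + m2) / catabolism
                        else NA_real_,
    active_fraction_initial = trajectory$active_fraction[1],
    active_fraction_final = trajectory$active_fraction[n]
  ), class = "cryodorm_summary")
}

#' @export
print.cryodorm_summary <- function(x, ...) {
  cat("Scenario summary (ug C L^-1):\n")
  cat(sprintf("  biomass change     %+.4g\n", x$biomass_change))
  cat(sprintf("  DOC consumed       %.4g\n", x$DOC_consumed))
  cat(sprintf("  CO2 respired       %.4g\n", x$CO2_respired))
  cat(sprintf("  growth uptake      %.4g\n", x$growth_uptake))
  cat(sprintf("  maintenance B1/B2  %.4g / %.4g\n",
              x$maintenance_B1, x$maintenance_B2))
  cat(sprintf("  maintenance share  %.3f of cumulative catabolism\n",
              x$maintenance_share))
  cat(sprintf("  active fraction    %.3f -> %.3f\n",
              x$active_fraction_initial, x$active_fraction_final))
  invisible(x)
}

#' Fixed-step fourth-order Runge-Kutta reference integrator
#'
#' An independent verification integrator for the same system: classical
#' RK4 with a fixed step, restarted at schedule boundaries, sharing no
#' stepping code with [integrate_scenario()]. Intended for tests and
#' cross-checks; the step must be at most 0.01 h.
#'
#' @param scenario a [preset()] or [custom_scenario()].
#' @param params a `cryodorm_params` list.
#' @param dt fixed step in hours (<= 0.01).
#' @param output_step spacing of reported states in hours; must be a
#'   multiple of `dt`.
#' @return A data.frame with `time_h`, `B1`, `B2`, `DOC`, `CO2_cum`.
#' @export
oracle_integrate <- function(scenario, params = default_params(), dt = 0.005,
                             output_step = 1) {
  stopifnot(inherits(scenario, "scenario_preset"))
  params <- validate_params(params)
  if (dt > 0.01) stop("oracle step dt must be <= 0.01 h")
  bounds <- c(0, scenario$schedule$end_hours)
  state <- scenario$initial_state
  times_out <- numeric(0); states_out <- list()
  record <- function(t, s) {
    times_out[[length(times_out) + 1L]] <<- t
    states_out[[length(states_out) + 1L]] <<- s
  }
  record(0, state)
  next_out <- output_step
  f <- function(y, temp) derivatives(y, temp, params)$deriv
  for (seg in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    temp <- temperature_at(scenario$schedule, t0)
    nstep <- ceiling((t1 - t0) / dt - 1e-9)
    h <- (t1 - t0) / nstep
    t <- t0
    for (i in seq_len(nstep)) {
      k1 <- f(state, temp)
      k2 <- f(pmax(state + h / 2 * k1, 0), temp)
      k3 <- f(pmax(state + h / 2 * k2, 0), temp)
      k4 <- f(pmax(state + h * k3, 0), temp)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      state <- pmax(state, 0)
      t <- t0 + i * h
      while (next_out <= t + 1e-9 &&
             next_out <= scenario$duration_hours + 1e-9) {
        record(next_out, state)
        next_out <- next_out + output_step
      }
    }
  }
  out <- do.call(rbind, states_out)
  data.frame(time_h = unlist(times_out),
             B1 = out[, "B1"], B2 = out[, "B2"],
             DOC = out[, "DOC"], CO2_cum = out[, "CO2_cum"])
}
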