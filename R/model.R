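#' Construct a model state
#'
#' The instantaneous state of the system: active biomass `B1`, dormant
#' biomass `B2`, dissolved organic carbon `DOC` (all ug C L^-1), and the
#' diagnostic cumulative respired carbon `CO2_cum`. The CO2 pool never feeds
#' back on the dynamics; it exists so that carbon closure is testable.
#'
#' @param B1,B2 active and dormant biomass concentrations (ug C L^-1).
#' @param DOC dissolved organic carbon concentration (ug C L^-1).
#' @param CO2_cum cumulative respired carbon (ug C L^-1), default 0.
#' @return A named numeric vector `c(B1, B2, DOC, CO2_cum)`.
#' @export
#' @examples
#' model_state(B1 = 0.55, B2 = 0, DOC = 1200)
model_state <- function(B1, B2, DOC, CO2_cum = 0) {
  s <- c(B1 = B1, B2 = B2, DOC = DOC, CO2_cum = CO2_cum)
  if (any(!is.finite(s))) stop("non-finite model state")
  if (any(s < 0)) {
    stop("model state components must be non-negative (got ",
         paste(sprintf("%s=%g", names(s)[s < 0], s[s < 0]), collapse = ", "),
         ")")
  }
  s
}

#' Temperature switching function (Fermi-Dirac form)
#'
#' Sigmoidal function of temperature controlling the direction and rate of
#' the active/dormant state change:
#' \deqn{\theta_S = \frac{1}{\exp((-T + K_S)/(st_S K_S)) + 1}}
#' Strictly increasing in temperature, with \eqn{\theta_S = 0.5} exactly at
#' the threshold `K_S`. Above the threshold (`theta > 0.5`) activation
#' dominates; below it deactivation dominates.
#'
#' @param temperature temperature(s) in deg C; vectorized.
#' @param params a `cryodorm_params` list (see [default_params()]).
#' @return Switch value(s) in (0, 1).
#' @export
#' @examples
#' compute_theta(0.1, default_params())  # 0.5 at the threshold
compute_theta <- function(temperature, params) {
  params <- validate_params(params)
  scale <- params$st_S * params$K_S
  1 / (exp((-temperature + params$K_S) / scale) + 1)
}

#' Michaelis-Menten growth flux of active biomass
#'
#' `B1 * v_max * DOC / (K_v + DOC)` (ug C L^-1 h^-1). This is the rate of new
#' biomass synthesis; total carbon uptake is this divided by the yield `Y`.
#'
#' @param B1 active biomass (ug C L^-1).
#' @param DOC dissolved organic carbon (ug C L^-1).
#' @param params a `cryodorm_params` list.
#' @return Growth flux, bounded by `B1 * v_max`.
#' @export
growth_flux <- function(B1, DOC, params) {
  if (any(B1 < 0) || any(DOC < 0)) stop("B1 and DOC must be non-negative")
  B1 * params$v_max * DOC / (params$K_v + DOC)
}

#' First-order mortality flux
#'
#' @param Bn biomass of either pool (ug C L^-1).
#' @param alpha_n mortality rate constant (h^-1).
#' @return `alpha_n * Bn` (ug C L^-1 h^-1). Dead biomass carbon returns to
#'   the DOC pool in full.
#' @export
mortality_flux <- function(Bn, alpha_n) {
  if (any(Bn < 0) || any(alpha_n < 0)) {
    stop("biomass and mortality rate must be non-negative")
  }
  alpha_n * Bn
}

#' Maintenance (exogenous catabolism) flux
#'
#' Carbon drawn from DOC and respired to CO2 to meet non-growth power
#' requirements, proportional to biomass. Both active and dormant pools pay
#' maintenance, the dormant pool typically at a much lower specific rate.
#'
#' @param Bn biomass of either pool (ug C L^-1).
#' @param m_n specific maintenance requirement (h^-1).
#' @return `m_n * Bn` (ug C L^-1 h^-1).
#' @export
maintenance_flux <- function(Bn, m_n) {
  if (any(Bn < 0) || any(m_n < 0)) {
    stop("biomass and maintenance rate must be non-negative")
  }
  m_n * Bn
}

#' Bidirectional state-switching fluxes
#'
#' Deactivation `xi = (1 - theta) * R_SD * B1` (active to dormant) and
#' activation `eps = theta * R_SA * B2` (dormant to active). Both fluxes can
#' be nonzero simultaneously; the switch value `theta` sets the net
#' direction.
#'
#' @param B1,B2 active and dormant biomass (ug C L^-1).
#' @param theta switch value in (0, 1), from [compute_theta()].
#' @param params a `cryodorm_params` list.
#' @return A list with elements `xi` and `eps` (ug C L^-1 h^-1).
#' @export
switching_fluxes <- function(B1, B2, theta, params) {
  if (any(theta <= 0) || any(theta >= 1)) {
    stop("theta must lie strictly in (0, 1)")
  }
  if (any(B1 < 0) || any(B2 < 0)) stop("biomass must be non-negative")
  list(xi  = (1 - theta) * params$R_SD * B1,
       eps = theta * params$R_SA * B2)
}

# Smooth substrate-limitation guard: multiplies DOC-consuming fluxes so they
# vanish as DOC -> 0 instead of driving DOC negative. kappa is far below any
# environmentally meaningful concentration; at the published scenarios'
# DOC ~ 1200 the factor differs from 1 by ~8e-10.
.doc_limitation_kappa <- 1e-6
doc_limitation <- function(DOC) DOC / (DOC + .doc_limitation_kappa)

#' Instantaneous fluxes of the model at a given state and temperature
#'
#' Evaluates every transfer function: growth, mortality of both pools,
#' maintenance of both pools, deactivation, activation, the switch value,
#' and the respiration rate.
#'
#' @param state a model state (see [model_state()]).
#' @param temperature temperature in deg C.
#' @param params a `cryodorm_params` list.
#' @return A named list: `V_B1`, `D_B1`, `D_B2`, `M_B1`, `M_B2`, `xi`,
#'   `eps`, `theta_S`, `CO2_rate` (all fluxes in ug C L^-1 h^-1).
#' @export
model_fluxes <- function(state, temperature, params) {
  B1 <- state[["B1"]]; B2 <- state[["B2"]]; DOC <- state[["DOC"]]
  if (any(c(B1, B2, DOC) < 0) || any(!is.finite(c(B1, B2, DOC)))) {
    stop("invalid model state")
  }
  # the sigmoid saturates to exactly 0 or 1 in floating point far from K_S;
  # keep theta strictly inside (0,1) for the flux laws (one-ulp-scale nudge)
  theta <- min(max(compute_theta(temperature, params), 1e-15), 1 - 1e-15)
  lim <- doc_limitation(DOC)
  V  <- growth_flux(B1, DOC, params) * lim
  D1 <- mortality_flux(B1, params$alpha_B1)
  D2 <- mortality_flux(B2, params$alpha_B2)
  M1 <- maintenance_flux(B1, params$m_B1) * lim
  M2 <- maintenance_flux(B2, params$m_B2) * lim
  sw <- switching_fluxes(B1, B2, theta, params)
  list(V_B1 = V, D_B1 = D1, D_B2 = D2, M_B1 = M1, M_B2 = M2,
       xi = sw$xi, eps = sw$eps, theta_S = theta,
       CO2_rate = V * (1 / params$Y - 1) + M1 + M2)
}

#' Time derivatives of the model state
#'
#' The coupled system:
#' \deqn{dB_1/dt = V_{B1} - D_{B1} - \xi + \epsilon}
#' \deqn{dB_2/dt = -D_{B2} + \xi - \epsilon}
#' \deqn{dDOC/dt = -V_{B1}/Y - (M_{B1} + M_{B2}) + (D_{B1} + D_{B2})}
#' plus the diagnostic \eqn{dCO_2/dt = V_{B1}(1/Y - 1) + M_{B1} + M_{B2}}.
#' The four components sum to zero exactly: respiration is the only carbon
#' sink and all necromass returns to DOC.
#'
#' @inheritParams model_fluxes
#' @return A list with `deriv` (named numeric vector, same layout as the
#'   state) and `fluxes` (as from [model_fluxes()]).
#' @export
derivatives <- function(state, temperature, params) {
  f <- model_fluxes(state, temperature, params)
  dB1  <- f$V_B1 - f$D_B1 - f$xi + f$eps
  dB2  <- -f$D_B2 + f$xi - f$eps
  dDOC <- -f$V_B1 / params$Y - (f$M_B1 + f$M_B2) + (f$D_B1 + f$D_B2)
  dCO2 <- f$CO2_rate
  list(deriv = c(B1 = dB1, B2 = dB2, DOC = dDOC, CO2_cum = dCO2),
       fluxes = f)
}

#' Convert a cell density to biomass carbon concentration
#'
#' `cells mL^-1 * fg C cell^-1 * 1e-6 = ug C L^-1`. With the standard
#' glacier-surface conversion of 11 fg C per bacterial cell, 5e4 cells mL^-1
#' corresponds to 0.55 ug C L^-1, the model's default initial biomass.
#'
#' @param cell_density cells per mL.
#' @param carbon_per_cell carbon content per cell (fg C), default 11.
#' @return Biomass concentration in ug C L^-1.
#' @export
#' @examples
#' cells_to_biomass(5e4)  # 0.55
cells_to_biomass <- function(cell_density, carbon_per_cell = 11) {
  if (any(cell_density < 0) || any(carbon_per_cell < 0)) {
    stop("cell density and carbon content must be non-negative")
  }
  cell_density * carbon_per_cell / 1e6
}
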