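# Shared fixtures and independent oracles for the test suite.

# Independent one-line-per-equation transcription of the governing system,
# written directly from the closed forms and sharing no code with the
# package's derivatives(). Used as the oracle for flux/derivative checks.
oracle_derivs <- function(B1, B2, DOC, temperature, p) {
  theta <- 1 / (exp((-temperature + p$K_S) / (p$st_S * p$K_S)) + 1)
  V  <- B1 * p$v_max * DOC / (p$K_v + DOC)
  D1 <- p$alpha_B1 * B1
  D2 <- p$alpha_B2 * B2
  M1 <- p$m_B1 * B1
  M2 <- p$m_B2 * B2
  xi  <- (1 - theta) * p$R_SD * B1
  eps <- theta * p$R_SA * B2
  c(dB1  = V - D1 - xi + eps,
    dB2  = -D2 + xi - eps,
    dDOC = -V / p$Y - (M1 + M2) + (D1 + D2),
    dCO2 = V * (1 / p$Y - 1) + M1 + M2)
}

# Parameter set with every rate zeroed: the null model.
null_params <- function() {
  default_params(v_max = 0, alpha_B1 = 0, alpha_B2 = 0,
                 m_B1 = 0, m_B2 = 0, R_SD = 0, R_SA = 0)
}

# Random valid states/parameters for property-style loops.
random_state <- function() {
  model_state(B1 = runif(1, 0, 5), B2 = runif(1, 0, 5),
              DOC = runif(1, 0, 2000), CO2_cum = runif(1, 0, 10))
}
random_params <- function() {
  default_params(v_max = runif(1, 0, 0.1), K_v = runif(1, 10, 500),
                 Y = runif(1, 0.1, 1), alpha_B1 = runif(1, 0, 0.01),
                 alpha_B2 = runif(1, 0, 0.01), m_B1 = runif(1, 0, 0.01),
                 m_B2 = runif(1, 0, 0.01), R_SD = runif(1, 0, 0.2),
                 R_SA = runif(1, 0, 0.2), K_S = runif(1, 0.05, 1),
                 st_S = runif(1, 0.5, 5))
}

# A tiny well-formed count table for I/O tests.
write_fixture_counts <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      sample_id = "S1", habitat = "snow", incubation = "in_situ",
      incubation_time_days = 1, replicate = "r1",
      field_of_view = 1:3,
      dapi_count = c(100L, 20L, 40L),
      boncat_count = c(50L, 17L, 0L))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
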