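# Shared fixtures and independent oracles for the test suite.

ref_sys <- function() system_parameters()
ref_drug <- function() drug_parameters()
ref_phys <- function(TBW = 90) {
  derive_patient_physiology(TBW, ref_sys(), ref_drug()$fd)
}

# Direct transcription of the model's concentration-form differential
# equations, independent of the compiled rate-matrix assembly. Returns
# the derivative of the concentration state (plus the EVD bag amount).
conc_derivative_oracle <- function(conc, sys, drug, phys, Q_EVD,
                                   input_rate = 0) {
  Qsink <- max(sys$Q_sink_physio - Q_EVD, 0)
  fdCO <- drug$fd * sys$CO
  with(as.list(conc), c(
    C_B = (input_rate + fdCO * C_tissue / drug$Kp +
             sys$Q_brain * C_brain_vasc -
             C_B * (fdCO + sys$Q_brain + drug$CL)) / sys$V_blood,
    C_tissue = fdCO * (C_B - C_tissue / drug$Kp) / phys$V_tissue,
    C_brain_vasc = (sys$Q_brain * C_B + drug$PS_ECF * C_ECF +
                      C_CSF * (drug$PS_CSF + Qsink) -
                      C_brain_vasc * (sys$Q_brain + drug$PS_ECF +
                                        drug$PS_CSF)) / sys$V_brain_vasc,
    C_ECF = (C_brain_vasc * drug$PS_ECF -
               C_ECF * (drug$PS_ECF + sys$Q_bulk)) / sys$V_ECF,
    C_CSF = (C_brain_vasc * drug$PS_CSF + C_ECF * sys$Q_bulk -
               C_CSF * (drug$PS_CSF + Qsink + Q_EVD)) / sys$V_CSF,
    A_EVD = C_CSF * Q_EVD))
}

# Adaptive ODE-solver backend (deSolve), used as the independent
# cross-check of the matrix-exponential propagation.
ode_oracle <- function(sys, drug, phys, regimen, Q_EVD = 0, times,
                       rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, parms) {
    t_in <- t %% regimen$tau
    on <- regimen$steady_state || t < regimen$n_doses * regimen$tau
    rate <- if (on && t_in < regimen$infusion_duration)
      regimen$dose / regimen$infusion_duration else 0
    list(conc_derivative_oracle(y, sys, drug, phys, Q_EVD, rate))
  }
  y0 <- c(C_B = 0, C_tissue = 0, C_brain_vasc = 0, C_ECF = 0, C_CSF = 0,
          A_EVD = 0)
  as.data.frame(deSolve::lsoda(
    y0, times, rhs, parms = NULL, rtol = rtol, atol = atol))
}

# Cached heavy fixtures (computed at most once per test file).
.fixture_env <- new.env()

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(cohort_design(),
                                           population_truth(), seed = 1)
  .fixture_env$cohort
}

fixture_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- fit_population(fixture_cohort())
  .fixture_env$fit
}
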