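# A tiny two-subject cohort keeps the optimisation-heavy tests fast.
tiny_cohort <- function(seed = 3) {
  generate_cohort(cohort_design(n_microdialysis = 1, n_evd = 1),
                  population_truth(), seed = seed)
}

# Noise-free, variability-free truth for exactness checks.
exact_truth <- function(...) {
  population_truth(cv_CL = 0, sigma_prop_plasma = 0, sigma_add_plasma = 0,
                   sigma_prop_ecf = 0, sigma_prop_csf = 0, ...)
}

test_that("the conditional log-likelihood matches its closed form at
           zero residuals", {
  d <- generate_cohort(cohort_design(n_microdialysis = 1, n_evd = 1),
                       exact_truth(), seed = 1)
  sub <- d[d$ID == 1, ]
  obs <- sub[!is.na(sub$DV), ]
  theta <- list(CL = 7.28, Kp = 0.796, PS_ECF = 6.4, PS_CSF = 3.2)
  sg <- c(prop_plasma = 0.15, add_plasma = 1, prop_ecf = 0.2,
          prop_csf = 0.25)
  ll <- individual_loglik(sub, theta, eta_CL = 0, sigmas = sg)
  # DV equals the model prediction, so only the normalising terms remain
  v <- ifelse(obs$STREAM == "plasma_unbound",
              sg[["prop_plasma"]]^2 * obs$DV^2 + sg[["add_plasma"]]^2,
              ifelse(obs$STREAM == "dialysate",
                     sg[["prop_ecf"]]^2 * obs$DV^2,
                     sg[["prop_csf"]]^2 * obs$DV^2))
  expect_equal(ll, -0.5 * sum(log(2 * pi * v)), tolerance = 1e-10)

  # doubling a purely additive sigma drops the plasma terms by log(2) each
  sg0 <- sg; sg0[["prop_plasma"]] <- 0
  ll1 <- individual_loglik(sub, theta, 0, sg0)
  sg2 <- sg0; sg2[["add_plasma"]] <- 2
  ll2 <- individual_loglik(sub, theta, 0, sg2)
  n_plasma <- sum(obs$STREAM == "plasma_unbound")
  expect_equal(ll1 - ll2, n_plasma * log(2), tolerance = 1e-10)

  # a clearly wrong clearance fits worse
  ll_wrong <- individual_loglik(sub, list(CL = 20, Kp = 0.796,
                                          PS_ECF = 6.4, PS_CSF = 3.2),
                                0, sg)
  expect_lt(ll_wrong, ll)
})

test_that("the Laplace marginal likelihood matches adaptive quadrature", {
  d <- tiny_cohort()
  truth <- population_truth()
  sys <- system_parameters(); drug <- drug_parameters()
  reg <- dosing_regimen()
  designs <- cnspbpk:::.subject_designs(d, sys, drug, reg)
  th <- cnspbpk:::.make_theta(truth$CL, truth$Kp, truth$PS_ECF,
                              truth$PS_CSF, truth$omega_CL, truth$sigmas)
  lap <- cnspbpk:::.laplace_nll_cpp(designs, th, rep(0, length(designs)))
  for (s in seq_along(designs)) {
    cond <- function(e) cnspbpk:::.subject_cond_nll_cpp(designs[[s]], th, e)
    # exact marginal: integrate p(y|eta) * N(eta; 0, omega^2) over eta
    f0 <- cond(0)
    integrand <- Vectorize(function(e)
      exp(-(cond(e) - f0)) * dnorm(e, 0, truth$omega_CL))
    # +/- 4 covers > 11 prior standard deviations
    exact <- f0 - log(integrate(integrand, -4, 4,
                                rel.tol = 1e-10)$value)
    expect_equal(lap$nll_subject[s], exact, tolerance = 0.01)
  }
})

test_that("low-noise data recover the generating parameters almost
           exactly", {
  truth <- population_truth(cv_CL = 1, sigma_prop_plasma = 0.01,
                            sigma_add_plasma = 0.05,
                            sigma_prop_ecf = 0.01, sigma_prop_csf = 0.01)
  d <- generate_cohort(cohort_design(), truth, seed = 5)
  f <- fit_population(d, seed = 5)
  expect_lt(abs(f$theta[["CL"]] - truth$CL) / truth$CL, 0.01)
  expect_lt(abs(f$theta[["Kp"]] - truth$Kp) / truth$Kp, 0.02)
})

test_that("estimate_PS mode recovers the barrier-clearance ratio", {
  # generated at a low permeability with the 2:1 ECF:CSF ratio; noise is
  # reduced so 8 subjects identify the barrier clearances
  truth <- population_truth(PS_ECF = 0.4, PS_CSF = 0.2, cv_CL = 10,
                            sigma_prop_plasma = 0.05,
                            sigma_add_plasma = 0.2,
                            sigma_prop_ecf = 0.08, sigma_prop_csf = 0.08)
  d <- generate_cohort(cohort_design(), truth, seed = 7)
  f <- fit_population(d, estimate_PS = TRUE, seed = 7)
  ratio <- f$theta[["PS_ECF"]] / f$theta[["PS_CSF"]]
  expect_gt(ratio, 1.4); expect_lt(ratio, 2.8)
  expect_lt(abs(f$theta[["PS_ECF"]] - truth$PS_ECF) / truth$PS_ECF, 0.5)
})

test_that("fitting refuses datasets with fewer than two subjects", {
  d <- tiny_cohort()
  expect_error(fit_population(d[d$ID == 1, ]), "at least 2 subjects")
})

test_that("the bootstrap is seed-reproducible and guards its inputs", {
  d <- tiny_cohort()
  ctrl <- list(triage_maxit = 150, maxit = 400, reltol = 1e-6)
  f <- fit_population(d, n_restarts = 1, control = ctrl)
  expect_error(bootstrap_ci(d[d$ID == 1, ], f), "at least 2 subjects")
  b1 <- bootstrap_ci(d, f, n_boot = 4, seed = 9, control = ctrl)
  b2 <- bootstrap_ci(d, f, n_boot = 4, seed = 9, control = ctrl)
  expect_identical(b1$ci, b2$ci)
  expect_equal(nrow(b1$replicates) + b1$n_failed, 4)
  expect_true(all(b1$ci[, 1] <= b1$ci[, 2]))
})

test_that("fold errors behave as ratios", {
  expect_equal(fold_error(2, 2), 1)
  expect_equal(fold_error(4, 2), 2)
  expect_equal(fold_error(c(1, 4), c(2, 2)), c(0.5, 2))
  # geometric mean: reciprocal pairs cancel
  expect_equal(mean_fold_error(c(1, 4), c(2, 2)), 1)
  expect_error(fold_error(-1, 1), "positive")
})

test_that("fitted predictions align with the generating model", {
  truth <- exact_truth()
  d <- generate_cohort(cohort_design(n_microdialysis = 1, n_evd = 1),
                       truth, seed = 2)
  # at the truth with eta = 0, predictions must equal the noise-free DVs
  sys <- system_parameters(); drug <- drug_parameters()
  reg <- dosing_regimen()
  designs <- cnspbpk:::.subject_designs(d, sys, drug, reg)
  th <- cnspbpk:::.make_theta(truth$CL, truth$Kp, truth$PS_ECF,
                              truth$PS_CSF, 0.3,
                              c(prop_plasma = 0.1, add_plasma = 0.1,
                                prop_ecf = 0.1, prop_csf = 0.1))
  for (s in seq_along(designs)) {
    pred <- as.numeric(cnspbpk:::.subject_pred_cpp(designs[[s]], th, 0))
    expect_equal(pred, designs[[s]]$dv, tolerance = 1e-8)
  }
})
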