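test_that("parameter constructors validate their inputs", {
  expect_s3_class(system_parameters(), "system_parameters")
  expect_error(system_parameters(CO = -1), "positive")
  expect_error(system_parameters(Q_brain = 400), "smaller than cardiac")
  expect_error(drug_parameters(CL = -1), "non-negative")
  expect_error(drug_parameters(Kp = 0), "Kp")
  expect_error(drug_parameters(fd = 1.2), "fd")
  # PS_CSF defaults to half of PS_ECF
  expect_equal(drug_parameters(PS_ECF = 5)$PS_CSF, 2.5)
})

test_that("patient physiology follows the volume and flow balances", {
  sys <- ref_sys()
  phys <- derive_patient_physiology(90, sys, fd = 0.86)
  expect_equal(phys$V_tissue,
               90 - sys$V_blood - sys$V_brain_vasc - sys$V_ECF - sys$V_CSF)
  expect_equal(phys$fd_brain, sys$Q_brain / sys$CO)
  # volume balance violation (TBW smaller than the fixed volumes)
  expect_error(derive_patient_physiology(5, sys), "volume balance")
  # flow-fraction constraint: fd + Q_brain/CO must not exceed 1
  expect_error(derive_patient_physiology(90, sys, fd = 0.9),
               "flow-fraction")
})

test_that("effective sink flow is floored at zero", {
  expect_equal(effective_sink_flow(0, 0.024), 0.024)
  expect_equal(effective_sink_flow(0.01, 0.024), 0.014)
  expect_equal(effective_sink_flow(0.04, 0.024), 0)
  expect_equal(effective_sink_flow(c(0, 0.05), 0.024), c(0.024, 0))
  expect_error(effective_sink_flow(-0.01, 0.024), "non-negative")
})

test_that("the transfer matrix reproduces the printed equations", {
  sys <- ref_sys(); drug <- ref_drug(); phys <- ref_phys()
  for (q in c(0, 0.01, 0.04)) {
    tm <- build_transfer_matrix(sys, drug, phys, Q_EVD = q)
    vols <- c(sys$V_blood, phys$V_tissue, sys$V_brain_vasc, sys$V_ECF,
              sys$V_CSF, 1)
    set.seed(42)
    for (k in 1:5) {
      conc <- stats::setNames(c(runif(5, 0.1, 10), 0),
                              c("C_B", "C_tissue", "C_brain_vasc",
                                "C_ECF", "C_CSF", "A_EVD"))
      rate <- if (k %% 2) 1000 else 0
      # amount-space derivative back to concentration space
      amounts <- conc * vols
      d_amounts <- as.numeric(tm$A %*% amounts) + tm$input * rate
      d_conc <- d_amounts / vols
      oracle <- conc_derivative_oracle(conc, sys, drug, phys, q, rate)
      expect_equal(unname(d_conc), unname(oracle), tolerance = 1e-12)
    }
  }
})

test_that("the transfer matrix conserves mass and is stable", {
  sys <- ref_sys(); phys <- ref_phys()
  # without clearance every column sums to zero (the EVD bag is a state)
  tm0 <- build_transfer_matrix(sys, drug_parameters(CL = 0), phys,
                               Q_EVD = 0.03)
  expect_lt(max(abs(colSums(tm0$A))), 1e-12)
  # with clearance the only column deficit is CL on the blood column
  drug <- ref_drug()
  tm <- build_transfer_matrix(sys, drug, phys, Q_EVD = 0.03)
  deficit <- -colSums(tm$A) * c(sys$V_blood, phys$V_tissue,
                                sys$V_brain_vasc, sys$V_ECF, sys$V_CSF, 1)
  expect_equal(unname(deficit), c(drug$CL, 0, 0, 0, 0, 0),
               tolerance = 1e-10)
  # stability: no eigenvalue with positive real part
  expect_lt(max(Re(eigen(tm$A, only.values = TRUE)$values)), 1e-12)
})

test_that("zero barrier permeability makes the CNS unreachable", {
  sys <- ref_sys(); phys <- ref_phys()
  drug <- drug_parameters(PS_ECF = 0, PS_CSF = 0)
  sim <- simulate_pbpk(sys, drug, phys,
                       dosing_regimen(steady_state = FALSE, n_doses = 1),
                       dt = 0.5, horizon = 8)
  expect_true(all(sim$C_ECF == 0))
  expect_true(all(sim$C_CSF == 0))
  expect_true(any(sim$C_B > 0))
})

test_that("EVD schedules are validated", {
  s <- evd_schedule(c(0, 1), c(1, 2), 0.02)
  expect_equal(s$V_EVD, c(0.02, 0.02))
  expect_error(evd_schedule(c(0, 0.5), c(1, 1.5), 0.02), "overlap")
  expect_error(evd_schedule(1, 1, 0.02), "t_end > t_start")
  expect_warning(evd_schedule(0, 1, 0.02, V_EVD = 0.05), "inconsistent")
  # consistent V_EVD passes silently
  expect_silent(evd_schedule(0, 1, 0.02, V_EVD = 0.02))
})

test_that("model configuration round-trips through JSON and YAML", {
  cfg <- list(CL = 5.5, Kp = 0.9, CO = 300, Q_brain = 40, PS_ECF = 2)
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jf, auto_unbox = TRUE, digits = NA)
  got <- read_model_config(jf)
  expect_equal(got$drug$CL, 5.5)
  expect_equal(got$drug$PS_CSF, 1)  # halving default applies
  expect_equal(got$sys$CO, 300)
  expect_equal(got$sys$Q_bulk, 0.0105)  # untouched default

  yf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfg), yf)
  got2 <- read_model_config(yf)
  expect_equal(got2$drug$CL, got$drug$CL)
  expect_equal(got2$sys$CO, got$sys$CO)
  expect_error(read_model_config("x.txt"), "json")
})
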