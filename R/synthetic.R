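# Seeded synthetic cohorts emulating the sparse neuro-ICU study design:
# steady-state 500 mg q8h 30-min infusions, 7-13 plasma samples per
# subject, CNS fractions collected at 0.5-h intervals early and 1-h
# intervals out to 8 h, half the cohort monitored by microdialysis
# (brain ECF) and half by an external ventricular drain (CSF).

#' Synthetic cohort design
#'
#' @param n_microdialysis Subjects monitored by brain microdialysis.
#' @param n_evd Subjects monitored via an external ventricular drain.
#' @param dose,tau,infusion_duration Regimen: dose (mg), interdose
#'   interval (h), infusion duration (h).
#' @param n_plasma_range Range (min, max) of plasma samples per subject.
#' @param cns_fine_until CNS fractions at `cns_fine_dt` spacing up to this
#'   time (h), then 1-h intervals to `cns_end`.
#' @param cns_fine_dt Early CNS collection-interval length (h).
#' @param cns_end End of CNS sampling (h).
#' @param qevd_range Range of per-interval drain flows (L/h).
#' @param recovery_range Range of in vivo probe recovery fractions.
#' @param weight_range Body-weight range (kg) for uniform draws.
#' @param weights Optional fixed body-weight vector (recycled over
#'   subjects) replacing the uniform draw.
#' @param vevd_jitter Relative SD of log-normal jitter applied to the
#'   nominal `V_EVD = Q_EVD * dt` sample volumes (0 = exactly consistent).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_microdialysis = 4, n_evd = 4, dose = 500,
                          tau = 8, infusion_duration = 0.5,
                          n_plasma_range = c(7, 13),
                          cns_fine_until = 3, cns_fine_dt = 0.5,
                          cns_end = 8,
                          qevd_range = c(0.001, 0.04),
                          recovery_range = c(0.2, 0.8),
                          weight_range = c(75, 115),
                          weights = NULL, vevd_jitter = 0) {
  if (n_microdialysis < 0 || n_evd < 0 || n_microdialysis + n_evd < 1)
    stop("need at least one subject", call. = FALSE)
  if (infusion_duration > tau)
    stop("infusion_duration must not exceed tau", call. = FALSE)
  if (cns_end > tau + 1e-9)
    stop("CNS sampling must end within the dosing interval", call. = FALSE)
  structure(list(n_microdialysis = n_microdialysis, n_evd = n_evd,
                 dose = dose, tau = tau,
                 infusion_duration = infusion_duration,
                 n_plasma_range = n_plasma_range,
                 cns_fine_until = cns_fine_until,
                 cns_fine_dt = cns_fine_dt, cns_end = cns_end,
                 qevd_range = qevd_range,
                 recovery_range = recovery_range,
                 weight_range = weight_range, weights = weights,
                 vevd_jitter = vevd_jitter),
            class = "cohort_design")
}

#' Generating (truth) values for synthetic cohorts
#'
#' Defaults are the fitted population values for metronidazole: CL 7.28
#' L/h with 35.2 %CV between-subject variability, Kp 0.796, barrier
#' clearances 6.4/3.2 L/h, combined residual error for plasma (14.4%
#' proportional + 1.18 mg/L additive) and proportional error for the
#' dialysate (22.8%) and EVD (28.2%) streams.
#'
#' @param CL,Kp,PS_ECF,PS_CSF,fd Population parameters (see
#'   [drug_parameters()]).
#' @param cv_CL Between-subject variability on CL as %CV; converted to the
#'   log-normal SD `omega = sqrt(log(1 + (cv/100)^2))`.
#' @param sigma_prop_plasma,sigma_add_plasma Plasma residual error
#'   (fraction; mg/L).
#' @param sigma_prop_ecf,sigma_prop_csf Proportional residual error for
#'   the dialysate and EVD streams (fractions).
#' @return An object of class `population_truth`.
#' @export
population_truth <- function(CL = 7.28, Kp = 0.796, cv_CL = 35.2,
                             PS_ECF = 6.4, PS_CSF = PS_ECF / 2, fd = 0.86,
                             sigma_prop_plasma = 0.144,
                             sigma_add_plasma = 1.18,
                             sigma_prop_ecf = 0.228,
                             sigma_prop_csf = 0.282) {
  structure(list(CL = CL, Kp = Kp, cv_CL = cv_CL,
                 omega_CL = sqrt(log(1 + (cv_CL / 100)^2)),
                 PS_ECF = PS_ECF, PS_CSF = PS_CSF, fd = fd,
                 sigmas = c(prop_plasma = sigma_prop_plasma,
                            add_plasma = sigma_add_plasma,
                            prop_ecf = sigma_prop_ecf,
                            prop_csf = sigma_prop_csf)),
            class = "population_truth")
}

# Draw a strictly positive noisy observation (redraw on non-positive).
.noisy_obs <- function(pred, prop_sd, add_sd = 0) {
  for (i in 1:200) {
    dv <- pred * (1 + stats::rnorm(1, 0, prop_sd)) +
      if (add_sd > 0) stats::rnorm(1, 0, add_sd) else 0
    if (dv > 0) return(dv)
  }
  stop("could not draw a positive observation (pred = ", signif(pred, 3),
       ")", call. = FALSE)
}

#' Generate a seeded synthetic cohort
#'
#' Simulates each subject's steady-state profile at their individual
#' clearance `CL_i = CL * exp(eta)`, `eta ~ N(0, omega^2)`, evaluates the
#' observation models at the design's sampling scheme and adds residual
#' noise, returning a long-format dataset in the [read_pk_dataset()]
#' dialect. Fully reproducible by `seed`.
#'
#' @param design A [cohort_design()].
#' @param truth A [population_truth()].
#' @param sys A [system_parameters()] object.
#' @param seed RNG seed.
#' @return A dataset `data.frame` (see [read_pk_dataset()]).
#' @export
#' @examples
#' d <- generate_cohort(cohort_design(), population_truth(), seed = 1)
#' table(d$STREAM[!is.na(d$DV)])
generate_cohort <- function(design = cohort_design(),
                            truth = population_truth(),
                            sys = system_parameters(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(truth, "population_truth"))
  set.seed(seed)
  regimen <- dosing_regimen(design$dose, design$infusion_duration,
                            design$tau)
  n <- design$n_microdialysis + design$n_evd
  groups <- rep(c("dialysate", "evd"),
                c(design$n_microdialysis, design$n_evd))
  wts <- if (!is.null(design$weights)) rep_len(design$weights, n)
         else stats::runif(n, design$weight_range[1],
                           design$weight_range[2])

  plasma_cand <- c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7,
                   design$tau)
  cns_bounds <- unique(c(seq(0, design$cns_fine_until,
                             by = design$cns_fine_dt),
                         seq(ceiling(design$cns_fine_until),
                             design$cns_end, by = 1)))

  rows <- list()
  for (i in seq_len(n)) {
    eta <- stats::rnorm(1, 0, truth$omega_CL)
    drug_i <- drug_parameters(CL = truth$CL * exp(eta), Kp = truth$Kp,
                              PS_ECF = truth$PS_ECF,
                              PS_CSF = truth$PS_CSF, fd = truth$fd)
    phys_i <- derive_patient_physiology(wts[i], sys, truth$fd)
    n_p <- sample(seq(design$n_plasma_range[1],
                      min(design$n_plasma_range[2],
                          length(plasma_cand))), 1)
    t_plasma <- sort(sample(plasma_cand, n_p))
    t1 <- utils::head(cns_bounds, -1); t2 <- utils::tail(cns_bounds, -1)
    qevd_i <- if (groups[i] == "evd") {
      stats::runif(length(t1), design$qevd_range[1],
                   design$qevd_range[2])
    } else rep(0, length(t1))
    vevd_i <- qevd_i * (t2 - t1)
    if (design$vevd_jitter > 0 && groups[i] == "evd")
      vevd_i <- vevd_i * exp(stats::rnorm(length(vevd_i), 0,
                                          design$vevd_jitter))
    evd_sched <- if (groups[i] == "evd") evd_schedule(t1, t2, qevd_i)
                 else NULL
    sim <- simulate_pbpk(sys, drug_i, phys_i, regimen, evd = evd_sched,
                         dt = design$tau, # breaks come from times_extra
                         times_extra = unique(c(t_plasma, cns_bounds)))
    sg <- truth$sigmas

    dose_row <- data.frame(ID = i, TIME = 0, T1 = NA, T2 = NA, DV = NA,
                           STREAM = NA, AMT = design$dose,
                           RATE = design$dose / design$infusion_duration,
                           QEVD = NA, VEVD = NA, RECOVERY = NA,
                           WT = wts[i])
    pl <- data.frame(
      ID = i, TIME = t_plasma, T1 = NA, T2 = NA,
      DV = vapply(t_plasma, function(t)
        .noisy_obs(sim$C_B[.sim_index(sim, t)], sg[["prop_plasma"]],
                   sg[["add_plasma"]]), numeric(1)),
      STREAM = "plasma_unbound", AMT = NA, RATE = NA, QEVD = NA,
      VEVD = NA, RECOVERY = NA, WT = wts[i])
    if (groups[i] == "dialysate") {
      rec <- stats::runif(1, design$recovery_range[1],
                          design$recovery_range[2])
      cns <- data.frame(
        ID = i, TIME = NA, T1 = t1, T2 = t2,
        DV = vapply(seq_along(t1), function(j)
          .noisy_obs(dialysate_prediction(sim, t1[j], t2[j]),
                     sg[["prop_ecf"]]), numeric(1)),
        STREAM = "dialysate", AMT = NA, RATE = NA, QEVD = NA, VEVD = NA,
        RECOVERY = rec, WT = wts[i])
    } else {
      cns <- data.frame(
        ID = i, TIME = NA, T1 = t1, T2 = t2,
        DV = vapply(seq_along(t1), function(j)
          .noisy_obs(evd_prediction(sim, t1[j], t2[j], qevd_i[j],
                                    vevd_i[j]),
                     sg[["prop_csf"]]), numeric(1)),
        STREAM = "evd", AMT = NA, RATE = NA, QEVD = qevd_i,
        VEVD = vevd_i, RECOVERY = NA, WT = wts[i])
    }
    rows[[i]] <- rbind(dose_row, pl, cns)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  validate_pk_dataset(out)
}

#' Low-permeability drug scenario
#'
#' Builds a hypothetical drug parameter set sharing the physicochemical
#' profile of a low-permeability antibiotic (cefotaxime-like defaults,
#' MW 455 g/mol, log P -1.5; metadata only — no permeability prediction is
#' made from them) with user-chosen barrier clearances. `PS_CSF` follows
#' the half-surface-area rule unless given.
#'
#' @param base A [drug_parameters()] template.
#' @param PS_ECF BBB clearance (L/h) before scaling; defaults to the
#'   template value.
#' @param PS_scale Multiplicative factor applied to `PS_ECF`.
#' @param MW,logP Physicochemical metadata.
#' @return A [drug_parameters()] object.
#' @export
#' @examples
#' low_permeability_drug(PS_ECF = 0.1)  # PS_CSF = 0.05 by the halving rule
low_permeability_drug <- function(base = drug_parameters(), PS_ECF = NULL,
                                  PS_scale = 1, MW = 455, logP = -1.5) {
  if (PS_scale <= 0) stop("PS_scale must be positive", call. = FALSE)
  ps <- (if (is.null(PS_ECF)) base$PS_ECF else PS_ECF) * PS_scale
  drug_parameters(CL = base$CL, Kp = base$Kp, PS_ECF = ps,
                  PS_CSF = ps_csf_from_ps_ecf(ps), fd = base$fd,
                  fu = base$fu, BP_ratio = base$BP_ratio,
                  MW = if (is.null(PS_ECF) && PS_scale == 1) base$MW
                       else MW,
                  logP = if (is.null(PS_ECF) && PS_scale == 1) base$logP
                         else logP)
}
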