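# One-at-a-time sensitivity analyses: pathophysiological parameter
# changes (barrier permeability, ECF volume, cerebral blood flow) and
# external-ventricular-drain flow. Profiles use a single 500 mg / 30-min
# infusion; exposures are AUCs over 0-24 h (well past five half-lives at
# the reference clearance).

.single_dose_regimen <- function(dose = 500, infusion_duration = 0.5,
                                 tau = 8) {
  dosing_regimen(dose = dose, infusion_duration = infusion_duration,
                 tau = tau, steady_state = FALSE, n_doses = 1)
}

# ECF/CSF AUC over [0, horizon] from the exact cumulative integrals.
.cns_auc <- function(sim, horizon) {
  i <- .sim_index(sim, horizon, "horizon")
  sys <- attr(sim, "sys")
  c(ECF = sim$cumint_ECF[i] / sys$V_ECF,
    CSF = sim$cumint_CSF[i] / sys$V_CSF)
}

#' One-at-a-time sweep of pathophysiological parameter changes
#'
#' Simulates a single intravenous infusion per scenario, varying exactly
#' one of: the barrier clearances (`PS_ECF` and `PS_CSF` scaled together,
#' brain-injury range up to 5-fold), the brain ECF volume (oedema, up to
#' 1.4-fold) or the cerebral blood flow (hypoperfusion, down to 0.2-fold),
#' while all other parameters stay at their reference values, and reports
#' the ECF and CSF AUC deviation from baseline.
#'
#' @param sys,drug,phys Reference model objects.
#' @param factors Named list of multiplicative factor grids for `PS`,
#'   `V_ECF` and `Q_brain` (each must be positive).
#' @param dose,infusion_duration Single-dose regimen (mg; h).
#' @param horizon AUC horizon (h).
#' @param dt Output grid spacing (h).
#' @return A `data.frame` (class `pbpk_sweep`) with one row per scenario:
#'   `parameter`, `factor`, `ECF_AUC`, `CSF_AUC`, `pct_dev_ECF`,
#'   `pct_dev_CSF`; scenario parameter sets are attached as the
#'   `"scenarios"` attribute. Simulated profiles are attached as
#'   `"profiles"`.
#' @export
sweep_pathophysiology <- function(sys, drug, phys,
                                  factors = list(
                                    PS = c(1, 2, 3, 4, 5),
                                    V_ECF = c(1, 1.05, 1.2, 1.4),
                                    Q_brain = c(1, 0.7, 0.4, 0.2)),
                                  dose = 500, infusion_duration = 0.5,
                                  horizon = 24, dt = 0.1) {
  if (any(unlist(factors) <= 0))
    stop("all sweep factors must be positive", call. = FALSE)
  regimen <- .single_dose_regimen(dose, infusion_duration)
  base_sim <- simulate_pbpk(sys, drug, phys, regimen, dt = dt,
                            horizon = horizon)
  base_auc <- .cns_auc(base_sim, horizon)

  rows <- list(); scen <- list(); prof <- list()
  for (par in names(factors)) {
    for (f in factors[[par]]) {
      sys_i <- sys; drug_i <- drug
      if (par == "PS") {
        drug_i$PS_ECF <- drug$PS_ECF * f
        drug_i$PS_CSF <- drug$PS_CSF * f
      } else if (par == "V_ECF") {
        sys_i$V_ECF <- sys$V_ECF * f
      } else if (par == "Q_brain") {
        sys_i$Q_brain <- sys$Q_brain * f
      } else stop("unknown sweep parameter '", par, "'", call. = FALSE)
      sim <- simulate_pbpk(sys_i, drug_i, phys, regimen, dt = dt,
                           horizon = horizon)
      auc <- .cns_auc(sim, horizon)
      lab <- sprintf("%s_x%g", par, f)
      rows[[lab]] <- data.frame(
        parameter = par, factor = f,
        ECF_AUC = auc[["ECF"]], CSF_AUC = auc[["CSF"]],
        pct_dev_ECF = 100 * (auc[["ECF"]] - base_auc[["ECF"]]) /
          base_auc[["ECF"]],
        pct_dev_CSF = 100 * (auc[["CSF"]] - base_auc[["CSF"]]) /
          base_auc[["CSF"]])
      scen[[lab]] <- list(parameter = par, factor = f, sys = sys_i,
                          drug = drug_i)
      prof[[lab]] <- sim
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out, class = c("pbpk_sweep", "data.frame"),
            baseline = base_auc, scenarios = scen, profiles = prof,
            horizon = horizon)
}

#' Sweep of the external ventricular drain flow
#'
#' Simulates single-dose CSF profiles over a grid of drain flows
#' (including the no-drain case), applying the effective sink-flow
#' coupling (sink floored at zero once the drain exceeds the
#' physiological reabsorption), and additionally reports the steady-state
#' fraction of the maintenance dose recovered in the collection bag.
#'
#' @param sys,drug,phys Reference model objects.
#' @param Q_EVD Grid of drain flows (L/h), `>= 0`.
#' @param dose,infusion_duration,tau Regimen (mg; h; h).
#' @param horizon Single-dose AUC horizon (h).
#' @param dt Output grid spacing (h).
#' @return A `data.frame` (class `pbpk_evd_sweep`): `Q_EVD`, effective
#'   `Q_sink`, single-dose `CSF_AUC` and `pct_dev_CSF` versus the
#'   no-drain scenario, and the steady-state `dose_fraction_pct` drained
#'   to the bag per interval. Profiles attached as `"profiles"`.
#' @export
sweep_evd <- function(sys, drug, phys, Q_EVD = c(0, 0.001, 0.02, 0.04),
                      dose = 500, infusion_duration = 0.5, tau = 8,
                      horizon = 24, dt = 0.1) {
  if (any(Q_EVD < 0)) stop("Q_EVD must be non-negative", call. = FALSE)
  Q_EVD <- sort(unique(c(0, Q_EVD)))
  regimen_sd <- .single_dose_regimen(dose, infusion_duration, tau)
  regimen_ss <- dosing_regimen(dose, infusion_duration, tau)
  rows <- list(); prof <- list()
  for (q in Q_EVD) {
    sim <- simulate_pbpk(sys, drug, phys, regimen_sd,
                         evd = if (q > 0) evd_schedule(0, horizon, q),
                         dt = dt, horizon = horizon)
    ss <- simulate_pbpk(sys, drug, phys, regimen_ss,
                        evd = if (q > 0) evd_schedule(0, tau, q),
                        dt = dt)
    lab <- sprintf("QEVD_%g", q)
    rows[[lab]] <- data.frame(
      Q_EVD = q,
      Q_sink = effective_sink_flow(q, sys$Q_sink_physio),
      CSF_AUC = .cns_auc(sim, horizon)[["CSF"]],
      dose_fraction_pct = evd_dose_fraction(ss, q))
    prof[[lab]] <- sim
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  base <- out$CSF_AUC[out$Q_EVD == 0]
  out$pct_dev_CSF <- 100 * (out$CSF_AUC - base) / base
  structure(out, class = c("pbpk_evd_sweep", "data.frame"),
            profiles = prof, horizon = horizon)
}
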