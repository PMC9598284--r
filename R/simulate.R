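#' Intermittent intravenous infusion regimen
#'
#' @param dose Dose per administration (mg).
#' @param infusion_duration Infusion duration (h).
#' @param tau Interdose interval (h).
#' @param steady_state If `TRUE` (default) the simulation returns one
#'   interval of the periodic steady-state solution.
#' @param n_doses Number of doses when `steady_state = FALSE`.
#' @return An object of class `dosing_regimen`.
#' @export
#' @examples
#' dosing_regimen()                    # 500 mg q8h, 30-min infusion, at SS
#' dosing_regimen(steady_state = FALSE, n_doses = 1)
dosing_regimen <- function(dose = 500, infusion_duration = 0.5, tau = 8,
                           steady_state = TRUE, n_doses = NULL) {
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (infusion_duration <= 0 || infusion_duration > tau)
    stop("infusion_duration must lie in (0, tau]", call. = FALSE)
  if (!steady_state && (is.null(n_doses) || n_doses < 1))
    stop("n_doses must be given (>= 1) when steady_state = FALSE",
         call. = FALSE)
  structure(list(dose = dose, infusion_duration = infusion_duration,
                 tau = tau, steady_state = steady_state,
                 n_doses = if (steady_state) NULL else as.integer(n_doses)),
            class = "dosing_regimen")
}

# Normalise the EVD argument into a schedule data.frame covering [0, horizon].
.evd_as_schedule <- function(evd, horizon) {
  if (is.null(evd)) return(NULL)
  if (inherits(evd, "evd_schedule")) return(evd)
  if (is.numeric(evd) && length(evd) == 1L) {
    if (evd == 0) return(NULL)
    return(evd_schedule(0, horizon, evd))
  }
  stop("evd must be NULL, a single flow (L/h) or an evd_schedule",
       call. = FALSE)
}

# Piecewise-constant segment description between consecutive breaks.
.segmentize <- function(breaks, regimen, evd_sched, n_doses) {
  dt <- diff(breaks)
  mid <- breaks[-length(breaks)] + dt / 2
  rate <- numeric(length(mid))
  rate_val <- regimen$dose / regimen$infusion_duration
  for (k in seq_len(n_doses) - 1L) {
    on <- mid >= k * regimen$tau & mid < k * regimen$tau +
      regimen$infusion_duration
    rate[on] <- rate_val
  }
  qevd <- numeric(length(mid))
  if (!is.null(evd_sched)) {
    for (i in seq_len(nrow(evd_sched))) {
      on <- mid >= evd_sched$t_start[i] & mid < evd_sched$t_end[i]
      qevd[on] <- evd_sched$Q_EVD[i]
    }
  }
  list(dt = dt, rate = rate, qevd = qevd)
}

.ss_initial_state <- function(pars, regimen, evd_sched) {
  breaks <- sort(unique(c(0, regimen$infusion_duration, regimen$tau,
                          if (!is.null(evd_sched))
                            c(evd_sched$t_start, evd_sched$t_end))))
  breaks <- breaks[breaks >= 0 & breaks <= regimen$tau]
  seg <- .segmentize(breaks, regimen, evd_sched, n_doses = 1L)
  ss <- .steady_state_cpp(pars, seg$dt, seg$rate, seg$qevd)
  if (ss$ok && ss$residual < 1e-8) return(drop(ss$x0))
  # fall back to repeated dosing until the interval map converges
  x <- numeric(9)
  for (i in seq_len(2000)) {
    xn <- .propagate_cpp(pars, x, seg$dt, seg$rate, seg$qevd)
    xn <- xn[nrow(xn), ]
    xn[6:9] <- 0  # EVD bag and integrals restart each interval
    rel <- sqrt(sum((xn[1:5] - x[1:5])^2)) / max(sqrt(sum(xn[1:5]^2)), 1e-300)
    x <- xn
    if (rel < 1e-8) return(x)
  }
  stop("steady state did not converge: periodicity residual ",
       signif(ss$residual, 3), ", repeated-dosing relative change ",
       signif(rel, 3), call. = FALSE)
}

#' Steady-state compartment amounts at the start of a dosing interval
#'
#' Solves the periodicity condition `x(tau) = x(0)` of the piecewise
#' constant-coefficient system exactly from the within-interval propagators;
#' if the periodicity system is singular, falls back to repeated dosing with
#' a relative convergence tolerance of 1e-8.
#'
#' @inheritParams simulate_pbpk
#' @return Named vector of amounts (mg) in blood, tissue, brain vasculature,
#'   ECF, CSF and the EVD bag (zero: the bag restarts each interval).
#' @export
steady_state <- function(sys, drug, phys, regimen = dosing_regimen(),
                         evd = NULL) {
  evd_sched <- .evd_as_schedule(evd, regimen$tau)
  x <- .ss_initial_state(.pack_pars(sys, drug, phys), regimen, evd_sched)
  stats::setNames(x[1:6],
                  c("blood", "tissue", "brain_vasc", "ECF", "CSF", "EVD"))
}

#' Simulate the minimal CNS PBPK model
#'
#' Propagates the linear compartmental system exactly (matrix exponential
#' per constant-coefficient segment, with breaks at infusion on/off times,
#' EVD collection-interval boundaries and every output time). Cumulative
#' time-integrals of the blood, ECF and CSF amounts are carried as extra
#' states, so interval-averaged observations and AUCs are analytic, not
#' grid quadrature.
#'
#' @param sys A [system_parameters()] object.
#' @param drug A [drug_parameters()] object.
#' @param phys A [derive_patient_physiology()] object.
#' @param regimen A [dosing_regimen()]; in steady-state mode one interdose
#'   interval of the periodic solution is returned.
#' @param evd `NULL` (no drain), a constant drain flow (L/h), or an
#'   [evd_schedule()].
#' @param dt Output grid spacing (h).
#' @param horizon Simulation horizon (h); defaults to `tau` at steady state
#'   and `n_doses * tau` otherwise.
#' @param times_extra Additional exact output times (h), e.g. collection
#'   interval bounds.
#' @return A `data.frame` of class `pbpk_sim` with columns `time` (h),
#'   concentrations `C_B`, `C_tissue`, `C_brain_vasc`, `C_ECF`, `C_CSF`
#'   (mg/L), the EVD bag amount `A_EVD` (mg) and cumulative amount-integrals
#'   `cumint_B`, `cumint_ECF`, `cumint_CSF` (mg h).
#' @export
#' @examples
#' sys <- system_parameters()
#' drug <- drug_parameters()
#' phys <- derive_patient_physiology(90, sys, drug$fd)
#' sim <- simulate_pbpk(sys, drug, phys)
#' head(sim)
simulate_pbpk <- function(sys, drug, phys, regimen = dosing_regimen(),
                          evd = NULL, dt = 0.05, horizon = NULL,
                          times_extra = NULL) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (is.null(horizon))
    horizon <- if (regimen$steady_state) regimen$tau
               else regimen$n_doses * regimen$tau
  n_doses <- if (regimen$steady_state) 1L
             else min(regimen$n_doses, ceiling(horizon / regimen$tau))
  evd_sched <- .evd_as_schedule(evd, horizon)
  pars <- .pack_pars(sys, drug, phys)

  dose_times <- (seq_len(n_doses) - 1L) * regimen$tau
  breaks <- c(seq(0, horizon, by = dt), horizon, dose_times,
              dose_times + regimen$infusion_duration,
              if (!is.null(evd_sched)) c(evd_sched$t_start,
                                         evd_sched$t_end),
              times_extra)
  breaks <- sort(unique(round(breaks, 9)))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]
  seg <- .segmentize(breaks, regimen, evd_sched, n_doses)

  x0 <- if (regimen$steady_state) .ss_initial_state(pars, regimen, evd_sched)
        else numeric(9)

  X <- .propagate_cpp(pars, x0, seg$dt, seg$rate, seg$qevd)
  out <- data.frame(
    time = breaks,
    C_B = X[, 1] / sys$V_blood,
    C_tissue = X[, 2] / phys$V_tissue,
    C_brain_vasc = X[, 3] / sys$V_brain_vasc,
    C_ECF = X[, 4] / sys$V_ECF,
    C_CSF = X[, 5] / sys$V_CSF,
    A_EVD = X[, 6],
    cumint_B = X[, 7],
    cumint_ECF = X[, 8],
    cumint_CSF = X[, 9])
  structure(out,
            class = c("pbpk_sim", "data.frame"),
            sys = sys, drug = drug, phys = phys, regimen = regimen,
            evd = evd_sched)
}

# Locate an exact output time on the simulation grid.
.sim_index <- function(sim, t, what = "time") {
  i <- which(abs(sim$time - t) < 1e-8)
  if (length(i) != 1L)
    stop(what, " = ", t, " h is not on the simulation grid; rerun ",
         "simulate_pbpk() with this value in times_extra", call. = FALSE)
  i
}

#' Predicted microdialysate concentration over a collection interval
#'
#' The recovery-corrected dialysate observation is modelled as the time
#' average of the brain ECF concentration over the collection interval
#' (the interval integral divided by the interval length).
#'
#' @param sim A [simulate_pbpk()] result whose grid contains `t1` and `t2`.
#' @param t1,t2 Collection interval bounds (h), `t1 < t2`.
#' @return Predicted dialysate concentration (mg/L).
#' @export
dialysate_prediction <- function(sim, t1, t2) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  i1 <- .sim_index(sim, t1, "t1"); i2 <- .sim_index(sim, t2, "t2")
  V_ECF <- attr(sim, "sys")$V_ECF
  (sim$cumint_ECF[i2] - sim$cumint_ECF[i1]) / V_ECF / (t2 - t1)
}

#' Predicted EVD collection-bag concentration over an interval
#'
#' The bag fills at rate `C_CSF * Q_EVD`; the measured concentration is the
#' drained amount over the interval divided by the collected volume. When
#' `V_EVD = Q_EVD * (t2 - t1)` this equals the time average of the CSF
#' concentration. With `Q_EVD = 0` no drug reaches the bag and the
#' concentration is undefined (`NA`).
#'
#' @inheritParams dialysate_prediction
#' @param Q_EVD Drain flow during the interval (L/h).
#' @param V_EVD Collected sample volume (L), `> 0`.
#' @return Predicted bag concentration (mg/L), or `NA` when `Q_EVD = 0`.
#' @export
evd_prediction <- function(sim, t1, t2, Q_EVD, V_EVD) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (V_EVD <= 0) stop("V_EVD must be positive", call. = FALSE)
  if (Q_EVD < 0) stop("Q_EVD must be non-negative", call. = FALSE)
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  if (Q_EVD == 0) return(NA_real_)
  i1 <- .sim_index(sim, t1, "t1"); i2 <- .sim_index(sim, t2, "t2")
  V_CSF <- attr(sim, "sys")$V_CSF
  Q_EVD * (sim$cumint_CSF[i2] - sim$cumint_CSF[i1]) / V_CSF / V_EVD
}

#' Linear trapezoidal AUC
#'
#' @param times Strictly increasing sampling times (h), at least two.
#' @param concentrations Concentrations at `times` (mg/L).
#' @return AUC (mg h/L).
#' @export
#' @examples
#' auc_trapezoid(c(0, 1), c(0, 2))  # 1
auc_trapezoid <- function(times, concentrations) {
  if (length(times) < 2L || length(times) != length(concentrations))
    stop("need >= 2 matched time/concentration points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  sum(diff(times) * (utils::head(concentrations, -1) +
                       utils::tail(concentrations, -1)) / 2)
}

#' Fraction of the dose recovered in the EVD bag over one interval
#'
#' At steady state, the percentage of one maintenance dose drained to the
#' collection bag over one interdose interval:
#' `100 * Q_EVD * integral(C_CSF) / dose`.
#'
#' @param sim A steady-state [simulate_pbpk()] result covering `[0, tau]`.
#' @param Q_EVD Drain flow (L/h).
#' @param tau Interdose interval (h); default from the simulated regimen.
#' @param dose Dose (mg); default from the simulated regimen.
#' @return Percent of the dose.
#' @export
evd_dose_fraction <- function(sim, Q_EVD,
                              tau = attr(sim, "regimen")$tau,
                              dose = attr(sim, "regimen")$dose) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (Q_EVD < 0) stop("Q_EVD must be non-negative", call. = FALSE)
  i1 <- .sim_index(sim, 0); i2 <- .sim_index(sim, tau, "tau")
  V_CSF <- attr(sim, "sys")$V_CSF
  100 * Q_EVD * (sim$cumint_CSF[i2] - sim$cumint_CSF[i1]) / V_CSF / dose
}
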