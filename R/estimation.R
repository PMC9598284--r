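# Population (nonlinear mixed-effects) estimation.
#
# The marginal likelihood over the subject-level random effect on CL is
# approximated by the Laplace method with per-subject mode finding, the
# standard conditional-estimation approach for sparse PK data. Between-
# subject variability is log-normal on CL only; residual error is combined
# (proportional + additive) for plasma and proportional for the CNS
# streams.

# theta vector consumed by the compiled core
.make_theta <- function(CL, Kp, PS_ECF, PS_CSF, omega, sigmas) {
  c(CL, Kp, PS_ECF, PS_CSF, omega,
    sigmas[["prop_plasma"]], sigmas[["add_plasma"]],
    sigmas[["prop_ecf"]], sigmas[["prop_csf"]])
}

#' Conditional log-likelihood of one subject's data
#'
#' Gaussian log-likelihood of the subject's observations given the
#' random-effect value `eta_CL` (so `CL_i = CL * exp(eta_CL)`), with
#' residual variance `sigma_prop^2 * pred^2 + sigma_add^2` for plasma and
#' `sigma_prop^2 * pred^2` for the dialysate and EVD streams.
#'
#' @param subject_data Rows of one subject from a [read_pk_dataset()]
#'   dataset.
#' @param theta Named list or vector with `CL`, `Kp`, `PS_ECF`, `PS_CSF`.
#' @param eta_CL Subject-level random effect on log CL.
#' @param sigmas Named vector: `prop_plasma`, `add_plasma`, `prop_ecf`,
#'   `prop_csf` (proportional terms as fractions, additive in mg/L).
#' @param sys A [system_parameters()] object.
#' @param drug Template [drug_parameters()] (supplies `fd`, `fu`, ...).
#' @param regimen A [dosing_regimen()].
#' @return The log-likelihood (a single number).
#' @export
individual_loglik <- function(subject_data, theta, eta_CL, sigmas,
                              sys = system_parameters(),
                              drug = drug_parameters(),
                              regimen = dosing_regimen()) {
  d <- .subject_design(subject_data, sys, drug, regimen)
  th <- .make_theta(theta[["CL"]], theta[["Kp"]], theta[["PS_ECF"]],
                    theta[["PS_CSF"]], omega = 1, sigmas = sigmas)
  nll <- .subject_cond_nll_cpp(d, th, eta_CL)
  if (!is.finite(nll))
    stop("non-finite prediction/likelihood for subject ", d$id,
         call. = FALSE)
  -nll
}

# Naive pooled starting value for CL: dose rate / trapezoidal plasma AUC.
.start_cl <- function(designs, regimen) {
  cls <- vapply(designs, function(d) {
    i <- d$obs_type == 0L
    if (sum(i) < 2L) return(NA_real_)
    o <- order(d$obs_time[i])
    auc <- auc_trapezoid(d$obs_time[i][o], d$dv[i][o])
    # stretch the sampled span to the full interval
    span <- diff(range(d$obs_time[i]))
    if (span <= 0) return(NA_real_)
    regimen$dose / (auc * regimen$tau / span)
  }, numeric(1))
  cl <- stats::median(cls, na.rm = TRUE)
  if (!is.finite(cl) || cl <= 0) cl <- 5
  cl
}

.fit_objective <- function(designs, fixed, estimate_PS, env) {
  function(p) {
    v <- unname(exp(p))
    # plausibility box: reject excursions into degenerate regions
    # (notably omega large enough that the random effect can absorb any
    # systematic misfit of the fixed effects)
    n_str <- if (estimate_PS) 4L else 2L
    if (any(v[seq_len(n_str)] < 1e-4) || any(v[seq_len(n_str)] > 1e4) ||
          v[n_str + 1L] > 4 || v[n_str + 1L] < 1e-5 ||
          any(v[-seq_len(n_str + 1L)] > 100))
      return(1e10)
    if (estimate_PS) {
      theta <- .make_theta(v[1], v[2], v[3], v[4], v[5],
                           c(prop_plasma = v[6], add_plasma = v[7],
                             prop_ecf = v[8], prop_csf = v[9]))
    } else {
      theta <- .make_theta(v[1], v[2], fixed[["PS_ECF"]], fixed[["PS_CSF"]],
                           v[3],
                           c(prop_plasma = v[4], add_plasma = v[5],
                             prop_ecf = v[6], prop_csf = v[7]))
    }
    res <- tryCatch(.laplace_nll_cpp(designs, theta, env$etas),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$nll)) return(1e10)
    env$etas <- res$etas
    res$nll
  }
}

#' Fit the population PBPK model
#'
#' Maximises the Laplace-approximated marginal likelihood over the
#' population clearance `CL`, tissue partition coefficient `Kp`, the
#' log-normal between-subject standard deviation on CL and the four
#' residual-error terms, with `fd` fixed (identifiability: it sits at the
#' maximum the flow-fraction constraint allows) and the barrier clearances
#' `PS_ECF`/`PS_CSF` fixed to their in silico values unless
#' `estimate_PS = TRUE`, in which case both are estimated. The optimiser
#' restarts from `n_restarts` jittered starting points and keeps the best
#' objective.
#'
#' @param data A dataset as documented in [read_pk_dataset()], with at
#'   least two subjects.
#' @param sys A [system_parameters()] object.
#' @param drug Template [drug_parameters()]; supplies `fd` and the fixed
#'   `PS` values.
#' @param regimen The common [dosing_regimen()] (steady state assumed).
#' @param estimate_PS Also estimate `PS_ECF` and `PS_CSF`.
#' @param n_restarts Number of jittered optimiser starts (first start is
#'   unjittered).
#' @param seed Seed for the start-point jitter (reproducibility).
#' @param start Optional named list overriding starting values
#'   (`CL`, `Kp`, `omega`, `sigmas`, and `PS_ECF`/`PS_CSF` when estimated).
#' @param control List of optimiser settings: `triage_maxit` (short
#'   Nelder-Mead run per start, used to pick the best basin), `maxit` and
#'   `reltol` for the final run from the best start.
#' @return An object of class `population_fit` with elements `theta`
#'   (estimates), `fixed`, `omega_CL` (SD and %CV as
#'   `100*sqrt(exp(omega^2)-1)`), `sigmas`, `objective` (-2 log marginal
#'   likelihood), `etas` (empirical-Bayes modes), `convergence`.
#' @export
fit_population <- function(data, sys = system_parameters(),
                           drug = drug_parameters(),
                           regimen = dosing_regimen(),
                           estimate_PS = FALSE, n_restarts = 3, seed = 1,
                           start = NULL,
                           control = list(triage_maxit = 300,
                                          maxit = 1500, reltol = 1e-8)) {
  designs <- .subject_designs(data, sys, drug, regimen)
  if (length(designs) < 2L)
    stop("population estimation needs at least 2 subjects", call. = FALSE)
  streams <- unlist(lapply(designs, `[[`, "stream"))

  s0 <- list(CL = .start_cl(designs, regimen), Kp = 1, omega = 0.3,
             sigmas = c(prop_plasma = 0.2, add_plasma = 0.5,
                        prop_ecf = 0.2, prop_csf = 0.2),
             PS_ECF = drug$PS_ECF, PS_CSF = drug$PS_CSF)
  if (!is.null(start)) s0[names(start)] <- start
  p0 <- if (estimate_PS) {
    log(c(s0$CL, s0$Kp, s0$PS_ECF, s0$PS_CSF, s0$omega, s0$sigmas))
  } else log(c(s0$CL, s0$Kp, s0$omega, s0$sigmas))
  fixed <- c(fd = drug$fd,
             if (!estimate_PS) c(PS_ECF = drug$PS_ECF,
                                 PS_CSF = drug$PS_CSF))

  if (!is.null(seed)) set.seed(seed)
  env <- new.env()
  env$etas <- rep(0, length(designs))
  obj <- .fit_objective(designs, fixed, estimate_PS, env)
  nm <- function(p, maxit) {
    tryCatch(stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         reltol = control$reltol)),
             error = function(e) NULL)
  }
  # triage the jittered starts with short runs, then run the best to
  # convergence (ties broken by first start reaching the best objective)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    p_start <- if (r == 1L) p0 else p0 + stats::rnorm(length(p0), 0, 0.2)
    if (estimate_PS) {
      # the likelihood is flat in PS once exchange is perfusion-limited,
      # so spread the starts over decades to reach a permeability-limited
      # basin when the data support one
      p_start[3:4] <- p_start[3:4] + log(c(1, 0.1, 0.01)[(r - 1L) %% 3L + 1L])
    }
    env$etas <- rep(0, length(designs))
    opt <- nm(p_start, control$triage_maxit)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) {
      best <- opt
      best$etas_warm <- env$etas
    }
  }
  if (is.null(best))
    stop("population fit did not converge from any start", call. = FALSE)
  # polish the winning start with its own empirical-Bayes warm start
  env$etas <- best$etas_warm
  final_opt <- nm(best$par, control$maxit)
  if (!is.null(final_opt) && is.finite(final_opt$value) &&
        final_opt$value <= best$value)
    best <- final_opt
  best <- list(opt = list(par = best$par, objective = best$value,
                          convergence = best$convergence,
                          message = if (best$convergence == 0) "converged"
                                    else "iteration limit reached"),
               etas = env$etas)

  v <- unname(exp(best$opt$par))
  if (estimate_PS) {
    theta <- c(CL = v[1], Kp = v[2], PS_ECF = v[3], PS_CSF = v[4])
    omega <- v[5]; sig <- v[6:9]
  } else {
    theta <- c(CL = v[1], Kp = v[2])
    omega <- v[3]; sig <- v[4:7]
  }
  names(sig) <- c("prop_plasma", "add_plasma", "prop_ecf", "prop_csf")
  th_full <- .make_theta(v[1], v[2],
                         if (estimate_PS) v[3] else fixed[["PS_ECF"]],
                         if (estimate_PS) v[4] else fixed[["PS_CSF"]],
                         omega, sig)
  final <- .laplace_nll_cpp(designs, th_full, best$etas)

  structure(list(
    theta = theta,
    fixed = fixed,
    omega_CL = omega,
    omega_CL_cv = 100 * sqrt(exp(omega^2) - 1),
    sigmas = sig,
    objective = 2 * final$nll,
    etas = stats::setNames(as.numeric(final$etas),
                           vapply(designs, function(d) as.character(d$id),
                                  "")),
    estimate_PS = estimate_PS,
    convergence = best$opt$convergence,
    message = best$opt$message,
    n_subjects = length(designs),
    n_obs = length(streams),
    sys = sys, drug = drug, regimen = regimen,
    data = data),
    class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat("Population PBPK fit (Laplace conditional estimation)\n")
  cat(sprintf("  subjects: %d, observations: %d, -2LL: %.2f\n",
              x$n_subjects, x$n_obs, x$objective))
  for (nm in names(x$theta))
    cat(sprintf("  %-8s %8.4g\n", nm, x$theta[[nm]]))
  cat(sprintf("  IIV CL   %8.4g %%CV (omega = %.4g)\n",
              x$omega_CL_cv, x$omega_CL))
  for (nm in names(x$sigmas))
    cat(sprintf("  sigma %-12s %8.4g\n", nm, x$sigmas[[nm]]))
  cat("  fixed:", paste(names(x$fixed), signif(unlist(x$fixed), 4),
                        sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Population and individual predictions for every observation
#'
#' @param fit A [fit_population()] result.
#' @param data Dataset to predict; defaults to the fitted data.
#' @return The observation rows with `PRED` (population, `eta = 0`) and
#'   `IPRED` (empirical-Bayes) columns appended.
#' @export
fitted_predictions <- function(fit, data = fit$data) {
  designs <- .subject_designs(data, fit$sys, fit$drug, fit$regimen)
  th <- .make_theta(fit$theta[["CL"]], fit$theta[["Kp"]],
                    if (fit$estimate_PS) fit$theta[["PS_ECF"]]
                    else fit$fixed[["PS_ECF"]],
                    if (fit$estimate_PS) fit$theta[["PS_CSF"]]
                    else fit$fixed[["PS_CSF"]],
                    fit$omega_CL, fit$sigmas)
  out <- lapply(designs, function(d) {
    eta <- fit$etas[[as.character(d$id)]]
    if (is.null(eta) || is.na(eta)) eta <- 0
    data.frame(ID = d$id, STREAM = d$stream, time = d$obs_time,
               DV = d$dv,
               PRED = as.numeric(.subject_pred_cpp(d, th, 0)),
               IPRED = as.numeric(.subject_pred_cpp(d, th, eta)))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement, refits from the point estimates,
#' and reports percentile 2.5/97.5% intervals for every estimated
#' parameter (including the IIV %CV and residual terms).
#'
#' @param data The original dataset.
#' @param fit The [fit_population()] result to bootstrap.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed (bit-for-bit reproducible).
#' @param max_fail_frac Abort if more than this fraction of refits fail.
#' @param ... Further arguments (e.g. `control`) passed to
#'   [fit_population()] for the refits.
#' @return A list with the percentile `ci` table and the replicate
#'   estimates (`replicates`).
#' @export
bootstrap_ci <- function(data, fit, n_boot = 200, seed = 1,
                         max_fail_frac = 0.2, ...) {
  ids <- unique(data$ID)
  if (length(ids) < 2L)
    stop("bootstrap needs at least 2 subjects", call. = FALSE)
  set.seed(seed)
  start <- list(CL = fit$theta[["CL"]], Kp = fit$theta[["Kp"]],
                omega = fit$omega_CL, sigmas = fit$sigmas)
  if (fit$estimate_PS)
    start <- c(start, list(PS_ECF = fit$theta[["PS_ECF"]],
                           PS_CSF = fit$theta[["PS_CSF"]]))
  reps <- vector("list", n_boot)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    boot <- do.call(rbind, lapply(seq_along(take), function(j) {
      rows <- data[data$ID == take[j], , drop = FALSE]
      rows$ID <- j  # resampled subjects are distinct individuals
      rows
    }))
    f <- tryCatch(
      fit_population(boot, sys = fit$sys, drug = fit$drug,
                     regimen = fit$regimen,
                     estimate_PS = fit$estimate_PS,
                     n_restarts = 1, seed = NULL, start = start, ...),
      error = function(e) NULL)
    if (is.null(f)) { fails <- fails + 1L; next }
    reps[[b]] <- c(f$theta, omega_CL_cv = f$omega_CL_cv, f$sigmas)
  }
  if (fails > max_fail_frac * n_boot)
    stop(fails, "/", n_boot, " bootstrap refits failed (> ",
         100 * max_fail_frac, "%)", call. = FALSE)
  reps <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  ci <- t(apply(reps, 2, stats::quantile, probs = c(0.025, 0.975)))
  list(ci = ci, replicates = as.data.frame(reps), n_failed = fails)
}

#' Fold errors between predicted and observed exposures
#'
#' @param pred_AUC,obs_AUC Positive per-subject AUCs (matched vectors).
#' @return Per-subject fold errors `pred/obs`.
#' @seealso [mean_fold_error()] for the geometric-mean summary.
#' @export
fold_error <- function(pred_AUC, obs_AUC) {
  if (any(pred_AUC <= 0) || any(obs_AUC <= 0))
    stop("AUCs must be positive", call. = FALSE)
  pred_AUC / obs_AUC
}

#' @rdname fold_error
#' @return `mean_fold_error()`: the geometric mean of the fold errors.
#' @export
mean_fold_error <- function(pred_AUC, obs_AUC) {
  exp(mean(log(fold_error(pred_AUC, obs_AUC))))
}
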