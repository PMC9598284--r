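# Model-evaluation diagnostics: visual predictive checks and
# goodness-of-fit summaries (AUC fold errors per observation stream).

#' Visual predictive check
#'
#' Simulates `n_sim` replicate cohorts at the exact design of the dataset
#' (same subjects, sampling schemes, drain flows and body weights), drawing
#' new between-subject random effects and residual errors from the fitted
#' model, and summarises the simulated observations as 5th/50th/95th
#' percentile bands per stream and nominal sampling time, overlaid with
#' the observed points.
#'
#' @param data The observed dataset ([read_pk_dataset()] dialect).
#' @param fit A [fit_population()] result.
#' @param n_sim Number of simulated replicate cohorts.
#' @param seed RNG seed (bands are seed-reproducible).
#' @return An object of class `pbpk_vpc`: list with `bands` (stream, time,
#'   p5/p50/p95), `observed` (stream, time, DV) and the simulation
#'   settings.
#' @export
vpc <- function(data, fit, n_sim = 1000, seed = 1) {
  designs <- .subject_designs(data, fit$sys, fit$drug, fit$regimen)
  th <- .make_theta(fit$theta[["CL"]], fit$theta[["Kp"]],
                    if (fit$estimate_PS) fit$theta[["PS_ECF"]]
                    else fit$fixed[["PS_ECF"]],
                    if (fit$estimate_PS) fit$theta[["PS_CSF"]]
                    else fit$fixed[["PS_CSF"]],
                    fit$omega_CL, fit$sigmas)
  sg <- fit$sigmas
  set.seed(seed)

  obs <- do.call(rbind, lapply(designs, function(d)
    data.frame(stream = d$stream, time = round(d$obs_time, 6),
               DV = d$dv)))
  for (s in c("plasma_unbound", "dialysate", "evd"))
    if (!any(obs$stream == s))
      warning("no observations in stream '", s, "'; panel omitted",
              call. = FALSE)

  sims <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    sim_r <- lapply(designs, function(d) {
      eta <- stats::rnorm(1, 0, fit$omega_CL)
      pred <- as.numeric(.subject_pred_cpp(d, th, eta))
      eps_p <- stats::rnorm(length(pred), 0, 1)
      dv <- ifelse(d$obs_type == 0L,
                   pred * (1 + eps_p * sg[["prop_plasma"]]) +
                     stats::rnorm(length(pred), 0, sg[["add_plasma"]]),
            ifelse(d$obs_type == 1L,
                   pred * (1 + eps_p * sg[["prop_ecf"]]),
                   pred * (1 + eps_p * sg[["prop_csf"]])))
      data.frame(stream = d$stream, time = round(d$obs_time, 6), DV = dv)
    })
    sims[[r]] <- do.call(rbind, sim_r)
  }
  simdf <- do.call(rbind, sims)
  key <- interaction(simdf$stream, simdf$time, drop = TRUE, sep = "|")
  qs <- t(vapply(split(simdf$DV, key),
                 stats::quantile, numeric(3),
                 probs = c(0.05, 0.5, 0.95), names = FALSE))
  meta <- do.call(rbind, strsplit(levels(key), "|", fixed = TRUE))
  bands <- data.frame(stream = meta[, 1],
                      time = as.numeric(meta[, 2]),
                      p5 = qs[, 1], p50 = qs[, 2], p95 = qs[, 3])
  bands <- bands[order(bands$stream, bands$time), ]
  rownames(bands) <- NULL
  structure(list(bands = bands, observed = obs, n_sim = n_sim,
                 seed = seed),
            class = "pbpk_vpc")
}

#' Fraction of observations inside the VPC 90% prediction band
#'
#' @param x A [vpc()] result.
#' @return Named list with the overall coverage fraction and per-stream
#'   coverage.
#' @export
vpc_coverage <- function(x) {
  stopifnot(inherits(x, "pbpk_vpc"))
  m <- merge(x$observed, x$bands, by = c("stream", "time"))
  inside <- m$DV >= m$p5 & m$DV <= m$p95
  list(overall = mean(inside),
       by_stream = vapply(split(inside, m$stream), mean, numeric(1)),
       n = nrow(m))
}

#' @export
print.pbpk_vpc <- function(x, ...) {
  cov <- vpc_coverage(x)
  cat(sprintf(
    "Visual predictive check: %d simulated cohorts, %d observations\n",
    x$n_sim, cov$n))
  cat(sprintf("  coverage of the 5-95%% band: %.1f%%\n",
              100 * cov$overall))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' @param x A [vpc()] result.
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot.pbpk_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x$bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50)) +
    ggplot2::geom_point(data = x$observed,
                        ggplot2::aes(y = .data$DV), alpha = 0.6) +
    ggplot2::facet_wrap(~stream, scales = "free_y") +
    ggplot2::labs(x = "time after dose (h)",
                  y = "unbound concentration (mg/L)")
}

#' Goodness-of-fit summaries
#'
#' Observed-versus-predicted pairs, residuals, per-subject steady-state
#' interval AUCs (linear trapezoid over the sampling times, interval
#' samples placed at their midpoints) and predicted/observed fold errors,
#' summarised per stream as geometric-mean fold errors.
#'
#' @param data The observed dataset.
#' @param fit A [fit_population()] result.
#' @return A list with `observations` (DV, PRED, IPRED, residuals),
#'   `auc` (per subject and stream) and `mfe` (geometric mean fold error
#'   per stream).
#' @export
gof_table <- function(data, fit) {
  pred <- fitted_predictions(fit, data)
  pred$RES <- pred$DV - pred$PRED
  pred$IRES <- pred$DV - pred$IPRED
  key <- interaction(pred$ID, pred$STREAM, drop = TRUE)
  auc <- do.call(rbind, lapply(split(pred, key), function(g) {
    g <- g[order(g$time), ]
    g <- g[!duplicated(g$time), ]
    if (nrow(g) < 2L) return(NULL)
    data.frame(ID = g$ID[1], STREAM = g$STREAM[1],
               obs_AUC = auc_trapezoid(g$time, g$DV),
               pred_AUC = auc_trapezoid(g$time, g$IPRED))
  }))
  rownames(auc) <- NULL
  auc$fold_error <- fold_error(auc$pred_AUC, auc$obs_AUC)
  mfe <- vapply(split(auc, auc$STREAM), function(g)
    mean_fold_error(g$pred_AUC, g$obs_AUC), numeric(1))
  list(observations = pred, auc = auc, mfe = mfe)
}
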