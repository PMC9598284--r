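#' Efflux ratio from bidirectional Caco-2 permeability
#'
#' Classifies transport as passive when the basolateral-to-apical over
#' apical-to-basolateral apparent-permeability ratio is below 2; for a
#' passive compound a single Papp is taken as the mean of both directions.
#'
#' @param Papp_AB Apical-to-basolateral apparent permeability (cm/s).
#' @param Papp_BA Basolateral-to-apical apparent permeability (cm/s).
#' @return A list with `ratio`, logical `passive`, and `mean_Papp` (cm/s;
#'   `NA` when not passive).
#' @export
#' @examples
#' efflux_ratio(1e-5, 1.2e-5)
efflux_ratio <- function(Papp_AB, Papp_BA) {
  if (Papp_AB <= 0 || Papp_BA <= 0)
    stop("apparent permeabilities must be positive", call. = FALSE)
  ratio <- Papp_BA / Papp_AB
  passive <- ratio < 2
  list(ratio = ratio, passive = passive,
       mean_Papp = if (passive) (Papp_AB + Papp_BA) / 2 else NA_real_)
}

#' Scale in vitro apparent permeability to an in vivo BBB clearance
#'
#' `PS = Papp x SA_BBB x B_W`, with unit handling done internally:
#' cm/s x cm^2/g x g = cm^3/s, converted to L/h.
#'
#' @param Papp Apparent permeability (cm/s).
#' @param SA_BBB BBB surface area per gram of brain (cm^2/g).
#' @param B_W Brain weight (g).
#' @return Permeability-surface area clearance (L/h).
#' @export
#' @examples
#' scale_papp_to_ps(1.112e-5, 157, 1274)  # about 8 L/h
scale_papp_to_ps <- function(Papp, SA_BBB = 157, B_W = 1274) {
  if (Papp < 0 || SA_BBB <= 0 || B_W <= 0)
    stop("Papp must be >= 0 and SA_BBB, B_W positive", call. = FALSE)
  Papp * 3600 * SA_BBB * B_W / 1000
}

#' BCSFB clearance from the BBB clearance
#'
#' The blood-CSF barrier is taken to have half the BBB surface area, so its
#' permeability-surface clearance is half the BBB value.
#'
#' @param PS_ECF BBB permeability-surface clearance (L/h).
#' @return `PS_ECF / 2` (L/h).
#' @export
#' @examples
#' ps_csf_from_ps_ecf(6.4)  # 3.2
ps_csf_from_ps_ecf <- function(PS_ECF) {
  if (any(PS_ECF < 0)) stop("PS_ECF must be non-negative", call. = FALSE)
  PS_ECF / 2
}

#' Fold-ratio comparison of PS values across determination routes
#'
#' Cross-compares the BBB and BCSFB permeability-surface clearances obtained
#' by in silico calculation, by in vitro Caco-2 scaling and by model
#' estimation, reporting pairwise fold ratios rounded to one decimal, plus
#' the estimated BBB:BCSFB ratio.
#'
#' @param PS_calculated,PS_in_vitro,PS_estimated Length-2 vectors
#'   `c(ECF, CSF)` of clearances (L/h).
#' @return A list with the value table (`values`, a `data.frame` with one
#'   row per barrier) and `fold_ratios` (calculated/estimated,
#'   in_vitro/estimated, calculated/in_vitro per barrier, and the
#'   estimated ECF:CSF ratio), all rounded to one decimal.
#' @export
#' @examples
#' ps_comparison_table(c(6.4, 3.2), c(8.0, 4.0), c(0.904, 0.398))
ps_comparison_table <- function(PS_calculated, PS_in_vitro, PS_estimated) {
  vals <- rbind(PS_calculated, PS_in_vitro, PS_estimated)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PS values must be positive", call. = FALSE)
  stopifnot(ncol(vals) == 2L)
  values <- data.frame(
    barrier = c("BBB (PS_ECF)", "BCSFB (PS_CSF)"),
    PS_calculated = PS_calculated,
    PS_in_vitro = PS_in_vitro,
    PS_estimated = PS_estimated)
  fold <- data.frame(
    barrier = values$barrier,
    calculated_over_estimated = round(PS_calculated / PS_estimated, 1),
    in_vitro_over_estimated = round(PS_in_vitro / PS_estimated, 1),
    calculated_over_in_vitro = round(PS_calculated / PS_in_vitro, 1))
  list(values = values, fold_ratios = fold,
       estimated_ECF_CSF_ratio = round(PS_estimated[1] / PS_estimated[2], 1))
}
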