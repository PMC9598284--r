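#' Physiological system parameters
#'
#' Constructor for the system-specific (drug-independent) parameters of the
#' minimal CNS PBPK model: CSF bulk and sink flows, cardiac output, cerebral
#' blood flow, compartment volumes, BBB surface area and brain weight.
#' Defaults are the adult physiological values used throughout the package.
#'
#' @param Q_bulk Bulk flow from brain ECF to CSF (L/h).
#' @param Q_sink_physio Physiological CSF reabsorption (sink) flow (L/h).
#' @param CO Cardiac output (L/h).
#' @param Q_brain Cerebral blood flow (L/h); must be below `CO`.
#' @param V_ECF Brain extracellular fluid volume (L).
#' @param V_CSF Cranial CSF volume (L).
#' @param V_blood Blood volume (L).
#' @param V_brain_vasc Brain vascular volume (L).
#' @param SA_BBB Blood-brain-barrier surface area per gram of brain (cm^2/g).
#' @param B_W Brain weight (g).
#' @return An object of class `system_parameters`.
#' @export
#' @examples
#' sys <- system_parameters()
#' sys$Q_brain / sys$CO  # fraction of cardiac output perfusing the brain
system_parameters <- function(Q_bulk = 0.0105,
                              Q_sink_physio = 0.024,
                              CO = 312,
                              Q_brain = 42,
                              V_ECF = 0.24,
                              V_CSF = 0.130,
                              V_blood = 5.85,
                              V_brain_vasc = 0.0637,
                              SA_BBB = 157,
                              B_W = 1274) {
  sys <- list(Q_bulk = Q_bulk, Q_sink_physio = Q_sink_physio, CO = CO,
              Q_brain = Q_brain, V_ECF = V_ECF, V_CSF = V_CSF,
              V_blood = V_blood, V_brain_vasc = V_brain_vasc,
              SA_BBB = SA_BBB, B_W = B_W)
  for (nm in names(sys)) {
    x <- sys[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("system parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (Q_brain >= CO)
    stop("Q_brain must be smaller than cardiac output CO", call. = FALSE)
  structure(sys, class = "system_parameters")
}

#' Drug-specific parameters
#'
#' Drug-level quantities of the model: total blood clearance of unbound drug,
#' the unbound tissue-to-blood partition coefficient of the lumped peripheral
#' tissue, passive permeability-surface area clearances at the BBB and BCSFB,
#' the fraction of cardiac output perfusing the peripheral tissue, plasma
#' unbound fraction, blood-to-plasma ratio and physicochemical metadata.
#' Defaults describe metronidazole with `PS_CSF = PS_ECF / 2` (the BCSFB is
#' taken to have half the BBB surface area).
#'
#' @param CL Total blood clearance of unbound drug (L/h).
#' @param Kp Unbound tissue-to-blood partition coefficient (-).
#' @param PS_ECF Passive permeability-surface clearance across the BBB (L/h).
#' @param PS_CSF Passive permeability-surface clearance across the BCSFB
#'   (L/h); defaults to `PS_ECF / 2`.
#' @param fd Fraction of cardiac output perfusing the lumped tissue (-).
#' @param fu Unbound fraction in plasma (-).
#' @param BP_ratio Blood-to-plasma concentration ratio (-).
#' @param MW Molecular weight (g/mol); metadata only.
#' @param logP Octanol:water partition coefficient; metadata only.
#' @return An object of class `drug_parameters`.
#' @export
drug_parameters <- function(CL = 7.28,
                            Kp = 0.796,
                            PS_ECF = 6.4,
                            PS_CSF = PS_ECF / 2,
                            fd = 0.86,
                            fu = 1,
                            BP_ratio = 0.82,
                            MW = 171,
                            logP = -0.459) {
  if (CL < 0 || PS_ECF < 0 || PS_CSF < 0)
    stop("CL, PS_ECF and PS_CSF must be non-negative", call. = FALSE)
  if (Kp <= 0) stop("Kp must be positive", call. = FALSE)
  if (fd <= 0 || fd >= 1)
    stop("fd must lie strictly between 0 and 1", call. = FALSE)
  if (fu <= 0 || fu > 1) stop("fu must lie in (0, 1]", call. = FALSE)
  if (BP_ratio <= 0) stop("BP_ratio must be positive", call. = FALSE)
  structure(list(CL = CL, Kp = Kp, PS_ECF = PS_ECF, PS_CSF = PS_CSF,
                 fd = fd, fu = fu, BP_ratio = BP_ratio, MW = MW,
                 logP = logP),
            class = "drug_parameters")
}

#' Derive patient-level physiology from body weight
#'
#' The lumped peripheral tissue volume follows from the whole-body volume
#' balance `V_blood + V_tissue + V_brain_vasc + V_ECF + V_CSF = TBW`, with
#' body density taken as 1 kg/L. The fraction of cardiac output perfusing
#' the brain is `Q_brain / CO`, and the flow-fraction constraint
#' `fd + fd_brain <= 1` is enforced.
#'
#' @param TBW Total body weight (kg).
#' @param sys A [system_parameters()] object.
#' @param fd Fraction of cardiac output perfusing the lumped tissue.
#' @return An object of class `patient_physiology` with fields `TBW`,
#'   `V_tissue` (L) and `fd_brain`.
#' @export
#' @examples
#' derive_patient_physiology(90, system_parameters(), fd = 0.86)
derive_patient_physiology <- function(TBW, sys = system_parameters(),
                                      fd = 0.86) {
  stopifnot(inherits(sys, "system_parameters"))
  if (!is.numeric(TBW) || length(TBW) != 1L || !is.finite(TBW) || TBW <= 0)
    stop("TBW must be a single positive number", call. = FALSE)
  V_tissue <- TBW - sys$V_blood - sys$V_brain_vasc - sys$V_ECF - sys$V_CSF
  if (V_tissue <= 0)
    stop("volume balance violated: ",
         "V_blood + V_brain_vasc + V_ECF + V_CSF exceeds TBW ",
         "(V_tissue = ", signif(V_tissue, 4), " L)", call. = FALSE)
  fd_brain <- sys$Q_brain / sys$CO
  if (fd + fd_brain > 1)
    stop("flow-fraction constraint violated: fd + fd_brain = ",
         signif(fd + fd_brain, 5), " > 1 (fd_brain = Q_brain/CO = ",
         signif(fd_brain, 5), ")", call. = FALSE)
  structure(list(TBW = TBW, V_tissue = V_tissue, fd_brain = fd_brain),
            class = "patient_physiology")
}

#' Effective CSF sink flow under external ventricular drainage
#'
#' The drain is assumed to compensate blocked CSF reabsorption, so the
#' drain flow is subtracted from the physiological sink flow; when the
#' drain exceeds it, reabsorption is taken as fully blocked and the sink
#' flow is floored at zero.
#'
#' @param Q_EVD External ventricular drain flow (L/h), `>= 0`.
#' @param Q_sink_physio Physiological sink flow (L/h), `>= 0`.
#' @return Effective sink flow `max(Q_sink_physio - Q_EVD, 0)` (L/h).
#' @export
#' @examples
#' effective_sink_flow(0.01, 0.024)  # 0.014
#' effective_sink_flow(0.04, 0.024)  # 0: reabsorption fully blocked
effective_sink_flow <- function(Q_EVD, Q_sink_physio) {
  if (any(!is.finite(Q_EVD)) || any(Q_EVD < 0))
    stop("Q_EVD must be non-negative", call. = FALSE)
  if (any(!is.finite(Q_sink_physio)) || any(Q_sink_physio < 0))
    stop("Q_sink_physio must be non-negative", call. = FALSE)
  pmax(Q_sink_physio - Q_EVD, 0)
}

#' External ventricular drain collection schedule
#'
#' Ordered, non-overlapping collection intervals with the per-interval drain
#' flow and collected sample volume. When `V_EVD` is omitted it is taken as
#' `Q_EVD * (t_end - t_start)`; when supplied, a consistency warning is
#' issued if it departs from that product by more than `tol` (relative).
#'
#' @param t_start,t_end Interval bounds (h).
#' @param Q_EVD Drain flow during each interval (L/h).
#' @param V_EVD Collected sample volume per interval (L); optional.
#' @param tol Relative tolerance for the `V_EVD` consistency check.
#' @return A `data.frame` of class `evd_schedule`.
#' @export
evd_schedule <- function(t_start, t_end, Q_EVD, V_EVD = NULL, tol = 0.2) {
  n <- length(t_start)
  stopifnot(length(t_end) == n, length(Q_EVD) %in% c(1L, n))
  Q_EVD <- rep_len(Q_EVD, n)
  if (any(Q_EVD < 0)) stop("Q_EVD must be non-negative", call. = FALSE)
  if (any(t_end <= t_start))
    stop("each interval must have t_end > t_start", call. = FALSE)
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; Q_EVD <- Q_EVD[o]
  if (n > 1L && any(t_start[-1L] < t_end[-n] - 1e-9))
    stop("EVD intervals must not overlap", call. = FALSE)
  nominal <- Q_EVD * (t_end - t_start)
  if (is.null(V_EVD)) {
    V_EVD <- nominal
  } else {
    V_EVD <- rep_len(V_EVD, n)[o]
    off <- nominal > 0 & abs(V_EVD - nominal) > tol * nominal
    if (any(off))
      warning(sum(off), " EVD interval(s) have V_EVD inconsistent with ",
              "Q_EVD * (t_end - t_start) beyond the ", tol * 100,
              "% tolerance", call. = FALSE)
  }
  structure(data.frame(t_start = t_start, t_end = t_end, Q_EVD = Q_EVD,
                       V_EVD = V_EVD),
            class = c("evd_schedule", "data.frame"))
}

# Pack parameters into the flat vector consumed by the compiled core.
.pack_pars <- function(sys, drug, phys) {
  c(sys$V_blood, phys$V_tissue, sys$V_brain_vasc, sys$V_ECF, sys$V_CSF,
    drug$fd * sys$CO, sys$Q_brain, drug$CL, drug$Kp, drug$PS_ECF,
    drug$PS_CSF, sys$Q_bulk, sys$Q_sink_physio)
}

#' Assemble the amount-space transfer matrix
#'
#' Builds the 6-state linear system (amounts in blood, lumped tissue, brain
#' vasculature, brain ECF, CSF and the absorbing EVD collection bag) whose
#' concentration-form derivatives reproduce the model equations, using the
#' effective sink flow for the given drain flow. The input mapping routes
#' the infusion rate (mg/h) into the blood state.
#'
#' @param sys A [system_parameters()] object.
#' @param drug A [drug_parameters()] object.
#' @param phys A [derive_patient_physiology()] object.
#' @param Q_EVD Drain flow (L/h) in force while this matrix applies.
#' @return A list with the 6x6 rate matrix `A` (1/h, amount space), the
#'   `input` unit vector, compartment `volumes` (L) and state names.
#' @export
build_transfer_matrix <- function(sys, drug, phys, Q_EVD = 0) {
  stopifnot(inherits(sys, "system_parameters"),
            inherits(drug, "drug_parameters"),
            inherits(phys, "patient_physiology"))
  if (Q_EVD < 0) stop("Q_EVD must be non-negative", call. = FALSE)
  if (drug$fd + phys$fd_brain > 1)
    stop("flow-fraction constraint violated: fd + fd_brain > 1",
         call. = FALSE)
  states <- c("blood", "tissue", "brain_vasc", "ECF", "CSF", "EVD")
  A <- .rate_matrix_cpp(.pack_pars(sys, drug, phys), Q_EVD)
  dimnames(A) <- list(states, states)
  input <- stats::setNames(c(1, 0, 0, 0, 0, 0), states)
  volumes <- stats::setNames(
    c(sys$V_blood, phys$V_tissue, sys$V_brain_vasc, sys$V_ECF, sys$V_CSF,
      NA_real_),
    states)
  list(A = A, input = input, volumes = volumes, states = states)
}

#' Read a model configuration file
#'
#' Reads a flat key-value JSON or YAML file holding system and drug
#' parameters (keys `Q_bulk`, `Q_sink_physio`, `CO`, `Q_brain`, `V_ECF`,
#' `V_CSF`, `V_blood`, `V_brain_vasc`, `SA_BBB`, `B_W`, `CL`, `Kp`, `fd`,
#' `PS_ECF`, `PS_CSF`, `fu`, `BP_ratio`, `MW`, `logP`). Units are fixed to
#' h, L, mg and mg/L; keys not present fall back to the package defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `sys` and `drug`.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be a .json, .yaml or .yml file", call. = FALSE))
  take <- function(keys) cfg[intersect(keys, names(cfg))]
  sys <- do.call(system_parameters,
                 take(c("Q_bulk", "Q_sink_physio", "CO", "Q_brain", "V_ECF",
                        "V_CSF", "V_blood", "V_brain_vasc", "SA_BBB",
                        "B_W")))
  drug <- do.call(drug_parameters,
                  take(c("CL", "Kp", "PS_ECF", "PS_CSF", "fd", "fu",
                         "BP_ratio", "MW", "logP")))
  list(sys = sys, drug = drug)
}

#' @export
print.system_parameters <- function(x, ...) {
  cat("System parameters (minimal CNS PBPK)\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("Drug parameters\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}
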