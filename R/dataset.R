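#' Long-format population PK dataset
#'
#' The estimation dataset is a long-format `data.frame` with one row per
#' dosing or observation event, NONMEM-flavoured columns:
#' \describe{
#'   \item{ID}{subject identifier}
#'   \item{TIME}{sampling time within the steady-state interval (h); point
#'     samples (plasma) only}
#'   \item{T1, T2}{collection-interval bounds (h); interval samples
#'     (dialysate, EVD) only}
#'   \item{DV}{observed unbound concentration (mg/L); `NA` on dose rows}
#'   \item{STREAM}{`"plasma_unbound"`, `"dialysate"` or `"evd"`}
#'   \item{AMT, RATE}{dose amount (mg) and infusion rate (mg/h); dose rows}
#'   \item{QEVD, VEVD}{per-interval drain flow (L/h) and sample volume (L);
#'     EVD rows}
#'   \item{RECOVERY}{in vivo probe recovery fraction; dialysate rows}
#'   \item{WT}{body weight (kg)}
#' }
#' Dialysate `DV` values are assumed already corrected by probe recovery.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`.
#' @export
read_pk_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  validate_pk_dataset(d)
}

#' @rdname read_pk_dataset
#' @param data A data.frame to validate in place.
#' @export
validate_pk_dataset <- function(data) {
  need <- c("ID", "TIME", "T1", "T2", "DV", "STREAM", "AMT", "RATE",
            "QEVD", "VEVD", "RECOVERY", "WT")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  obs <- data[!is.na(data$DV), , drop = FALSE]
  bad <- setdiff(unique(obs$STREAM),
                 c("plasma_unbound", "dialysate", "evd"))
  if (length(bad))
    stop("unknown observation stream(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(obs$DV <= 0))
    stop("observed concentrations must be positive", call. = FALSE)
  iv <- obs$STREAM %in% c("dialysate", "evd")
  if (any(is.na(obs$T1[iv]) | is.na(obs$T2[iv]) |
            obs$T2[iv] <= obs$T1[iv]))
    stop("interval observations need valid T1 < T2", call. = FALSE)
  ev <- obs$STREAM == "evd"
  if (any(is.na(obs$QEVD[ev]) | obs$QEVD[ev] < 0 |
            is.na(obs$VEVD[ev]) | obs$VEVD[ev] <= 0))
    stop("EVD observations need QEVD >= 0 and VEVD > 0", call. = FALSE)
  rec <- obs$RECOVERY[obs$STREAM == "dialysate"]
  rec <- rec[!is.na(rec)]
  if (any(rec <= 0 | rec > 1))
    stop("probe recovery must lie in (0, 1]", call. = FALSE)
  data
}

#' Write a PK dataset to CSV
#' @param data A dataset as documented in [read_pk_dataset()].
#' @param path Output CSV path.
#' @export
write_pk_dataset <- function(data, path) {
  utils::write.csv(validate_pk_dataset(data), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# Compile one subject's rows into the compact design consumed by the
# compiled likelihood core: a one-interval steady-state segment schedule
# plus break-index mappings for every observation.
.subject_design <- function(rows, sys, drug, regimen) {
  wt <- rows$WT[!is.na(rows$WT)][1]
  if (is.na(wt)) stop("subject ", rows$ID[1], " has no body weight",
                      call. = FALSE)
  phys <- derive_patient_physiology(wt, sys, drug$fd)
  obs <- rows[!is.na(rows$DV), , drop = FALSE]
  if (!nrow(obs)) stop("subject ", rows$ID[1], " has no observations",
                       call. = FALSE)
  iv <- obs$STREAM %in% c("dialysate", "evd")
  breaks <- sort(unique(round(c(0, regimen$infusion_duration, regimen$tau,
                                obs$TIME[!iv], obs$T1[iv], obs$T2[iv]),
                              9)))
  if (any(breaks < 0) || any(breaks > regimen$tau + 1e-9))
    stop("subject ", rows$ID[1],
         ": observation times must lie within [0, tau]", call. = FALSE)
  # piecewise-constant drain flow from the EVD rows
  ev <- obs[obs$STREAM == "evd", , drop = FALSE]
  dt <- diff(breaks)
  mid <- breaks[-length(breaks)] + dt / 2
  rate <- ifelse(mid < regimen$infusion_duration,
                 regimen$dose / regimen$infusion_duration, 0)
  qevd <- numeric(length(mid))
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev)))
      qevd[mid >= ev$T1[i] & mid < ev$T2[i]] <- ev$QEVD[i]
  }
  idx <- function(t) {
    i <- match(round(t, 9), breaks)
    if (anyNA(i)) stop("internal: observation time off the break grid")
    i - 1L  # 0-based row index into the state matrix
  }
  type <- match(obs$STREAM, c("plasma_unbound", "dialysate", "evd")) - 1L
  i1 <- integer(nrow(obs)); i2 <- integer(nrow(obs)); dt_obs <- numeric(nrow(obs))
  i1[!iv] <- idx(obs$TIME[!iv])
  i1[iv] <- idx(obs$T1[iv]); i2[iv] <- idx(obs$T2[iv])
  dt_obs[iv] <- obs$T2[iv] - obs$T1[iv]
  list(id = rows$ID[1],
       seg_dt = dt, seg_rate = rate, seg_qevd = qevd,
       obs_type = type, i1 = i1, i2 = i2, dt_obs = dt_obs,
       qevd_obs = ifelse(is.na(obs$QEVD), 0, obs$QEVD),
       vevd_obs = ifelse(is.na(obs$VEVD), 1, obs$VEVD),
       dv = obs$DV, stream = obs$STREAM,
       obs_time = ifelse(iv, (obs$T1 + obs$T2) / 2, obs$TIME),
       pars = .pack_pars(sys, drug, phys), wt = wt)
}

.subject_designs <- function(data, sys, drug, regimen) {
  data <- validate_pk_dataset(data)
  lapply(split(data, data$ID), .subject_design, sys = sys, drug = drug,
         regimen = regimen)
}
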