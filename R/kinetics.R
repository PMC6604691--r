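#' Plasma input function
#'
#' A sampled plasma time-activity curve driving tissue uptake: decay-corrected
#' activity concentration expressed as SUV (normalized for injected activity
#' and body weight), optionally with a parallel unlabeled-drug concentration
#' channel from an immunoassay.
#'
#' @param times sample times in hours post-injection, strictly increasing.
#' @param cp plasma activity as SUV (dimensionless), non-negative.
#' @param patient_id,administration identifiers; `administration` is
#'   `"first"` (tracer-only baseline) or `"second"` (predose + tracer).
#' @param conc_ug_ml optional unlabeled drug concentration (ug/mL) at `times`.
#' @return an object of class `plasma_curve`.
#' @export
plasma_curve <- function(times, cp, patient_id = "p1",
                         administration = c("first", "second"),
                         conc_ug_ml = NULL) {
  administration <- match.arg(administration)
  check_times(times)
  if (length(cp) != length(times))
    stop_domain("'cp' and 'times' must have equal length")
  if (length(times) < 2L)
    stop_domain("a plasma curve needs at least 2 samples")
  if (any(!is.finite(cp)) || any(cp < 0))
    stop_domain("'cp' must be finite and >= 0")
  if (!is.null(conc_ug_ml) && length(conc_ug_ml) != length(times))
    stop_domain("'conc_ug_ml' must match 'times' in length")
  structure(
    list(patient_id = as.character(patient_id),
         administration = administration,
         times = as.numeric(times), cp = as.numeric(cp),
         conc_ug_ml = if (is.null(conc_ug_ml)) NULL else as.numeric(conc_ug_ml)),
    class = "plasma_curve")
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("<plasma_curve> patient %s, %s administration, %d samples over [%g, %g] h\n",
              x$patient_id, x$administration, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Interpolate the plasma curve at arbitrary times
#'
#' Antibody plasma decay is multi-exponential, so interior values are
#' interpolated log-linearly (each segment an exponential) whenever both
#' bracketing samples are positive; segments touching a zero fall back to
#' linear interpolation. Values at sample times are exact.
#'
#' @param curve a [plasma_curve()].
#' @param t times (hours) within the sampled support.
#' @param method `"loglinear"` (default) or `"linear"`.
#' @return plasma SUV at `t`.
#' @export
interpolate_cp <- function(curve, t, method = c("loglinear", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "plasma_curve"))
  if (any(t < min(curve$times) - 1e-12) || any(t > max(curve$times) + 1e-12))
    stop_domain(sprintf(
      "time outside plasma support [%g, %g] h: extrapolation refused",
      min(curve$times), max(curve$times)))
  tt <- curve$times; cc <- curve$cp
  vapply(t, function(ti) {
    ti <- min(max(ti, tt[1]), tt[length(tt)])
    i <- findInterval(ti, tt, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(tt) - 1L)
    t1 <- tt[i]; t2 <- tt[i + 1L]; c1 <- cc[i]; c2 <- cc[i + 1L]
    if (ti == t1) return(c1)
    if (ti == t2) return(c2)
    w <- (ti - t1) / (t2 - t1)
    if (method == "loglinear" && c1 > 0 && c2 > 0)
      exp((1 - w) * log(c1) + w * log(c2))
    else
      (1 - w) * c1 + w * c2
  }, numeric(1))
}

## Integral of one interpolated segment [t1, t2] with endpoint values c1, c2.
## Exponential segment has closed form (c1 - c2) * dt / log(c1/c2).
segment_auc <- function(t1, t2, c1, c2, method) {
  dt <- t2 - t1
  if (dt <= 0) return(0)
  if (method == "loglinear" && c1 > 0 && c2 > 0 &&
      abs(log(c1 / c2)) > 1e-10) {
    (c1 - c2) * dt / log(c1 / c2)
  } else {
    (c1 + c2) / 2 * dt
  }
}

#' Cumulative area under the plasma curve
#'
#' Integral of the interpolated input function from time 0 to `t`
#' (SUV x hours). The curve is back-extrapolated flat from its first sample
#' to t = 0 (the infusion period is not modeled; its contribution to the AUC
#' at the 48-120 h scans is negligible).
#'
#' @inheritParams interpolate_cp
#' @return AUC(0, t) for each element of `t`; nondecreasing in `t`.
#' @export
cumulative_auc <- function(curve, t, method = c("loglinear", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "plasma_curve"))
  if (any(t < 0)) stop_domain("AUC requested at negative time")
  if (any(t > max(curve$times) + 1e-12))
    stop_domain("AUC requested beyond plasma support: extrapolation refused")
  tt <- curve$times; cc <- curve$cp
  if (tt[1] > 0) {           # flat back-extrapolation to t = 0
    tt <- c(0, tt); cc <- c(cc[1], cc)
  }
  seg <- vapply(seq_len(length(tt) - 1L), function(i)
    segment_auc(tt[i], tt[i + 1L], cc[i], cc[i + 1L], method), numeric(1))
  cum <- c(0, cumsum(seg))
  vapply(t, function(ti) {
    i <- findInterval(ti, tt, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(tt) - 1L)
    ci <- if (ti <= tt[1]) cc[1] else interpolate_cp_raw(tt, cc, ti, method)
    cum[i] + segment_auc(tt[i], min(ti, tt[i + 1L]), cc[i], ci, method)
  }, numeric(1))
}

## interpolation on raw vectors (used internally where the padded t=0 sample
## would fail plasma_curve validation)
interpolate_cp_raw <- function(tt, cc, ti, method) {
  i <- findInterval(ti, tt, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(tt) - 1L)
  t1 <- tt[i]; t2 <- tt[i + 1L]; c1 <- cc[i]; c2 <- cc[i + 1L]
  if (ti <= t1) return(c1)
  if (ti >= t2) return(c2)
  w <- (ti - t1) / (t2 - t1)
  if (method == "loglinear" && c1 > 0 && c2 > 0)
    exp((1 - w) * log(c1) + w * log(c2))
  else (1 - w) * c1 + w * c2
}

#' Lesion time-activity record
#'
#' SUVpeak of one lesion across the scan times of one administration, with
#' the administration's total antibody mass dose (mg/kg) as context for the
#' downstream dose-inhibition fit. Missing values (`NA`) mark scans where the
#' lesion was below the limit of quantification or not assessed.
#'
#' @param patient_id,lesion_id,administration identifiers.
#' @param tissue_class one of `"bone"`, `"soft-tissue"`, `"lung"`,
#'   `"lymph-node"`.
#' @param dose_mg_kg total antibody mass dose (tracer + predose) in mg/kg.
#' @param scan_times scan times, hours post-injection, strictly increasing.
#' @param suv SUVpeak values (NA allowed).
#' @return an object of class `lesion_tac`.
#' @export
lesion_tac <- function(patient_id, lesion_id, administration, dose_mg_kg,
                       scan_times, suv,
                       tissue_class = c("soft-tissue", "bone", "lung",
                                        "lymph-node")) {
  tissue_class <- match.arg(tissue_class)
  check_times(scan_times, "scan_times")
  if (length(suv) != length(scan_times))
    stop_domain("'suv' must match 'scan_times' in length")
  check_scalar(dose_mg_kg, "dose_mg_kg", nonneg = TRUE)
  structure(
    list(patient_id = as.character(patient_id),
         lesion_id = as.character(lesion_id),
         tissue_class = tissue_class,
         administration = match.arg(administration, c("first", "second")),
         dose_mg_kg = dose_mg_kg,
         scan_times = as.numeric(scan_times), suv = as.numeric(suv)),
    class = "lesion_tac")
}

#' Patlak transformation of a lesion time-activity curve
#'
#' The graphical linearization for irreversible uptake: the tissue signal
#' SUV(t) = A Cp(t) + B AUC(t) is divided through by Cp(t), giving
#' y = SUV/Cp against "normalized time" x = AUC(t)/Cp(t). On these axes
#' irreversible accumulation is a straight line with slope B (net
#' internalization rate, 1/h) and intercept A (reversible distribution).
#'
#' @param tac a [lesion_tac()].
#' @param plasma the matching [plasma_curve()] (same patient and
#'   administration).
#' @param min_fit_time_h scans earlier than this are excluded; the model
#'   assumes the reversible compartment has equilibrated with plasma, which
#'   is not yet true at the 2 h scan. Default 24 h.
#' @param method plasma interpolation passed to [cumulative_auc()].
#' @return data.frame with columns `time_h`, `x` (hours), `y`
#'   (dimensionless), ordered by time; scans with missing SUV or zero Cp are
#'   dropped (the latter with a warning).
#' @export
patlak_points <- function(tac, plasma, min_fit_time_h = 24,
                          method = c("loglinear", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(tac, "lesion_tac"), inherits(plasma, "plasma_curve"))
  if (!identical(tac$patient_id, plasma$patient_id) ||
      !identical(tac$administration, plasma$administration))
    stop_domain("lesion and plasma curve belong to different patient/administration")
  keep <- !is.na(tac$suv) & tac$scan_times >= min_fit_time_h
  t <- tac$scan_times[keep]; s <- tac$suv[keep]
  if (length(t) == 0)
    return(data.frame(time_h = numeric(0), x = numeric(0), y = numeric(0)))
  cp <- interpolate_cp(plasma, t, method)
  if (any(cp <= 0)) {
    warning("dropping scan time(s) with zero plasma concentration")
    t <- t[cp > 0]; s <- s[cp > 0]; cp <- cp[cp > 0]
  }
  auc <- cumulative_auc(plasma, t, method)
  data.frame(time_h = t, x = auc / cp, y = s / cp)
}

#' Fit the Patlak line
#'
#' Ordinary least squares through the Patlak points. With exactly two points
#' the line passes through both and r-squared is 1 by construction. Negative
#' slopes are retained (not truncated) but flagged, so that downstream ratio
#' statistics stay unbiased.
#'
#' @param points data.frame with columns `x`, `y` as from [patlak_points()].
#' @return an object of class `patlak_fit` with fields `intercept_A`,
#'   `slope_B` (1/h), `r_squared`, `n_points`, `x_values`, `y_values`,
#'   `flags` (character vector, possibly empty).
#' @export
patlak_fit <- function(points) {
  x <- points$x; y <- points$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop_domain("Patlak fit needs at least 2 points")
  if (diff(range(x)) < 1e-12)
    stop_domain("Patlak fit needs distinct x values")
  fit <- stats::lm.fit(cbind(1, x), y)
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (length(x) == 2L || ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  flags <- character(0)
  if (b < 0) flags <- c(flags, "negative_slope")
  structure(
    list(intercept_A = a, slope_B = b, r_squared = r2,
         n_points = length(x), x_values = x, y_values = y, flags = flags),
    class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> A = %.4g, B = %.4g /h, r2 = %.4f, n = %d%s\n",
              x$intercept_A, x$slope_B, x$r_squared, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Patlak analysis of a whole study table
#'
#' Convenience batch driver: runs [patlak_points()] + [patlak_fit()] for
#' every lesion x administration in a study (simulated or read from CSV).
#'
#' @param plasma_tab data.frame with columns `patient_id`, `administration`,
#'   `time_h`, `suv` (and optionally `conc_ug_ml`).
#' @param lesion_tab data.frame with columns `patient_id`, `lesion_id`,
#'   `tissue_class`, `administration`, `dose_mg_kg`, `time_h`, `suv_peak`.
#' @inheritParams patlak_points
#' @return data.frame, one row per lesion x administration: `patient_id`,
#'   `lesion_id`, `administration`, `dose_mg_kg`, `A`, `B_per_h`, `r2`,
#'   `n_points`, `flags`. Lesions with fewer than 2 usable scans are skipped.
#' @export
patlak_study <- function(plasma_tab, lesion_tab, min_fit_time_h = 24,
                         method = c("loglinear", "linear")) {
  method <- match.arg(method)
  out <- list()
  keys <- unique(lesion_tab[, c("patient_id", "lesion_id", "administration")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    lrows <- lesion_tab[lesion_tab$patient_id == k$patient_id &
                        lesion_tab$lesion_id == k$lesion_id &
                        lesion_tab$administration == k$administration, ]
    prows <- plasma_tab[plasma_tab$patient_id == k$patient_id &
                        plasma_tab$administration == k$administration, ]
    if (nrow(prows) < 2L) next
    ord <- order(lrows$time_h)
    lrows <- lrows[ord, ]
    curve <- plasma_curve(prows$time_h[order(prows$time_h)],
                          prows$suv[order(prows$time_h)],
                          patient_id = k$patient_id,
                          administration = k$administration)
    tac <- lesion_tac(k$patient_id, k$lesion_id, k$administration,
                      dose_mg_kg = lrows$dose_mg_kg[1],
                      scan_times = lrows$time_h, suv = lrows$suv_peak,
                      tissue_class = lrows$tissue_class[1])
    pts <- patlak_points(tac, curve, min_fit_time_h, method)
    if (nrow(pts) < 2L) next
    fit <- patlak_fit(pts)
    out[[length(out) + 1L]] <- data.frame(
      patient_id = k$patient_id, lesion_id = k$lesion_id,
      administration = k$administration, dose_mg_kg = lrows$dose_mg_kg[1],
      A = fit$intercept_A, B_per_h = fit$slope_B, r2 = fit$r_squared,
      n_points = fit$n_points,
      flags = paste(fit$flags, collapse = ";"))
  }
  if (length(out) == 0)
    return(data.frame(patient_id = character(0), lesion_id = character(0),
                      administration = character(0), dose_mg_kg = numeric(0),
                      A = numeric(0), B_per_h = numeric(0), r2 = numeric(0),
                      n_points = integer(0), flags = character(0)))
  do.call(rbind, out)
}
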