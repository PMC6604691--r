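#' Predicted uptake-rate ratio under the saturation model
#'
#' The dose-inhibition curve for the internalization-rate ratio (percent of
#' baseline): a hyperbolically inhibited specific term plus a constant
#' nonspecific floor,
#' `R(dose) = (1 - dose/(dose + id50)) * (100 - rnsp) + rnsp`.
#' `R(0) = 100` exactly; the curve is strictly decreasing for `rnsp < 100`
#' and tends to `rnsp` at infinite dose.
#'
#' @param dose competing antibody mass dose, mg/kg.
#' @param id50 half-maximal inhibitory mass dose, mg/kg (> 0).
#' @param rnsp nonspecific residual percentage, in \[0, 100\].
#' @return percent ratio.
#' @export
predict_R <- function(dose, id50, rnsp) {
  check_scalar(id50, "id50", positive = TRUE)
  check_scalar(rnsp, "rnsp", nonneg = TRUE)
  if (rnsp > 100) stop_domain("'rnsp' must be in [0, 100]")
  if (any(dose < 0)) stop_domain("'dose' must be >= 0")
  (1 - dose / (dose + id50)) * (100 - rnsp) + rnsp
}

#' Normalize an on-treatment Patlak slope to its baseline
#'
#' Each lesion carries its own receptor density, so slopes are comparable
#' across lesions only as percentages of the lesion's own tracer-only
#' baseline slope. A baseline normalized against itself is 100% by
#' definition. Lesions whose baseline slope is not positive cannot be
#' normalized and are excluded with a recorded reason.
#'
#' @param baseline,treatment [patlak_fit()] objects for the same lesion.
#' @param patient_id,lesion_id,dose_mg_kg context carried onto the ratio.
#' @return data.frame row with `patient_id`, `lesion_id`, `dose_mg_kg`,
#'   `ratio_pct`, `excluded` (logical), `reason` (string, `""` if kept).
#' @export
normalize_to_baseline <- function(baseline, treatment, patient_id = "p1",
                                  lesion_id = "l1", dose_mg_kg = 0) {
  stopifnot(inherits(baseline, "patlak_fit"), inherits(treatment, "patlak_fit"))
  if (baseline$slope_B <= 0) {
    return(data.frame(patient_id = patient_id, lesion_id = lesion_id,
                      dose_mg_kg = dose_mg_kg, ratio_pct = NA_real_,
                      excluded = TRUE,
                      reason = "baseline slope not positive"))
  }
  data.frame(patient_id = patient_id, lesion_id = lesion_id,
             dose_mg_kg = dose_mg_kg,
             ratio_pct = 100 * treatment$slope_B / baseline$slope_B,
             excluded = FALSE, reason = "")
}

#' Slope ratios for a whole study
#'
#' Pairs each lesion's second-administration Patlak slope with its baseline
#' slope from the fit table produced by [patlak_study()].
#'
#' @param fits data.frame from [patlak_study()].
#' @return data.frame of ratios (see [normalize_to_baseline()]), plus a
#'   `baseline_dose_mg_kg` column (the tracer-only mass dose on the same
#'   axis, used for anchor points).
#' @export
slope_ratios <- function(fits) {
  out <- list()
  keys <- unique(fits[, c("patient_id", "lesion_id")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    b <- fits[fits$patient_id == k$patient_id &
              fits$lesion_id == k$lesion_id &
              fits$administration == "first", ]
    s <- fits[fits$patient_id == k$patient_id &
              fits$lesion_id == k$lesion_id &
              fits$administration == "second", ]
    if (nrow(b) != 1L || nrow(s) != 1L) next
    r <- if (b$B_per_h <= 0)
      data.frame(patient_id = k$patient_id, lesion_id = k$lesion_id,
                 dose_mg_kg = s$dose_mg_kg, ratio_pct = NA_real_,
                 excluded = TRUE, reason = "baseline slope not positive")
    else
      data.frame(patient_id = k$patient_id, lesion_id = k$lesion_id,
                 dose_mg_kg = s$dose_mg_kg,
                 ratio_pct = 100 * s$B_per_h / b$B_per_h,
                 excluded = FALSE, reason = "")
    r$baseline_dose_mg_kg <- b$dose_mg_kg
    out[[length(out) + 1L]] <- r
  }
  if (length(out) == 0)
    return(data.frame(patient_id = character(0), lesion_id = character(0),
                      dose_mg_kg = numeric(0), ratio_pct = numeric(0),
                      excluded = logical(0), reason = character(0),
                      baseline_dose_mg_kg = numeric(0)))
  do.call(rbind, out)
}

#' Fit the dose-inhibition saturation model
#'
#' Nonlinear least squares of the ratio model over pooled lesion-level
#' points (all patients' lesions weighted equally). Bounds: `id50 > 0`,
#' `rnsp` in \[0, 100\]. Starting values are scale-aware: `id50` at the
#' median nonzero dose, `rnsp` at the minimum observed ratio clipped to
#' \[0, 100\].
#'
#' Because the tracer itself carries antibody mass, the baseline
#' administration sits at a small nonzero dose on the mg/kg axis. When
#' `baseline_dose` is supplied (the default path in [run_pipeline()]), the
#' model prediction is itself normalized to that dose,
#' `100 * R(dose)/R(baseline_dose)`, which is exactly consistent with how
#' the observed ratios are formed and pins the baseline to 100%; with
#' `baseline_dose = NULL` the raw curve `R(dose)` is fitted directly.
#'
#' @param ratios data.frame with columns `dose_mg_kg`, `ratio_pct` (rows
#'   with `excluded == TRUE` or missing ratios are dropped); typically from
#'   [slope_ratios()].
#' @param include_baseline_anchor add one (baseline_dose, 100%) point per
#'   distinct patient baseline, mirroring baseline studies normalized to
#'   100%. Requires `baseline_dose` (or a `baseline_dose_mg_kg` column).
#' @param fix_rnsp optional: hold `rnsp` fixed at this percentage and fit
#'   `id50` alone.
#' @param baseline_dose tracer-only mass dose in mg/kg (see above); `NULL`
#'   fits the unnormalized curve.
#' @return object of class `dose_inhibition_fit`: `id50`, `rnsp`, `id90`
#'   (= 9 x id50, the algebraic identity of the hyperbolic model),
#'   `residual_sse`, `converged`, `flags`, `n_points`, and `se` (named
#'   standard errors when estimable).
#' @export
fit_inhibition <- function(ratios, include_baseline_anchor = TRUE,
                           fix_rnsp = NULL, baseline_dose = NULL) {
  r <- ratios
  if (!is.null(r$excluded)) r <- r[!r$excluded, , drop = FALSE]
  r <- r[is.finite(r$ratio_pct) & is.finite(r$dose_mg_kg), , drop = FALSE]
  if (is.null(baseline_dose) && !is.null(r$baseline_dose_mg_kg) &&
      nrow(r) > 0)
    baseline_dose <- stats::median(r$baseline_dose_mg_kg)
  dose <- r$dose_mg_kg; ratio <- r$ratio_pct
  if (include_baseline_anchor) {
    if (is.null(baseline_dose))
      stop_domain("baseline anchor requested but no baseline dose known")
    n_anchor <- max(1L, length(unique(r$patient_id)))
    dose <- c(rep(baseline_dose, n_anchor), dose)
    ratio <- c(rep(100, n_anchor), ratio)
  }
  n_free <- if (is.null(fix_rnsp)) 2L else 1L
  if (length(unique(dose)) < n_free + 1L)
    stop_domain(sprintf(
      "under-determined: %d free parameter(s) need > %d distinct dose levels",
      n_free, n_free))
  flags <- character(0)
  if (stats::sd(ratio) < 1e-9) {
    return(structure(
      list(id50 = NA_real_, rnsp = NA_real_, id90 = NA_real_,
           residual_sse = 0, converged = FALSE,
           flags = "non_identifiable_flat", n_points = length(ratio),
           se = NULL, dose = dose, ratio = ratio,
           baseline_dose = baseline_dose, fix_rnsp = fix_rnsp),
      class = "dose_inhibition_fit"))
  }
  model <- function(d, id50, rnsp) {
    p <- predict_R(d, id50, rnsp)
    if (!is.null(baseline_dose)) 100 * p / predict_R(baseline_dose, id50, rnsp)
    else p
  }
  id50_0 <- stats::median(dose[dose > if (is.null(baseline_dose)) 0
                               else baseline_dose + 1e-12])
  if (!is.finite(id50_0) || id50_0 <= 0) id50_0 <- stats::median(dose[dose > 0])
  rnsp_0 <- min(max(min(ratio), 0), 100)
  dat <- data.frame(d = dose, y = ratio)
  fit <- NULL; converged <- FALSE
  if (is.null(fix_rnsp)) {
    fit <- tryCatch(
      stats::nls(y ~ model(d, id50, rnsp), data = dat,
                 start = list(id50 = id50_0, rnsp = rnsp_0),
                 lower = c(id50 = 1e-6, rnsp = 0),
                 upper = c(id50 = 1e6, rnsp = 100),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
  } else {
    check_scalar(fix_rnsp, "fix_rnsp", nonneg = TRUE)
    if (fix_rnsp > 100) stop_domain("'fix_rnsp' must be in [0, 100]")
    fit <- tryCatch(
      stats::nls(y ~ model(d, id50, fix_rnsp), data = dat,
                 start = list(id50 = id50_0),
                 lower = c(id50 = 1e-6), upper = c(id50 = 1e6),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    ## fall back to bounded quasi-Newton on the SSE surface
    obj <- function(par) {
      rn <- if (is.null(fix_rnsp)) par[2] else fix_rnsp
      sum((ratio - model(dose, par[1], rn))^2)
    }
    par0 <- if (is.null(fix_rnsp)) c(id50_0, rnsp_0) else id50_0
    lower <- if (is.null(fix_rnsp)) c(1e-6, 0) else 1e-6
    upper <- if (is.null(fix_rnsp)) c(1e6, 100) else 1e6
    op <- stats::optim(par0, obj, method = "L-BFGS-B",
                       lower = lower, upper = upper)
    id50 <- op$par[1]
    rnsp <- if (is.null(fix_rnsp)) op$par[2] else fix_rnsp
    sse <- op$value
    converged <- op$convergence == 0
    se <- NULL
    flags <- c(flags, "nls_failed_optim_fallback")
  } else {
    cf <- stats::coef(fit)
    id50 <- unname(cf["id50"])
    rnsp <- if (is.null(fix_rnsp)) unname(cf["rnsp"]) else fix_rnsp
    sse <- sum(stats::residuals(fit)^2)
    converged <- fit$convInfo$isConv
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) NULL)
    if (is.null(se)) flags <- c(flags, "covariance_not_estimable")
  }
  if (!converged) flags <- c(flags, "not_converged")
  structure(
    list(id50 = id50, rnsp = rnsp, id90 = 9 * id50,
         residual_sse = sse, converged = converged, flags = flags,
         n_points = length(ratio), se = se, dose = dose, ratio = ratio,
         baseline_dose = baseline_dose, fix_rnsp = fix_rnsp),
    class = "dose_inhibition_fit")
}

#' @export
print.dose_inhibition_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_inhibition_fit> ID50 = %.3g mg/kg, Rnsp = %.3g%%, ID90 = %.3g mg/kg (n = %d, SSE = %.3g)%s\n",
    x$id50, x$rnsp, x$id90, x$n_points, x$residual_sse,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Inhibitory mass dose at a given saturation level
#'
#' The dose at which the specific (dose-dependent) term of the saturation
#' model is inhibited by `q` percent. Inverting the hyperbola analytically:
#' `dose = id50 * q / (100 - q)`, so the 90% inhibitory dose is always
#' exactly nine times the ID50.
#'
#' @param fit a [fit_inhibition()] result, or a bare numeric id50 (mg/kg).
#' @param q inhibition percentage, strictly inside (0, 100).
#' @return dose in mg/kg.
#' @export
inhibitory_dose <- function(fit, q) {
  id50 <- if (inherits(fit, "dose_inhibition_fit")) fit$id50 else fit
  check_scalar(id50, "id50", positive = TRUE)
  check_scalar(q, "q")
  if (q <= 0 || q >= 100) stop_domain("'q' must be strictly inside (0, 100)")
  id50 * q / (100 - q)
}

#' Plot a dose-inhibition fit
#'
#' Ratio percentage against mass dose on a log axis, the fitted curve, and
#' the nonspecific asymptote as a dotted line.
#'
#' @param x a `dose_inhibition_fit`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.dose_inhibition_fit <- function(x, ...) {
  if (!is.finite(x$id50)) stop_domain("cannot plot a non-identifiable fit")
  d <- pmax(x$dose, 1e-3)
  graphics::plot(d, x$ratio, log = "x",
                 xlab = "total antibody mass dose (mg/kg)",
                 ylab = "internalization rate (% of baseline)",
                 ylim = c(0, max(110, x$ratio)), ...)
  dd <- exp(seq(log(min(d)), log(max(d) * 1.5), length.out = 200))
  pr <- predict_R(dd, x$id50, x$rnsp)
  if (!is.null(x$baseline_dose))
    pr <- 100 * pr / predict_R(x$baseline_dose, x$id50, x$rnsp)
  graphics::lines(dd, pr)
  graphics::abline(h = x$rnsp, lty = 3)
  invisible(x)
}
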