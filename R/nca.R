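#' Noncompartmental analysis of a concentration-time curve
#'
#' Model-free summary of an unlabeled-drug plasma curve: maximum observed
#' concentration (Cmax; first occurrence on ties), its time (Tmax), and the
#' area under the curve up to the last observation (AUClast) by the linear
#' trapezoid rule. No extrapolation to infinity is performed.
#'
#' @param time sample times in hours, strictly increasing.
#' @param conc concentrations in ug/mL, non-negative.
#' @param t_end optional window end (hours): samples after `t_end` are
#'   ignored, so AUClast can be reported over a fixed window such as 0-48 h.
#' @param method `"linear"` trapezoid (default) or `"linear_up_log_down"`
#'   (logarithmic trapezoid on strictly decreasing positive segments).
#' @return list of class `nca_result`: `cmax`, `tmax`, `auc_last`, `t_last`,
#'   `flags`.
#' @export
nca <- function(time, conc, t_end = NULL, method = c("linear",
                                                     "linear_up_log_down")) {
  method <- match.arg(method)
  check_times(time, "time")
  if (length(time) < 2L) stop_domain("NCA needs at least 2 samples")
  if (length(conc) != length(time))
    stop_domain("'conc' must match 'time' in length")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_domain("'conc' must be finite and >= 0")
  if (!is.null(t_end)) {
    keep <- time <= t_end + 1e-12
    time <- time[keep]; conc <- conc[keep]
    if (length(time) < 2L) stop_domain("fewer than 2 samples inside window")
  }
  flags <- character(0)
  if (all(conc == 0)) flags <- c(flags, "all_zero_curve")
  i_max <- which.max(conc)            # first occurrence on ties
  auc <- 0
  for (i in seq_len(length(time) - 1L)) {
    dt <- time[i + 1L] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    auc <- auc + if (method == "linear_up_log_down" &&
                     c1 > c2 && c2 > 0) {
      (c1 - c2) * dt / log(c1 / c2)
    } else {
      (c1 + c2) / 2 * dt
    }
  }
  structure(list(cmax = conc[i_max], tmax = time[i_max],
                 auc_last = auc, t_last = time[length(time)],
                 flags = flags),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> Cmax = %.4g ug/mL at Tmax = %.3g h; AUClast = %.5g h*ug/mL (t_last = %.3g h)\n",
              x$cmax, x$tmax, x$auc_last, x$t_last))
  invisible(x)
}

#' Ratio of activity-derived to immunoassay drug concentration
#'
#' Consistency check between the radiolabeled and unlabeled dispositions:
#' the radioactivity channel (SUV) is recalculated to a mass concentration
#' using the administered antibody mass and body weight
#' (`conc = SUV * total_mass_mg / body_weight_kg`, in ug/mL at 1 g/mL
#' density), then divided per time point by the immunoassay concentration.
#' A ratio near 1 with small spread indicates the label traces the drug.
#'
#' @param curve a [plasma_curve()] carrying both channels (`cp` as SUV and
#'   `conc_ug_ml`).
#' @param total_mass_mg administered antibody mass (tracer + predose), mg.
#' @param body_weight_kg patient body weight, kg.
#' @return list with `mean_ratio`, `sd`, `n` (time points used), `ratios`;
#'   time points with a zero immunoassay concentration are excluded with a
#'   warning.
#' @export
labeled_unlabeled_ratio <- function(curve, total_mass_mg, body_weight_kg) {
  stopifnot(inherits(curve, "plasma_curve"))
  if (is.null(curve$conc_ug_ml))
    stop_domain("plasma curve has no unlabeled-concentration channel")
  check_scalar(total_mass_mg, "total_mass_mg", positive = TRUE)
  check_scalar(body_weight_kg, "body_weight_kg", positive = TRUE)
  act_mass <- curve$cp * total_mass_mg / body_weight_kg
  denom <- curve$conc_ug_ml
  keep <- denom > 0
  if (any(!keep))
    warning(sprintf("%d time point(s) with zero immunoassay concentration excluded",
                    sum(!keep)))
  ratios <- act_mass[keep] / denom[keep]
  list(mean_ratio = mean(ratios),
       sd = if (length(ratios) > 1L) stats::sd(ratios) else 0,
       n = length(ratios), ratios = ratios)
}

#' NCA over a whole study plasma table
#'
#' @param plasma_tab data.frame with `patient_id`, `administration`,
#'   `time_h`, `conc_ug_ml`.
#' @param t_end optional AUC window end, hours.
#' @return data.frame, one row per patient x administration with `cmax`,
#'   `tmax`, `auc_last`, `t_last`.
#' @export
nca_study <- function(plasma_tab, t_end = NULL) {
  keys <- unique(plasma_tab[, c("patient_id", "administration")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    rows <- plasma_tab[plasma_tab$patient_id == k$patient_id &
                       plasma_tab$administration == k$administration, ]
    rows <- rows[order(rows$time_h), ]
    res <- nca(rows$time_h, rows$conc_ug_ml, t_end = t_end)
    data.frame(patient_id = k$patient_id, administration = k$administration,
               cmax = res$cmax, tmax = res$tmax,
               auc_last = res$auc_last, t_last = res$t_last)
  })
  do.call(rbind, out)
}
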