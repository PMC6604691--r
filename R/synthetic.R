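#' Configuration of a synthetic immuno-PET study
#'
#' Describes the cohort design of a two-administration target-engagement
#' study: every patient first receives a tracer-only (baseline)
#' administration of the radiolabeled antibody, then, two weeks later, a
#' predose of unlabeled antibody followed by a second tracer administration.
#' Defaults mirror a 6-patient dose-escalation design: 37 MBq of tracer on
#' 8 mg of antibody, predose levels spanning 0-30 mg/kg, PET scans at about
#' 2, 48 and 120 h post-injection, and blood sampling at 1, 3, 6, 12 and
#' 24 h plus immediately before each scan.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient quantifiable lesions per patient (recycled).
#' @param body_weight_kg body weight per patient (recycled).
#' @param injected_activity_MBq injected tracer activity.
#' @param tracer_mass_mg antibody mass carried by the tracer itself (mg);
#'   it competes for the receptor like any other antibody mass, so it is
#'   added to every dose on the mg/kg axis.
#' @param predose_levels_mg_kg unlabeled-antibody predose (mg/kg) given
#'   before the second tracer administration, one per patient (recycled);
#'   0 means tracer-only again.
#' @param scan_times hours post-injection of the PET scans (>= 2 required).
#' @param plasma_sample_times blood sampling times (hours); scan times are
#'   always included as well.
#' @param pk_params plasma model: `c0_suv` (plasma SUV extrapolated to t=0),
#'   `frac_fast` (fraction of the fast distribution phase), `lambda_fast`
#'   and `lambda_slow` (1/h), and `lambda_tmdd` (1/h), the saturable
#'   target-mediated addition to the terminal rate which vanishes at high
#'   mass dose: lambda_terminal(dose) = lambda_slow +
#'   lambda_tmdd * ID50 / (dose + ID50).
#' @param lesion_params `A` (dimensionless reversible coefficient), `B0`
#'   (baseline internalization slope, 1/h), and lognormal inter-lesion
#'   coefficients of variation `cv_A`, `cv_B0`.
#' @param engagement_params `id50` (mg/kg) and `rnsp` (percent residual
#'   internalization at full receptor saturation).
#' @param noise_cv multiplicative (lognormal) measurement noise CV applied
#'   per lesion scan; default 0.10.
#' @param seed integer RNG seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_patients = 6,
                         lesions_per_patient = 3,
                         body_weight_kg = 75,
                         injected_activity_MBq = 37,
                         tracer_mass_mg = 8,
                         predose_levels_mg_kg = c(0.32, 1, 30, 30, 0.5, 0),
                         scan_times = c(2, 48, 120),
                         plasma_sample_times = c(1, 3, 6, 12, 24),
                         pk_params = list(c0_suv = 20, frac_fast = 0.35,
                                          lambda_fast = 0.08,
                                          lambda_slow = 0.003,
                                          lambda_tmdd = 0.011),
                         lesion_params = list(A = 0.3, B0 = 0.005,
                                              cv_A = 0.2, cv_B0 = 0.4),
                         engagement_params = list(id50 = 2, rnsp = 30),
                         noise_cv = 0.10,
                         seed = 1L) {
  check_scalar(n_patients, "n_patients", positive = TRUE)
  if (any(body_weight_kg <= 0))
    stop_domain("invalid config: body weight must be > 0")
  check_scalar(injected_activity_MBq, "injected_activity_MBq", positive = TRUE)
  check_scalar(tracer_mass_mg, "tracer_mass_mg", positive = TRUE)
  if (any(predose_levels_mg_kg < 0))
    stop_domain("invalid config: predose levels must be >= 0")
  check_times(scan_times, "scan_times")
  if (length(scan_times) < 2L)
    stop_domain("invalid config: at least 2 scan times are required")
  check_times(plasma_sample_times, "plasma_sample_times")
  check_scalar(engagement_params$id50, "id50", positive = TRUE)
  check_scalar(engagement_params$rnsp, "rnsp", nonneg = TRUE)
  if (engagement_params$rnsp > 100)
    stop_domain("invalid config: rnsp must be in [0, 100]")
  check_scalar(lesion_params$A, "A", nonneg = TRUE)
  check_scalar(lesion_params$B0, "B0", nonneg = TRUE)
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  structure(
    list(n_patients = as.integer(n_patients),
         lesions_per_patient = rep_len(as.integer(lesions_per_patient),
                                       n_patients),
         body_weight_kg = rep_len(as.numeric(body_weight_kg), n_patients),
         injected_activity_MBq = injected_activity_MBq,
         tracer_mass_mg = tracer_mass_mg,
         predose_levels_mg_kg = rep_len(as.numeric(predose_levels_mg_kg),
                                        n_patients),
         scan_times = as.numeric(scan_times),
         plasma_sample_times = as.numeric(plasma_sample_times),
         pk_params = pk_params, lesion_params = lesion_params,
         engagement_params = engagement_params,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "study_config")
}

#' True internalization slope under the saturation model
#'
#' Ground-truth dose dependence of the Patlak slope: the specific
#' (receptor-mediated) component of the internalization rate is inhibited
#' hyperbolically by competing antibody mass dose, while a nonspecific
#' fraction `rnsp` (pinocytosis and similar) persists at any dose:
#'
#' `B(dose) = B0 * ((1 - dose/(dose + id50)) * (100 - rnsp) + rnsp) / 100`
#'
#' @param dose competing antibody mass dose, mg/kg (>= 0).
#' @param B0 baseline internalization slope at zero competing dose, 1/h.
#' @param id50 half-maximal inhibitory mass dose, mg/kg (> 0).
#' @param rnsp residual percent at full saturation, in \[0, 100\].
#' @return slope in 1/h; equals `B0` at dose 0 and `B0 * rnsp/100` in the
#'   high-dose limit; strictly decreasing in dose when `rnsp < 100`.
#' @export
true_slope <- function(dose, B0, id50, rnsp) {
  if (any(dose < 0)) stop_domain("'dose' must be >= 0")
  check_scalar(B0, "B0", nonneg = TRUE)
  check_scalar(id50, "id50", positive = TRUE)
  check_scalar(rnsp, "rnsp", nonneg = TRUE)
  if (rnsp > 100) stop_domain("'rnsp' must be in [0, 100]")
  B0 * ((1 - dose / (dose + id50)) * (100 - rnsp) + rnsp) / 100
}

## mean-1 lognormal multipliers with coefficient of variation cv
lognormal_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a plasma input function
#'
#' Biexponential plasma kinetics with a saturable (target-mediated) terminal
#' phase: at low antibody mass dose the target acts as an extra clearance
#' route and the terminal rate is fastest; as the dose saturates the target
#' the terminal rate falls toward its linear floor. The curve is sampled at
#' the configured blood-sampling times plus the scan times and is
#' deterministic (measurement noise lives on the lesion channel).
#'
#' @param config a [study_config()].
#' @param dose unlabeled predose in mg/kg (>= 0); the tracer's own antibody
#'   mass, converted to mg/kg, is always added on top.
#' @param seed accepted for interface symmetry; the curve itself is
#'   deterministic.
#' @param patient index into the per-patient config vectors (body weight).
#' @param administration label stored on the returned curve.
#' @return a [plasma_curve()] with the unlabeled-concentration channel
#'   filled in (total antibody mass assumed to share the tracer's kinetics).
#' @export
simulate_plasma <- function(config, dose, seed = NULL, patient = 1L,
                            administration = c("first", "second")) {
  administration <- match.arg(administration)
  stopifnot(inherits(config, "study_config"))
  check_scalar(dose, "dose", nonneg = TRUE)
  bw <- config$body_weight_kg[patient]
  if (!is.finite(bw) || bw <= 0 || config$injected_activity_MBq <= 0)
    stop_domain("invalid config: body weight and injected activity must be > 0")
  total_dose <- dose + config$tracer_mass_mg / bw
  p <- config$pk_params
  id50 <- config$engagement_params$id50
  lam2 <- p$lambda_slow + p$lambda_tmdd * id50 / (total_dose + id50)
  times <- sort(unique(c(config$plasma_sample_times, config$scan_times)))
  cp <- p$c0_suv * (p$frac_fast * exp(-p$lambda_fast * times) +
                    (1 - p$frac_fast) * exp(-lam2 * times))
  total_mass_mg <- total_dose * bw
  conc <- cp * total_mass_mg / bw   # SUV -> ug/mL at 1 g/mL density
  plasma_curve(times, cp, patient_id = paste0("p", patient),
               administration = administration, conc_ug_ml = conc)
}

#' Simulate a lesion time-activity curve
#'
#' Forward model of the tissue signal: a reversible component proportional
#' to the instantaneous plasma concentration plus an irreversible
#' (internalized) component proportional to the cumulative plasma exposure,
#' `SUV(t) = A Cp(t) + B AUC(t)`, with multiplicative lognormal measurement
#' noise applied independently per scan.
#'
#' @param plasma a [plasma_curve()] covering `[0, max(scan_times)]`.
#' @param A dimensionless reversible coefficient (>= 0).
#' @param B internalization slope, 1/h (>= 0).
#' @param scan_times scan times in hours.
#' @param noise_cv fractional coefficient of variation of the lognormal
#'   noise (0 disables noise).
#' @param seed optional RNG seed for the noise draws.
#' @param lesion_id,tissue_class,dose_mg_kg metadata stored on the result.
#' @return a [lesion_tac()].
#' @export
simulate_lesion_tac <- function(plasma, A, B, scan_times, noise_cv = 0,
                                seed = NULL, lesion_id = "l1",
                                tissue_class = "soft-tissue",
                                dose_mg_kg = 0) {
  stopifnot(inherits(plasma, "plasma_curve"))
  check_scalar(A, "A", nonneg = TRUE)
  check_scalar(B, "B", nonneg = TRUE)
  check_times(scan_times, "scan_times")
  if (max(scan_times) > max(plasma$times) + 1e-12)
    stop_domain("scan time beyond plasma support: extrapolation refused")
  cp <- interpolate_cp(plasma, scan_times)
  auc <- cumulative_auc(plasma, scan_times)
  suv <- A * cp + B * auc
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    suv <- suv * lognormal_mult(length(suv), noise_cv)
  }
  lesion_tac(plasma$patient_id, lesion_id, plasma$administration,
             dose_mg_kg = dose_mg_kg, scan_times = scan_times, suv = suv,
             tissue_class = tissue_class)
}

#' Generate a complete synthetic study with ground truth
#'
#' Assembles the two-administration design: per patient, a tracer-only
#' baseline administration and a second administration after the assigned
#' unlabeled predose. Per-lesion reversible coefficients and baseline
#' internalization slopes are drawn lognormally around the configured
#' centers; the realized slope at each administration follows
#' [true_slope()] applied to that administration's total mass dose (tracer
#' mass included), so the generated data satisfy the saturation model
#' exactly before noise.
#'
#' @param config a [study_config()].
#' @return an object of class `synthetic_study`: list with `plasma`
#'   (long-format data.frame: patient_id, administration, time_h, suv,
#'   conc_ug_ml), `lesions` (patient_id, lesion_id, tissue_class,
#'   administration, dose_mg_kg, time_h, suv_peak), and `truth` (the config
#'   plus a per-lesion data.frame of realized A, B0 and B at each
#'   administration).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  lp <- config$lesion_params
  ep <- config$engagement_params
  classes <- c("bone", "soft-tissue", "lung", "lymph-node")
  class_prob <- c(0.45, 0.15, 0.10, 0.30)  # mix typical of advanced solid tumors
  plasma_rows <- list(); lesion_rows <- list(); truth_rows <- list()
  for (pt in seq_len(config$n_patients)) {
    bw <- config$body_weight_kg[pt]
    tracer_mg_kg <- config$tracer_mass_mg / bw
    predose <- config$predose_levels_mg_kg[pt]
    doses <- c(first = tracer_mg_kg, second = predose + tracer_mg_kg)
    nles <- config$lesions_per_patient[pt]
    A_l <- lp$A * lognormal_mult(nles, lp$cv_A)
    B0_l <- lp$B0 * lognormal_mult(nles, lp$cv_B0)
    cls_l <- sample(classes, nles, replace = TRUE, prob = class_prob)
    for (adm in c("first", "second")) {
      pd <- if (adm == "first") 0 else predose
      curve <- simulate_plasma(config, pd, patient = pt,
                               administration = adm)
      plasma_rows[[length(plasma_rows) + 1L]] <- data.frame(
        patient_id = curve$patient_id, administration = adm,
        time_h = curve$times, suv = curve$cp,
        conc_ug_ml = curve$conc_ug_ml)
      for (les in seq_len(nles)) {
        B_true <- true_slope(doses[[adm]], B0_l[les], ep$id50, ep$rnsp)
        tac <- simulate_lesion_tac(
          curve, A_l[les], B_true, config$scan_times,
          noise_cv = config$noise_cv,
          seed = sub_seed(config$seed, pt, les,
                          if (adm == "first") 1L else 2L),
          lesion_id = paste0("p", pt, "_les", les),
          tissue_class = cls_l[les], dose_mg_kg = doses[[adm]])
        lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
          patient_id = tac$patient_id, lesion_id = tac$lesion_id,
          tissue_class = tac$tissue_class, administration = adm,
          dose_mg_kg = doses[[adm]], time_h = tac$scan_times,
          suv_peak = tac$suv)
      }
    }
    truth_rows[[pt]] <- data.frame(
      patient_id = paste0("p", pt),
      lesion_id = paste0("p", pt, "_les", seq_len(nles)),
      tissue_class = cls_l, A = A_l, B0 = B0_l,
      dose_first_mg_kg = doses[["first"]],
      dose_second_mg_kg = doses[["second"]],
      B_first = true_slope(doses[["first"]], 1, ep$id50, ep$rnsp) * B0_l,
      B_second = true_slope(doses[["second"]], 1, ep$id50, ep$rnsp) * B0_l)
  }
  structure(
    list(plasma = do.call(rbind, plasma_rows),
         lesions = do.call(rbind, lesion_rows),
         truth = list(config = config, lesions = do.call(rbind, truth_rows))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d patients, %d lesion TAC rows, %d plasma rows\n",
              x$truth$config$n_patients, nrow(x$lesions), nrow(x$plasma)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the plain-text interchange files used by the rest of the pipeline:
#' `plasma.csv`, `lesions.csv` and `truth.json` (full config plus realized
#' per-lesion parameters). Output is byte-stable for a fixed seed.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("plasma.csv", "lesions.csv", "truth.json"))
  utils::write.csv(study$plasma, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(study$lesions, paths[2], row.names = FALSE, quote = FALSE)
  truth <- study$truth
  truth$config <- unclass(truth$config)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), paths[3])
  invisible(paths)
}

#' Physical decay factor of zirconium-89
#'
#' All SUVs in this package are decay-corrected to injection time. For the
#' optional raw-counts view (e.g. when emulating uncorrected scanner output)
#' multiply by this factor. The 89Zr half-life is 78.4 h (about 3.3 days).
#'
#' @param t_h hours post-injection.
#' @param half_life_h half-life in hours.
#' @return fraction of activity remaining at `t_h`.
#' @export
zr89_decay_factor <- function(t_h, half_life_h = 78.41) {
  exp(-log(2) * t_h / half_life_h)
}
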