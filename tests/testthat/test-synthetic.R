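test_that("true_slope follows the saturation model and its limits", {
  expect_equal(true_slope(0, B0 = 0.005, id50 = 2, rnsp = 30), 0.005)
  # at dose = ID50 with 30% nonspecific floor: (0.5 * 70 + 30) / 100
  expect_equal(true_slope(2, B0 = 0.01, id50 = 2, rnsp = 30), 0.65 * 0.01)
  # high-dose asymptote is the nonspecific fraction
  expect_equal(true_slope(1e9, B0 = 0.01, id50 = 2, rnsp = 30),
               0.30 * 0.01, tolerance = 1e-6)
  expect_error(true_slope(1, B0 = 0.01, id50 = 0, rnsp = 30), "id50")
  expect_error(true_slope(-1, B0 = 0.01, id50 = 2, rnsp = 30), "dose")
})

test_that("true_slope is strictly decreasing in dose unless rnsp = 100", {
  doses <- c(0, 0.1, 0.5, 1, 2, 5, 10, 30, 100)
  for (rnsp in c(0, 30, 70)) {
    v <- true_slope(doses, B0 = 0.004, id50 = 2, rnsp = rnsp)
    expect_true(all(diff(v) < 0), info = paste("rnsp =", rnsp))
  }
  v100 <- true_slope(doses, B0 = 0.004, id50 = 2, rnsp = 100)
  expect_true(all(v100 == 0.004))
})

test_that("simulated plasma clears more slowly at higher mass dose", {
  cfg <- study_config()
  lo <- simulate_plasma(cfg, dose = 0)
  hi <- simulate_plasma(cfg, dose = 30)
  t120 <- which(lo$times == 120)
  expect_gte(hi$cp[t120], lo$cp[t120])
  expect_true(all(lo$cp > 0) && all(hi$cp > 0))
  # switching the saturable component off removes all dose dependence
  cfg0 <- study_config(pk_params = list(c0_suv = 20, frac_fast = 0.35,
                                        lambda_fast = 0.08,
                                        lambda_slow = 0.005,
                                        lambda_tmdd = 0))
  expect_identical(simulate_plasma(cfg0, 0)$cp,
                   simulate_plasma(cfg0, 30)$cp)
  expect_error(simulate_plasma(study_config(body_weight_kg = 75), -1),
               "dose")
  expect_error(study_config(body_weight_kg = 0), "body weight")
})

test_that("simulated plasma matches the closed-form biexponential AUC", {
  cfg <- study_config(plasma_sample_times = c(0.5, 1, 2, 3, 6, 9, 12, 18,
                                              24, 36, 48, 72, 96, 120))
  for (dose in c(0, 1, 30)) {
    p <- cfg$pk_params
    total <- dose + cfg$tracer_mass_mg / cfg$body_weight_kg[1]
    lam2 <- p$lambda_slow + p$lambda_tmdd *
      cfg$engagement_params$id50 / (total + cfg$engagement_params$id50)
    c1 <- p$c0_suv * p$frac_fast
    c2 <- p$c0_suv * (1 - p$frac_fast)
    # closed-form AUC of the biexponential on [0, 120]
    auc_cf <- c1 / p$lambda_fast * (1 - exp(-p$lambda_fast * 120)) +
      c2 / lam2 * (1 - exp(-lam2 * 120))
    curve <- simulate_plasma(cfg, dose)
    expect_equal(cumulative_auc(curve, 120), auc_cf, tolerance = 0.005)
    # and the AUC(inf) identity holds for the closed form itself
    expect_equal(c1 / p$lambda_fast + c2 / lam2,
                 quad_trapz(biexp_fun(p$c0_suv, p$frac_fast,
                                      p$lambda_fast, lam2), 3000),
                 tolerance = 0.005)
  }
})

test_that("lesion forward model reduces correctly in degenerate cases", {
  fn <- biexp_fun()
  curve <- sampled_curve(fn, sched)
  # purely reversible: SUV / Cp is constant = A
  tac <- simulate_lesion_tac(curve, A = 1.4, B = 0, scan_times = c(24, 48, 120))
  cp <- interpolate_cp(curve, c(24, 48, 120))
  expect_equal(tac$suv / cp, rep(1.4, 3))
  # constant input, no reversible term: linear accumulation B * c * t
  const <- plasma_curve(c(0, 200), c(5, 5))
  tac2 <- simulate_lesion_tac(const, A = 0, B = 0.01, scan_times = c(10, 50, 120))
  expect_equal(tac2$suv, 0.01 * 5 * c(10, 50, 120))
  expect_error(simulate_lesion_tac(curve, 1, 0.001, scan_times = c(48, 200)),
               "support")
})

test_that("lesion signal matches an independent quadrature of the forward model", {
  fn <- biexp_fun(l2 = 0.012)
  curve <- sampled_curve(fn, sched)
  tac <- simulate_lesion_tac(curve, A = 1, B = 0.002, scan_times = 120)
  oracle <- 1 * interpolate_cp(curve, 120) +
    0.002 * quad_loglinear(curve$times, curve$cp, 120)
  expect_equal(tac$suv, oracle, tolerance = 0.001)
})

test_that("generated studies have the documented structure and exact truth", {
  cfg <- study_config(noise_cv = 0, seed = 11)
  st <- generate_study(cfg)
  # two administrations per patient, each with its own plasma curve
  adm <- unique(st$plasma[, c("patient_id", "administration")])
  expect_equal(nrow(adm), 2 * cfg$n_patients)
  # every lesion TAC references an existing plasma curve
  les_keys <- unique(st$lesions[, c("patient_id", "administration")])
  expect_true(all(interaction(les_keys) %in% interaction(adm)))
  # truth slopes satisfy the saturation model exactly
  tr <- st$truth$lesions
  ep <- cfg$engagement_params
  expect_equal(tr$B_second,
               true_slope(tr$dose_second_mg_kg, 1, ep$id50, ep$rnsp) * tr$B0)
  # plasma AUC nondecreasing, SUVs positive
  p1 <- st$plasma[st$plasma$patient_id == "p1" &
                  st$plasma$administration == "first", ]
  curve <- plasma_curve(p1$time_h, p1$suv)
  expect_true(all(diff(cumulative_auc(curve, c(1, 6, 24, 48, 120))) > 0))
  expect_true(all(st$lesions$suv_peak > 0))
})

test_that("same seed reproduces byte-identical study files", {
  cfg <- study_config(seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(generate_study(cfg), d1)
  write_study(generate_study(cfg), d2)
  for (f in c("plasma.csv", "lesions.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("noise-free pipeline recovers every lesion's slope within 1%", {
  cfg <- study_config(noise_cv = 0, seed = 3)
  st <- generate_study(cfg)
  fits <- patlak_study(st$plasma, st$lesions)
  tr <- st$truth$lesions
  for (adm in c("first", "second")) {
    f <- fits[fits$administration == adm, ]
    m <- merge(f, tr, by = c("patient_id", "lesion_id"))
    truth <- if (adm == "first") m$B_first else m$B_second
    expect_true(all(abs(m$B_per_h / truth - 1) < 0.01), info = adm)
  }
})
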