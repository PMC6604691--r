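test_that("suv_from_activity normalizes by injected activity per gram", {
  # 37 MBq in 74 kg -> 0.5 kBq/g; 1.0 kBq/mL is twice that
  expect_equal(suv_from_activity(1.0, 37, 74), 2.0)
  expect_equal(suv_from_activity(0, 37, 74), 0)
  # uniform-phantom identity: conc = injected activity / body mass
  for (act in c(10, 37, 370)) for (bw in c(50, 75, 100)) {
    expect_equal(suv_from_activity(act * 1000 / (bw * 1000), act, bw), 1)
  }
  expect_error(suv_from_activity(1, 0, 74), "injected_activity")
  expect_error(suv_from_activity(1, 37, -1), "body_weight")
})

test_that("suv_mean matches brute-force summation on random volumes", {
  set.seed(5)
  vals <- array(runif(10^3, 0, 20), dim = c(10, 10, 10))
  vol <- image_volume(vals, voxel_size_mm = 4)
  memb <- array(runif(10^3) < 0.3, dim = c(10, 10, 10))
  memb[1, 1, 1] <- TRUE
  mask <- voi_mask(memb, "random")
  # independent oracle: explicit loop over voxels
  acc <- 0; n <- 0
  for (i in 1:10) for (j in 1:10) for (k in 1:10) if (memb[i, j, k]) {
    acc <- acc + vals[i, j, k]; n <- n + 1
  }
  expect_equal(suv_mean(vol, mask), acc / n)
  expect_equal(suv_mean(image_volume(array(7, c(3, 3, 3))),
                        voi_mask(array(TRUE, c(3, 3, 3)))), 7)
  expect_error(voi_mask(array(FALSE, c(2, 2, 2))), "no voxels")
})

test_that("suv_peak is a sphere-mean maximum bounded by suv_max", {
  # uniform volume: peak equals the value
  vol <- image_volume(array(3.5, c(8, 8, 8)), voxel_size_mm = 4)
  mask <- voi_mask(array(TRUE, c(8, 8, 8)))
  expect_equal(as.numeric(suv_peak(vol, mask)), 3.5)
  # single hot voxel is averaged down: peak strictly below max
  set.seed(8)
  vals <- array(1, c(9, 9, 9)); vals[5, 5, 5] <- 50
  vol2 <- image_volume(vals, voxel_size_mm = 4)
  mask2 <- voi_mask(array(TRUE, c(9, 9, 9)))
  pk <- suv_peak(vol2, mask2)
  expect_lt(as.numeric(pk), suv_max(vol2, mask2))
  expect_gt(as.numeric(pk), 1)
})

test_that("suv_peak equals an exhaustive brute-force placement search", {
  set.seed(21)
  d <- c(6, 6, 6); vs <- 5
  vals <- array(runif(prod(d), 0, 10), d)
  vol <- image_volume(vals, voxel_size_mm = vs)
  memb <- array(FALSE, d); memb[2:5, 2:5, 2:5] <- TRUE
  mask <- voi_mask(memb)
  sphere_ml <- 1.0
  r <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  # oracle: explicit loops over every masked center and every voxel
  best <- -Inf
  for (ci in 1:d[1]) for (cj in 1:d[2]) for (ck in 1:d[3]) {
    if (!memb[ci, cj, ck]) next
    acc <- 0; n <- 0
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (((i - ci)^2 + (j - cj)^2 + (k - ck)^2) * vs^2 <= r^2) {
        acc <- acc + vals[i, j, k]; n <- n + 1
      }
    }
    if (n > 0 && acc / n > best) best <- acc / n
  }
  expect_equal(as.numeric(suv_peak(vol, mask, sphere_ml)), best)
})

test_that("suv_peak falls back to mask mean for sub-sphere lesions", {
  vals <- array(2, c(6, 6, 6)); vals[3, 3, 3] <- 9
  vol <- image_volume(vals, voxel_size_mm = 4)   # 0.064 mL per voxel
  memb <- array(FALSE, c(6, 6, 6)); memb[3, 3, 3] <- TRUE
  mask <- voi_mask(memb)
  expect_warning(pk <- suv_peak(vol, mask, sphere_volume_ml = 1), "smaller")
  expect_true(attr(pk, "fallback"))
  expect_equal(as.numeric(pk), 9)
})

test_that("lesion size filter is inclusive at the threshold", {
  rec <- data.frame(lesion_id = c("a", "b", "c"),
                    diameter_cm = c(1.5, 2.0, 3.2))
  kept <- filter_lesions(rec)
  expect_equal(kept$lesion_id, c("b", "c"))
  expect_equal(nrow(filter_lesions(rec[0, ])), 0)
  all_big <- data.frame(lesion_id = c("x", "y"), diameter_cm = c(2, 5))
  expect_identical(filter_lesions(all_big), all_big)
})

test_that("hscore is the intensity-weighted sum, validated and bounded", {
  expect_equal(hscore(0, 0, 100), 300)
  expect_equal(hscore(0, 0, 0), 0)
  expect_equal(hscore(20, 30, 10), 110)
  # linearity in each argument
  expect_equal(hscore(10, 0, 0) + hscore(0, 10, 0) + hscore(0, 0, 10),
               hscore(10, 10, 10))
  set.seed(2)
  for (i in 1:20) {
    p <- diff(c(0, sort(runif(3, 0, 100)))) # random valid composition
    h <- hscore(p[1], p[2], p[3])
    expect_gte(h, 0); expect_lte(h, 300)
  }
  expect_error(hscore(60, 30, 30), "sum")
  expect_error(hscore(-1, 0, 0), "0, 100")
  expect_error(hscore(0, 101, 0), "0, 100")
})

test_that("SUVpeak table summary reproduces the fixture ranges", {
  tab <- read_lesion_table(lesion_table_fixture())
  s1 <- suv_table_summary(tab, "first")
  expect_equal(s1$min, 1.3)   # 1.26 rounds half-up to 1.3
  expect_equal(s1$max, 15.7)  # 15.66 rounds half-up to 15.7
  s2 <- suv_table_summary(tab, "second")
  expect_equal(s2$min, 1.6)
  expect_equal(s2$max, 11.2)
  # BLQ/NA rows are excluded from the count
  expect_equal(s1$n, sum(is.finite(tab$suv_peak) & tab$administration == "first"))
  one <- data.frame(administration = "first", suv_peak = 4.26)
  expect_equal(suv_table_summary(one, "first"),
               list(min = 4.3, max = 4.3, n = 1L))
  none <- data.frame(administration = "first", suv_peak = NA_real_)
  expect_error(suv_table_summary(none, "first"), "no quantifiable")
})

test_that("round_half_up breaks ties upward at the printed precision", {
  expect_equal(round_half_up(15.66), 15.7)
  expect_equal(round_half_up(1.57), 1.6)
  expect_equal(round_half_up(2.25), 2.3)  # base round() would give 2.2
  expect_equal(round_half_up(-2.25), -2.3)
})
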