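ts <- function(s) as.POSIXct("2026-01-05 09:00:00", tz = "UTC") + s

test_that("UR is the per-area concentration ratio", {
  expect_equal(compute_ur(400, 20, 10, 10), 20)
  # equal concentrations give UR = 1
  expect_equal(compute_ur(50, 5, 100, 10), 1)
  expect_error(compute_ur(10, 1, 0, 1), "undefined")
  expect_error(compute_ur(10, 0, 5, 1), "areas")
})

test_that("CUR rescales UR by the area ratio to the standard size", {
  expect_equal(compute_cur(4.0, 22.06, s_t1 = 22.06), 4.0)
  expect_equal(compute_cur(4.0, 11.03, s_t1 = 22.06), 2.0)
  expect_error(compute_cur(4.0, -1), "area")
  # identity: CUR / UR = S_T / S_T1 for arbitrary inputs
  set.seed(1)
  ur <- runif(50, 0.5, 20); st <- runif(50, 5, 45)
  expect_equal(compute_cur(ur, st) / ur, st / DEFAULT_S_T1)
})

test_that("decay correction follows the half-life law and inverts", {
  expect_equal(decay_correct(100, ts(0), ts(0)), 100)
  expect_equal(decay_correct(100, ts(0), ts(TC99M_HALF_LIFE_H * 3600)), 50)
  expect_equal(decay_correct(100, ts(0), ts(20 * 60)), 96.23, tolerance = 1e-4)
  # round trip, including back-correction
  a <- decay_correct(37, ts(0), ts(500))
  expect_equal(decay_correct(a, ts(500), ts(0)), 37)
})

test_that("injected counts combine assays, decay, leakage and calibration", {
  rec <- injection_record(syringe_assay(100, ts(0)), syringe_assay(10, ts(0)),
                          injection_time = ts(0))
  calib <- calibration_factor(1000)
  expect_equal(compute_injected_counts(rec, calib, ts(0), 300), 2.7e7)
  # leakage equal to the entire net dose -> 0 counts
  leak_img <- planar_image(matrix(c(90000L, 0L, 0L, 0L), 2, 2),
                           pixel_spacing = 1, acquisition_duration = 1,
                           acquisition_start = ts(0))
  leak_roi <- roi_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  rec2 <- injection_record(syringe_assay(100, ts(0)), syringe_assay(10, ts(0)),
                           ts(0), leak_img, leak_roi)
  expect_equal(compute_injected_counts(rec2, calib, ts(0), 300), 0)
  expect_error(injection_record(syringe_assay(10, ts(0)),
                                syringe_assay(100, ts(0)), ts(0)),
               "below")
})

test_that("injected counts round-trip through a phantom record within 1%", {
  sp <- small_spec(seed = 21L)
  ph <- generate_phantom(sp)
  n_inj <- compute_injected_counts(ph$truth$record, ph$truth$calib,
                                   ph$image$acquisition_start,
                                   ph$image$acquisition_duration)
  expect_equal(n_inj, ph$truth$expected_injected_counts, tolerance = 1e-10)
  # and the whole-image counts (gland + background) agree with the
  # forward model at Poisson precision
  total <- sum(ph$image$counts)
  expected <- ph$truth$expected_thyroid_counts +
    (sp$background_concentration * sp$pixel_spacing^2) *
    (sp$matrix_size^2 - roi_pixel_count(ph$truth$thyroid_mask))
  expect_lt(abs(total - expected) / expected, 0.01)
})

test_that("TcTU inverts the noiseless forward model to machine precision", {
  for (tctu in c(0.5, 2.17, 8, 45)) {
    ph <- generate_phantom(small_spec(true_tctu = tctu), noise = FALSE)
    est <- compute_tctu(ph$image, ph$truth$thyroid_mask,
                        ph$truth$background_mask,
                        ph$truth$record, ph$truth$calib)
    expect_equal(as.numeric(est), tctu, tolerance = 1e-12)
    expect_false(attr(est, "clipped"))
  }
})

test_that("a background-only phantom yields TcTU near 0", {
  ph <- generate_phantom(small_spec(true_tctu = 0, seed = 8L))
  est <- compute_tctu(ph$image, ph$truth$thyroid_mask,
                      ph$truth$background_mask,
                      ph$truth$record, ph$truth$calib)
  expect_lt(abs(as.numeric(est)), 0.05)
})

test_that("UR converges to k + 1 when the gland is k times background", {
  # gland concentration k x background, on the noiseless image: the
  # gland pixels carry gland + background activity
  sp <- small_spec(background_concentration = 1000)
  ph0 <- generate_phantom(sp, noise = FALSE)
  n_thy <- roi_pixel_count(ph0$truth$thyroid_mask)
  pix <- sp$pixel_spacing^2
  k <- 3
  # choose true_tctu so gland concentration is exactly k x background
  gland_counts <- k * sp$background_concentration * pix * n_thy
  sp$true_tctu <- 100 * gland_counts / phantom_injected_counts(sp)
  ph <- generate_phantom(sp, noise = FALSE)
  m <- quantify_study(ph$image, ph$truth$thyroid_mask,
                      ph$truth$background_mask)
  expect_equal(m$UR, k + 1, tolerance = 1e-12)
})

test_that("ratios are invariant under uniform count rescaling", {
  ph <- generate_phantom(small_spec(seed = 13L))
  img <- ph$image
  scaled <- planar_image(img$counts * 7L, img$pixel_spacing,
                         img$acquisition_duration, img$acquisition_start)
  m1 <- quantify_study(img, ph$truth$thyroid_mask, ph$truth$background_mask)
  m2 <- quantify_study(scaled, ph$truth$thyroid_mask,
                       ph$truth$background_mask)
  expect_equal(m1$UR, m2$UR)
  expect_equal(m1$CUR, m2$CUR)
})

test_that("TcTU parameter recovery: replicate mean within 3 SE of truth", {
  n_rep <- 200
  est <- vapply(seq_len(n_rep), function(i) {
    ph <- generate_phantom(small_spec(true_tctu = 2.17, seed = 5000L + i))
    as.numeric(compute_tctu(ph$image, ph$truth$thyroid_mask,
                            ph$truth$background_mask,
                            ph$truth$record, ph$truth$calib))
  }, numeric(1))
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 2.17), 3 * se)
})
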