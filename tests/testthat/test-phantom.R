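test_that("a phantom with no activity anywhere is an all-zero image", {
  sp <- small_spec(true_tctu = 0, background_concentration = 0)
  ph <- generate_phantom(sp)
  expect_true(all(ph$image$counts == 0))
})

test_that("phantom generation is bit-identical under a fixed seed", {
  sp <- small_spec(gland_area = 22.06, seed = 42L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$counts, b$image$counts)
  expect_identical(a$truth$thyroid_mask$idx, b$truth$thyroid_mask$idx)
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_phantom(sp)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("expected pixel means over the gland conserve the spec-implied counts", {
  sp <- small_spec()
  ph <- generate_phantom(sp, noise = FALSE)
  tr <- ph$truth
  n_inj <- phantom_injected_counts(sp)
  gland <- sp$true_tctu / 100 * n_inj
  pixarea <- sp$pixel_spacing^2
  # analytic conservation: gland share + background under the mask
  expect_equal(tr$expected_thyroid_counts,
               gland + sp$background_concentration * pixarea *
                 roi_pixel_count(tr$thyroid_mask))
  # the noiseless image integrates to the expectation over each mask
  expect_equal(roi_counts(ph$image, tr$thyroid_mask)$C,
               tr$expected_thyroid_counts)
  expect_equal(roi_counts(ph$image, tr$background_mask)$C,
               tr$expected_background_counts)
  # masks disjoint
  expect_false(roi_overlaps(tr$thyroid_mask, tr$background_mask))
})

test_that("doubling the gland area preserves gland counts and halves concentration", {
  base <- generate_phantom(small_spec(background_concentration = 0),
                           noise = FALSE)
  dbl <- generate_phantom(small_spec(gland_area = 2 * 22.06,
                                     background_concentration = 0),
                          noise = FALSE)
  c1 <- roi_counts(base$image, base$truth$thyroid_mask)
  c2 <- roi_counts(dbl$image, dbl$truth$thyroid_mask)
  expect_equal(c1$C, c2$C)
  # concentration halves, up to rasterization of the doubled outline
  expect_equal(c2$C / c2$S, (c1$C / c1$S) / 2, tolerance = 0.02)
})

test_that("Poisson relative error at >= 1e6 expected gland counts is under 1%", {
  sp <- small_spec(true_tctu = 30, seed = 11L)  # ~1.15e6 gland counts
  ph <- generate_phantom(sp)
  expect_gt(sp$true_tctu / 100 * phantom_injected_counts(sp), 1e6)
  meas <- roi_counts(ph$image, ph$truth$thyroid_mask)$C
  expect_lt(abs(meas - ph$truth$expected_thyroid_counts) /
              ph$truth$expected_thyroid_counts, 0.01)
})

test_that("a gland too large for the matrix raises a geometry error", {
  expect_error(generate_phantom(small_spec(gland_area = 400)), "fit")
})

test_that("cohort sampling recovers configured group parameters", {
  design <- cohort_group("control", 1000, 2.17, 0.20, 22.06, 2.82)
  truth <- sample_cohort_truth(design, seed = 5L)
  expect_equal(nrow(truth), 1000)
  se <- 2.82 / sqrt(1000)
  expect_lt(abs(mean(truth$gland_area) - 22.06), 3 * se)
  expect_true(all(truth$gland_area > 0))
  expect_true(all(truth$true_tctu <= 100))
  # per-subject seeds are distinct and inside integer range
  expect_false(anyDuplicated(truth$seed) > 0)
  # fixed seed => bit-identical cohort
  expect_identical(truth, sample_cohort_truth(design, seed = 5L))
})

test_that("empty or invalid cohort groups are rejected", {
  expect_error(cohort_group("x", 0, 2, 0.2, 20, 2), "n >= 1")
  expect_error(cohort_group("x", 5, -1, 0.2, 20, 2), "uptake")
  expect_error(cohort_group("x", 5, 2, 0.2, 20, -1), "area")
})

test_that("with all areas at the standard size, CUR equals UR subject by subject", {
  design <- cohort_group("control", 8, 2.17, 0.3, 22.06, 0)
  truth <- sample_cohort_truth(design, seed = 3L)
  m <- quantify_cohort(truth, small_spec(), s_t1 = DEFAULT_S_T1)
  # rasterization fixes one common S_T; standardize to that exact area
  s_t <- unique(m$S_T)
  expect_length(s_t, 1)
  cur <- compute_cur(m$UR, m$S_T, s_t1 = s_t)
  expect_equal(cur, m$UR)
})

test_that("cohort truth table serializes as CSV", {
  truth <- sample_cohort_truth(cohort_group("g", 3, 2, 0.2, 20, 2), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_truth(truth, path)
  back <- read.csv(path)
  expect_equal(back$true_tctu, truth$true_tctu)
  expect_equal(back$group, truth$group)
})
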