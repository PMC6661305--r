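#' @title Synthetic planar thyroid phantoms
#' @description
#' Digital phantoms emulating a pertechnetate thyroid study: a
#' two-lobed elliptical gland with uniform tracer concentration over a
#' uniform neck background, imaged by an ideal planar camera whose
#' pixels register independent Poisson counts. The phantom is built
#' from the same forward model the quantification inverts — a known
#' injected activity, camera sensitivity and uptake fraction — so the
#' ground-truth TcTU, UR and CUR are available exactly and every
#' downstream stage can be tested for parameter recovery without any
#' patient data. Scatter, attenuation, collimator blur and patient
#' motion are deliberately not modelled.
#' @name phantom
NULL

#' Phantom specification
#'
#' @param gland_area total functional gland area in cm^2 (both lobes).
#' @param true_tctu ground-truth uptake: percent of the injected
#'   activity in the gland at imaging time, in `[0, 100]`.
#' @param background_concentration expected background counts per cm^2
#'   over the acquisition.
#' @param injected_activity net injected activity in MBq at injection
#'   time.
#' @param sensitivity camera calibration factor ground truth, in
#'   counts s^-1 MBq^-1.
#' @param acquisition_duration thyroid acquisition time in seconds.
#' @param uptake_time seconds between injection and acquisition start.
#' @param pixel_spacing cm per pixel (isotropic).
#' @param matrix_size pixels per axis (square matrix).
#' @param lobe_aspect height/width ratio of each elliptical lobe.
#' @param lobe_gap gap between the lobes' inner edges in cm.
#' @param isthmus_height height (cm) of an optional connecting isthmus
#'   band between the lobes; 0 disables it.
#' @param seed integer RNG seed for the Poisson draw.
#'
#' @details The defaults describe a typical adult study: 148 MBq
#' injected, imaging for 300 s starting 20 min post injection on a
#' 256x256 matrix, a control-mean gland (22.06 cm^2, TcTU 2.17%) and a
#' background level that puts the control uptake ratio near its
#' control-group value.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(gland_area = 22.06,
                         true_tctu = 2.17,
                         background_concentration = 1170,
                         injected_activity = 148,
                         sensitivity = 90,
                         acquisition_duration = 300,
                         uptake_time = 1200,
                         pixel_spacing = 0.075,
                         matrix_size = 256,
                         lobe_aspect = 1.8,
                         lobe_gap = 0.6,
                         isthmus_height = 0,
                         seed = 1L) {
  spec <- list(gland_area = gland_area, true_tctu = true_tctu,
               background_concentration = background_concentration,
               injected_activity = injected_activity,
               sensitivity = sensitivity,
               acquisition_duration = acquisition_duration,
               uptake_time = uptake_time,
               pixel_spacing = pixel_spacing,
               matrix_size = as.integer(matrix_size),
               lobe_aspect = lobe_aspect, lobe_gap = lobe_gap,
               isthmus_height = isthmus_height,
               seed = as.integer(seed))
  with(spec, {
    if (gland_area <= 0) stop("gland_area must be > 0")
    if (true_tctu < 0 || true_tctu > 100) stop("true_tctu must be in [0, 100]")
    if (background_concentration < 0) stop("background_concentration must be >= 0")
    if (injected_activity <= 0 || sensitivity <= 0 ||
        acquisition_duration <= 0 || uptake_time < 0 ||
        pixel_spacing <= 0 || matrix_size < 8) {
      stop("rates, durations and geometry must be positive")
    }
    if (lobe_aspect <= 0 || lobe_gap < 0 || isthmus_height < 0) {
      stop("invalid lobe geometry")
    }
  })
  structure(spec, class = "phantom_spec")
}

# Rasterized gland and background-strip masks for a phantom geometry.
# Pixel (i, j) centre at ((j - 0.5) * h, (i - 0.5) * h) cm (1-based here).
# Returns roi_mask pair; errors if the geometry does not fit the matrix.
.phantom_masks <- function(spec) {
  h <- spec$pixel_spacing
  n <- spec$matrix_size
  fov <- n * h
  lobe_area <- spec$gland_area / 2
  a <- sqrt(lobe_area / (pi * spec$lobe_aspect))   # semi-width, cm
  b <- a * spec$lobe_aspect                        # semi-height, cm
  dx <- a + spec$lobe_gap / 2                      # lobe centre offset
  cx <- fov / 2
  cy <- 0.35 * fov
  strip_gap <- 0.8
  strip_h <- 1.5
  y_strip0 <- cy + b + strip_gap
  y_strip1 <- y_strip0 + strip_h
  if (cx - dx - a < h || cx + dx + a > fov - h ||
      cy - b < h || y_strip1 > fov - h) {
    stop("gland and background strip do not fit in the image matrix")
  }
  xc <- (seq_len(n) - 0.5) * h
  yc <- (seq_len(n) - 0.5) * h
  X <- matrix(xc, n, n, byrow = TRUE)
  Y <- matrix(yc, n, n)
  in_lobe <- function(x0) ((X - x0) / a)^2 + ((Y - cy) / b)^2 <= 1
  gland <- in_lobe(cx - dx) | in_lobe(cx + dx)
  if (spec$isthmus_height > 0) {
    gland <- gland | (abs(X - cx) <= dx &
                        abs(Y - cy) <= spec$isthmus_height / 2)
  }
  strip <- X >= cx - dx - a & X <= cx + dx + a &
    Y >= y_strip0 & Y <= y_strip1
  list(thyroid = roi_mask(gland), background = roi_mask(strip))
}

#' Expected (net injected) counts implied by a phantom spec
#'
#' The number of counts the camera registers from the full injected
#' activity over the acquisition: the activity decayed over the uptake
#' interval times sensitivity times duration. The gland receives
#' `true_tctu`% of this.
#'
#' @param spec a [phantom_spec()].
#' @param half_life_h isotope half-life in hours.
#' @return expected injected counts (numeric scalar).
#' @export
phantom_injected_counts <- function(spec, half_life_h = TC99M_HALF_LIFE_H) {
  stopifnot(inherits(spec, "phantom_spec"))
  a_img <- spec$injected_activity * 2^(-spec$uptake_time / (half_life_h * 3600))
  a_img * spec$sensitivity * spec$acquisition_duration
}

#' Generate one synthetic planar thyroid study
#'
#' Builds the gland and background-strip masks, computes the expected
#' per-pixel count means — a uniform gland concentration (the gland's
#' share of the injected counts spread over its rasterized area) added
#' on top of a uniform background concentration everywhere — and draws
#' independent Poisson counts per pixel. Areas downstream are computed
#' from the rasterized mask, so the mask area and the `S_T` entering UR
#' and CUR agree exactly and the noiseless phantom inverts to
#' `true_tctu` without rasterization bias.
#'
#' @param spec a [phantom_spec()].
#' @param noise draw Poisson counts (default); `FALSE` returns the
#'   noiseless expectation image (fractional counts).
#' @param half_life_h isotope half-life in hours.
#' @return a list with `image` (a [planar_image()]) and `truth`, a
#'   `phantom_truth` list carrying the spec, both [roi_mask()]s, the
#'   expected thyroid/background ROI counts, the rasterized `S_T` and
#'   `S_B`, the expected injected counts, and a ready-made
#'   [injection_record()] + [calibration_factor()] for quantification.
#' @export
generate_phantom <- function(spec, noise = TRUE,
                             half_life_h = TC99M_HALF_LIFE_H) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- .phantom_masks(spec)
  n <- spec$matrix_size
  pix_area <- spec$pixel_spacing^2
  n_inj <- phantom_injected_counts(spec, half_life_h)
  gland_counts <- spec$true_tctu / 100 * n_inj
  n_thy <- length(masks$thyroid$idx)
  mu <- matrix(spec$background_concentration * pix_area, n, n)
  mu[masks$thyroid$idx] <- mu[masks$thyroid$idx] + gland_counts / n_thy
  t0 <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")
  t_img <- t0 + spec$uptake_time
  if (noise) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    counts <- matrix(stats::rpois(n * n, mu), n, n)
  } else {
    counts <- mu
  }
  image <- planar_image(counts, pixel_spacing = spec$pixel_spacing,
                        acquisition_duration = spec$acquisition_duration,
                        acquisition_start = t_img,
                        check_integer = noise)
  record <- injection_record(
    pre = syringe_assay(spec$injected_activity, t0),
    post = syringe_assay(0, t0),
    injection_time = t0
  )
  truth <- structure(list(
    spec = spec,
    thyroid_mask = masks$thyroid,
    background_mask = masks$background,
    expected_thyroid_counts = sum(mu[masks$thyroid$idx]),
    expected_background_counts = sum(mu[masks$background$idx]),
    expected_gland_counts = gland_counts,
    expected_injected_counts = n_inj,
    S_T = n_thy * pix_area,
    S_B = length(masks$background$idx) * pix_area,
    record = record,
    calib = calibration_factor(spec$sensitivity)
  ), class = "phantom_truth")
  list(image = image, truth = truth)
}

# save/restore the global RNG state so phantom generation is reproducible
# from its own seed without disturbing the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- cohort emulation -----------------------------------------------------

#' Cohort group specification table
#'
#' One row per clinical group: group name, size, log-normal parameters
#' for the true uptake fraction and truncated-normal parameters for the
#' functional gland area.
#'
#' @param name group label.
#' @param n subjects in the group.
#' @param tctu_median,tctu_sdlog median (percent) and log-scale SD of
#'   the log-normal true-TcTU distribution.
#' @param area_mean,area_sd mean and SD (cm^2) of the normal gland-area
#'   distribution, truncated at > 0 by resampling.
#' @return a one-row data frame; rbind rows to build a cohort design.
#' @export
cohort_group <- function(name, n, tctu_median, tctu_sdlog,
                         area_mean, area_sd) {
  if (n < 1) stop("each group needs n >= 1 subjects")
  if (tctu_median <= 0 || tctu_sdlog < 0) stop("invalid uptake distribution")
  if (area_mean <= 0 || area_sd < 0) stop("invalid area distribution")
  data.frame(name = name, n = as.integer(n),
             tctu_median = tctu_median, tctu_sdlog = tctu_sdlog,
             area_mean = area_mean, area_sd = area_sd,
             stringsAsFactors = FALSE)
}

#' Default cohort design emulating a mixed thyroid-clinic population
#'
#' A control group (TcTU median 2.17%, area 22.06 +/- 2.82 cm^2) plus
#' disease groups spanning hyperthyroid, hypothyroid/destructive and
#' postoperative-remnant presentations, sized and parameterized so that
#' the cohort covers small, normal and large functional gland areas and
#' both decreased and increased uptake. Group uptake medians and
#' dispersions are modeling choices (see the methods vignette).
#'
#' @return a data frame of [cohort_group()] rows.
#' @export
default_cohort_design <- function() {
  rbind(
    cohort_group("control",                 67, 2.17, 0.20, 22.06, 2.82),
    cohort_group("hyperthyroidism",         79, 13.4, 0.45, 33.0,  7.0),
    cohort_group("simple_goiter",           40, 3.04, 0.35, 33.0,  6.0),
    cohort_group("subacute_thyroiditis",    28, 0.25, 0.40, 22.0,  4.0),
    cohort_group("hypothyroidism",          41, 0.61, 0.60, 18.0,  5.0),
    cohort_group("postop_hyperthyroidism",  23, 1.72, 0.35, 12.0,  3.0),
    cohort_group("postop_thyroid_nodule",   44, 0.64, 0.50, 13.0,  3.0),
    cohort_group("thyroid_nodule",          48, 1.89, 0.25, 21.0,  4.0),
    cohort_group("hashimoto",               19, 4.17, 0.55, 28.0,  6.0)
  )
}

#' Sample per-subject ground truth for a synthetic cohort
#'
#' Draws each subject's true uptake (log-normal, resampled above 100%)
#' and functional gland area (normal truncated at > 0 by resampling)
#' from the group design, and assigns a per-subject phantom seed derived
#' from the cohort seed by counter.
#'
#' @param design a data frame of [cohort_group()] rows.
#' @param seed cohort RNG seed.
#' @return a data frame with one row per subject: `subject`, `group`,
#'   `true_tctu`, `gland_area`, `seed`.
#' @export
sample_cohort_truth <- function(design = default_cohort_design(), seed = 1L) {
  if (!all(c("name", "n", "tctu_median", "tctu_sdlog",
             "area_mean", "area_sd") %in% names(design))) {
    stop("design must be built from cohort_group() rows")
  }
  if (any(design$n < 1)) stop("each group needs n >= 1 subjects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rtrunc <- function(n, sample_fun, ok) {
    x <- sample_fun(n)
    while (any(bad <- !ok(x))) x[bad] <- sample_fun(sum(bad))
    x
  }
  rows <- lapply(seq_len(nrow(design)), function(g) {
    d <- design[g, ]
    tctu <- rtrunc(d$n, function(m) stats::rlnorm(m, log(d$tctu_median),
                                                  d$tctu_sdlog),
                   function(x) x <= 100)
    area <- rtrunc(d$n, function(m) stats::rnorm(m, d$area_mean, d$area_sd),
                   function(x) x > 0)
    data.frame(group = d$name, true_tctu = tctu, gland_area = area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$subject <- seq_len(nrow(out))
  # per-image seeds derived by counter, kept inside 32-bit integer range
  out$seed <- (as.integer(seed) %% 1000003L) * 2048L + out$subject
  out[, c("subject", "group", "true_tctu", "gland_area", "seed")]
}

#' Generate a full synthetic cohort of planar thyroid studies
#'
#' Samples the per-subject ground truth ([sample_cohort_truth()]) and
#' generates one Poisson phantom per subject, holding the acquisition
#' protocol (`base_spec`) fixed across subjects.
#'
#' @param design a data frame of [cohort_group()] rows.
#' @param seed cohort RNG seed; per-image seeds derive from it.
#' @param base_spec a [phantom_spec()] providing the acquisition
#'   protocol; its `gland_area`, `true_tctu` and `seed` are overridden
#'   per subject.
#' @param noise draw Poisson counts (default) or return expectation
#'   images.
#' @return a list with `truth` (the cohort ground-truth data frame) and
#'   `studies` (a list of [generate_phantom()] results, one per row).
#' @export
generate_cohort <- function(design = default_cohort_design(), seed = 1L,
                            base_spec = phantom_spec(), noise = TRUE) {
  truth <- sample_cohort_truth(design, seed)
  studies <- lapply(seq_len(nrow(truth)), function(i) {
    sp <- base_spec
    sp$gland_area <- truth$gland_area[i]
    sp$true_tctu <- truth$true_tctu[i]
    sp$seed <- truth$seed[i]
    generate_phantom(sp, noise = noise)
  })
  list(truth = truth, studies = studies)
}

#' Write a cohort ground-truth table as CSV
#' @param truth the data frame from [sample_cohort_truth()].
#' @param path output CSV path.
#' @export
write_cohort_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
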