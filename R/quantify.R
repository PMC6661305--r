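#' @title Uptake quantification: UR, CUR and TcTU
#' @description
#' The quantification layer turns ROI counts, syringe dose-calibrator
#' assays and a camera calibration factor into the three uptake
#' parameters:
#'
#' * **UR** — the thyroid-to-background uptake ratio, the per-area count
#'   concentration ratio `(C_T/S_T) / (C_B/S_B)`;
#' * **CUR** — the corrected uptake ratio, UR rescaled by the subject's
#'   functional thyroid area relative to a standardized (control-mean)
#'   thyroid area `S_T1`: `CUR = UR * S_T / S_T1`;
#' * **TcTU** — the quantitative pertechnetate thyroid uptake, the
#'   percentage of the net injected activity (decay-corrected, leakage
#'   subtracted, converted to camera counts over the acquisition)
#'   accumulated in the thyroid after background subtraction.
#' @name quantify
NULL

#' Physical half-life of Tc-99m in hours
#' @export
TC99M_HALF_LIFE_H <- 6.0067

#' Default standardized thyroid area S_T1 in cm^2 (control-group mean)
#' @export
DEFAULT_S_T1 <- 22.06

#' Syringe dose-calibrator assay
#' @param activity measured activity in MBq.
#' @param assay_time `POSIXct` timestamp of the measurement.
#' @return an object of class `syringe_assay`.
#' @export
syringe_assay <- function(activity, assay_time) {
  activity <- as.numeric(activity)
  if (!is.finite(activity) || activity < 0) stop("activity must be >= 0 MBq")
  if (!inherits(assay_time, "POSIXct")) assay_time <- as.POSIXct(assay_time, tz = "UTC")
  structure(list(activity = activity, assay_time = assay_time),
            class = "syringe_assay")
}

#' Injection record: pre/post syringe assays and optional leakage imaging
#'
#' @param pre,post [syringe_assay()] before and after the injection.
#' @param injection_time `POSIXct` injection timestamp.
#' @param leakage_image optional [planar_image()] of the injection site
#'   (acquired when extravasation is visible).
#' @param leakage_roi optional [roi_mask()] outlining the leakage on that
#'   image.
#' @return an object of class `injection_record`.
#' @export
injection_record <- function(pre, post, injection_time,
                             leakage_image = NULL, leakage_roi = NULL) {
  stopifnot(inherits(pre, "syringe_assay"), inherits(post, "syringe_assay"))
  if (!inherits(injection_time, "POSIXct")) {
    injection_time <- as.POSIXct(injection_time, tz = "UTC")
  }
  if (pre$activity < post$activity) {
    stop("pre-injection activity is below post-injection activity")
  }
  if (pre$assay_time > injection_time || injection_time > post$assay_time) {
    stop("times must be ordered pre <= injection <= post")
  }
  if (xor(is.null(leakage_image), is.null(leakage_roi))) {
    stop("leakage_image and leakage_roi must be given together")
  }
  structure(list(pre = pre, post = post, injection_time = injection_time,
                 leakage_image = leakage_image, leakage_roi = leakage_roi),
            class = "injection_record")
}

#' Camera calibration factor
#'
#' Conversion between activity measured in the dose calibrator and the
#' count rate registered by the gamma camera, in counts s^-1 MBq^-1.
#' Determined per camera following the manufacturer's calibration
#' procedure; here it is a single configurable number.
#'
#' @param value counts s^-1 MBq^-1, > 0.
#' @export
calibration_factor <- function(value) {
  value <- as.numeric(value)
  if (!is.finite(value) || value <= 0) {
    stop("calibration factor must be > 0 counts/s/MBq")
  }
  structure(list(value = value), class = "calibration_factor")
}

#' Radioactive decay correction
#'
#' Propagates an activity from one time to another with the exponential
#' decay law `A(t) = A0 * 2^(-dt / T_half)`. A negative elapsed time
#' back-corrects (i.e. yields a larger activity).
#'
#' @param activity activity in MBq (vectorized).
#' @param from_time,to_time `POSIXct` timestamps (or numbers in seconds).
#' @param half_life_h isotope half-life in hours; defaults to Tc-99m
#'   ([TC99M_HALF_LIFE_H]).
#' @return decay-corrected activity in MBq.
#' @examples
#' decay_correct(100, 0, 20 * 60)  # 20 min of Tc-99m decay -> 96.23 MBq
#' @export
decay_correct <- function(activity, from_time, to_time,
                          half_life_h = TC99M_HALF_LIFE_H) {
  dt_s <- as.numeric(difftime(to_time, from_time, units = "secs"))
  activity * 2^(-dt_s / (half_life_h * 3600))
}

#' Net injected activity expressed as camera counts
#'
#' Computes the activity actually delivered to the circulation —
#' `pre - post` syringe assays, each decay-corrected to a common
#' reference time, minus any extravasated activity estimated from the
#' leakage image (leakage count rate divided by the calibration factor,
#' decay-corrected from the leakage acquisition start to the reference
#' time) — and converts it to the number of counts the camera would
#' register from that activity over `duration` seconds:
#' `counts = activity * calib * duration`.
#'
#' @param record an [injection_record()].
#' @param calib a [calibration_factor()].
#' @param reference_time `POSIXct` time to which all activities are
#'   decay-corrected (normally the thyroid acquisition start).
#' @param duration acquisition duration in seconds over which the counts
#'   are accumulated (normally the thyroid acquisition duration).
#' @param half_life_h isotope half-life in hours.
#' @return net injected counts (numeric scalar, >= 0).
#' @export
compute_injected_counts <- function(record, calib, reference_time, duration,
                                    half_life_h = TC99M_HALF_LIFE_H) {
  stopifnot(inherits(record, "injection_record"),
            inherits(calib, "calibration_factor"))
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0 s")
  a_pre <- decay_correct(record$pre$activity, record$pre$assay_time,
                         reference_time, half_life_h)
  a_post <- decay_correct(record$post$activity, record$post$assay_time,
                          reference_time, half_life_h)
  net <- a_pre - a_post
  if (!is.null(record$leakage_image)) {
    lk <- roi_counts(record$leakage_image, record$leakage_roi)
    rate <- lk$C / record$leakage_image$acquisition_duration   # counts/s
    a_leak <- decay_correct(rate / calib$value,
                            record$leakage_image$acquisition_start,
                            reference_time, half_life_h)
    net <- net - a_leak
  }
  if (net < -sqrt(.Machine$double.eps) * record$pre$activity) {
    stop("negative net injected activity: check assays and leakage data")
  }
  max(net, 0) * calib$value * duration
}

#' Thyroid-to-background uptake ratio (UR)
#'
#' The per-unit-area concentration ratio between the thyroid and
#' background ROIs: `UR = (C_T / S_T) / (C_B / S_B)`.
#'
#' @param c_t,s_t thyroid ROI counts and area (cm^2).
#' @param c_b,s_b background ROI counts and area (cm^2).
#' @return UR (dimensionless).
#' @export
compute_ur <- function(c_t, s_t, c_b, s_b) {
  if (any(s_t <= 0) || any(s_b <= 0)) stop("ROI areas must be > 0")
  if (any(c_b <= 0)) stop("zero background counts: UR is undefined")
  (c_t / s_t) / (c_b / s_b)
}

#' Corrected uptake ratio (CUR)
#'
#' UR rescaled by the subject's functional thyroid area relative to the
#' standardized thyroid area `S_T1` (the control-group mean area):
#' `CUR = UR * S_T / S_T1`. Equivalently, CUR is the ratio of the
#' thyroid counts per standardized thyroid size, `C_T1 = C_T / S_T1`, to
#' the background count concentration `C_B1 = C_B / S_B`. Unlike UR, CUR
#' responds to gland size: a small remnant gland with a high local
#' concentration no longer masquerades as normal total uptake.
#'
#' @param ur uptake ratio from [compute_ur()].
#' @param s_t thyroid ROI area in cm^2.
#' @param s_t1 standardized thyroid area in cm^2 (default
#'   [DEFAULT_S_T1]).
#' @return CUR (dimensionless).
#' @export
compute_cur <- function(ur, s_t, s_t1 = DEFAULT_S_T1) {
  if (any(s_t <= 0)) stop("thyroid area must be > 0")
  if (any(s_t1 <= 0)) stop("standardized area s_t1 must be > 0")
  ur * s_t / s_t1
}

#' Quantitative pertechnetate thyroid uptake (TcTU)
#'
#' `TcTU(%) = 100 * (C_T - (C_B / S_B) * S_T) / N_inj`, where the
#' numerator is the thyroid ROI counts with the background count
#' concentration (scaled to the thyroid area) subtracted, and `N_inj`
#' is the net injected activity expressed as camera counts over the same
#' acquisition duration ([compute_injected_counts()]), decay-corrected
#' to the thyroid acquisition start. A negative background-subtracted
#' numerator is clipped to 0 and flagged via the `"clipped"` attribute.
#'
#' @param image thyroid [planar_image()].
#' @param thyroid_roi,background_roi [roi_mask()] objects on `image`;
#'   must be disjoint.
#' @param record an [injection_record()].
#' @param calib a [calibration_factor()].
#' @param half_life_h isotope half-life in hours.
#' @return TcTU in percent.
#' @export
compute_tctu <- function(image, thyroid_roi, background_roi, record, calib,
                         half_life_h = TC99M_HALF_LIFE_H) {
  if (roi_overlaps(thyroid_roi, background_roi)) {
    stop("thyroid and background ROIs overlap")
  }
  thy <- roi_counts(image, thyroid_roi)
  bkg <- roi_counts(image, background_roi)
  n_inj <- compute_injected_counts(record, calib,
                                   reference_time = image$acquisition_start,
                                   duration = image$acquisition_duration,
                                   half_life_h = half_life_h)
  if (n_inj <= 0) stop("injected counts <= 0: TcTU is undefined")
  net <- thy$C - (bkg$C / bkg$S) * thy$S
  tctu <- 100 * max(net, 0) / n_inj
  attr(tctu, "clipped") <- net < 0
  tctu
}

#' Full uptake measurement for one study
#'
#' Convenience wrapper computing every per-study quantity — ROI counts
#' and areas, the standardized count concentrations, UR, CUR and (when
#' an injection record and calibration factor are supplied) TcTU — as a
#' one-row data frame.
#'
#' @inheritParams compute_tctu
#' @param s_t1 standardized thyroid area in cm^2.
#' @return a one-row data frame with columns `C_T`, `S_T`, `C_B`, `S_B`,
#'   `C_T1` (= `C_T / S_T1`, counts per standardized thyroid size),
#'   `C_B1` (= `C_B / S_B`), `UR`, `CUR` and `TcTU` (NA when no dose
#'   record is available) plus `tctu_clipped`.
#' @export
quantify_study <- function(image, thyroid_roi, background_roi,
                           record = NULL, calib = NULL,
                           s_t1 = DEFAULT_S_T1,
                           half_life_h = TC99M_HALF_LIFE_H) {
  thy <- roi_counts(image, thyroid_roi)
  bkg <- roi_counts(image, background_roi)
  ur <- compute_ur(thy$C, thy$S, bkg$C, bkg$S)
  cur <- compute_cur(ur, thy$S, s_t1)
  tctu <- NA_real_
  clipped <- NA
  if (!is.null(record)) {
    if (is.null(calib)) stop("a calibration factor is required for TcTU")
    tctu <- compute_tctu(image, thyroid_roi, background_roi, record, calib,
                         half_life_h = half_life_h)
    clipped <- attr(tctu, "clipped")
    attributes(tctu) <- NULL
  }
  data.frame(C_T = thy$C, S_T = thy$S, C_B = bkg$C, S_B = bkg$S,
             C_T1 = thy$C / s_t1, C_B1 = bkg$C / bkg$S,
             UR = ur, CUR = cur, TcTU = tctu, tctu_clipped = clipped)
}
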