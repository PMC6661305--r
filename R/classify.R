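#' @title Reference ranges and three-class uptake labels
#' @description
#' Reference ranges are parametric 95% intervals, mean +/- 1.96 SD, fit
#' on the control group. A value below the lower limit is classed
#' `decreased`, above the upper limit `increased`, and anything in the
#' closed interval `normal`. Gland areas are stratified the same way
#' (`small` / `normal` / `large`). Concordance between a
#' semiquantitative class (from UR or CUR) and the quantitative TcTU
#' class is tabulated per area stratum, and discordant cells are typed
#' as over- or underestimation by the direction of the disagreement.
#' @name classify
NULL

.uptake_levels <- c("decreased", "normal", "increased")
.area_levels <- c("small", "normal", "large")

#' Build a reference range from explicit mean and SD
#'
#' Limits are `mean - 1.96 sd` and `mean + 1.96 sd`, rounded to
#' `rounding` decimals for reporting (the unrounded limits are kept
#' alongside; classification can use either).
#'
#' @param mean,sd distribution mean and standard deviation.
#' @param parameter optional parameter name (e.g. `"TcTU"`).
#' @param rounding decimal places for the reported limits (2 for uptake
#'   parameters, 1 for areas, by convention).
#' @return an object of class `reference_range` with `mean`, `sd`, `n`,
#'   `lower`, `upper` (rounded) and `lower_raw`, `upper_raw`.
#' @export
reference_range <- function(mean, sd, parameter = "", rounding = 2) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stop("mean must be finite and sd >= 0")
  }
  lo <- mean - 1.96 * sd
  hi <- mean + 1.96 * sd
  structure(list(parameter = parameter, mean = mean, sd = sd, n = NA_integer_,
                 rounding = rounding,
                 lower = round(lo, rounding), upper = round(hi, rounding),
                 lower_raw = lo, upper_raw = hi),
            class = "reference_range")
}

#' Fit a reference range on control-sample values
#'
#' @param values numeric vector of control measurements (n >= 2).
#' @inheritParams reference_range
#' @return a `reference_range`; see [reference_range()].
#' @export
fit_reference_range <- function(values, parameter = "", rounding = 2) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite control values")
  rr <- reference_range(base::mean(values), stats::sd(values),
                        parameter, rounding)
  rr$n <- length(values)
  rr
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("reference_range %s: mean %.4g, SD %.4g -> [%s, %s]\n",
              x$parameter, x$mean, x$sd,
              format(x$lower), format(x$upper)))
  invisible(x)
}

#' Assign three-class uptake labels against a reference range
#'
#' `decreased` below the lower limit, `increased` above the upper limit,
#' `normal` on the closed interval in between (boundary values are
#' normal).
#'
#' @param value numeric vector of parameter values.
#' @param range a [reference_range()].
#' @param use_rounded classify against the rounded reported limits (the
#'   default) or the unrounded ones.
#' @return a factor with levels `decreased < normal < increased`.
#' @export
classify_value <- function(value, range, use_rounded = TRUE) {
  stopifnot(inherits(range, "reference_range"))
  lo <- if (use_rounded) range$lower else range$lower_raw
  hi <- if (use_rounded) range$upper else range$upper_raw
  cls <- ifelse(value < lo, "decreased",
                ifelse(value > hi, "increased", "normal"))
  factor(cls, levels = .uptake_levels, ordered = TRUE)
}

#' Stratify gland areas as small / normal / large
#'
#' @param s_t thyroid areas in cm^2.
#' @param range a [reference_range()] for the control-group area
#'   (defaults to the published control area 22.06 +/- 2.82 cm^2, whose
#'   rounded limits are 16.5 and 27.6).
#' @param use_rounded classify against the rounded limits.
#' @return a factor with levels `small < normal < large`.
#' @export
area_stratum <- function(s_t,
                         range = reference_range(22.06, 2.82,
                                                 "thyroid area", rounding = 1),
                         use_rounded = TRUE) {
  cls <- classify_value(s_t, range, use_rounded)
  factor(.area_levels[as.integer(cls)], levels = .area_levels, ordered = TRUE)
}

#' Concordance between a semiquantitative class and the TcTU class
#'
#' Cross-classifies per-subject uptake classes, overall and per area
#' stratum; a subject is concordant when the two classes are equal.
#'
#' @param semi_classes factor of classes from a semiquantitative
#'   parameter (UR or CUR), levels `decreased`/`normal`/`increased`.
#' @param tctu_classes factor of quantitative TcTU classes, same levels.
#' @param strata optional factor of area strata
#'   (`small`/`normal`/`large`) for per-stratum tables.
#' @return an object of class `concordance_result`: `overall` (a list
#'   with the 3x3 `table` — TcTU class in rows, semiquantitative class
#'   in columns — plus `n`, `concordant`, `rate` in percent) and
#'   `by_stratum`, a named list of the same per stratum, plus a tidy
#'   `summary` data frame.
#' @export
concordance_table <- function(semi_classes, tctu_classes, strata = NULL) {
  semi_classes <- factor(semi_classes, levels = .uptake_levels)
  tctu_classes <- factor(tctu_classes, levels = .uptake_levels)
  if (length(semi_classes) != length(tctu_classes)) {
    stop("class vectors must have equal length")
  }
  if (anyNA(semi_classes) || anyNA(tctu_classes)) {
    stop("classes contain values outside decreased/normal/increased")
  }
  one <- function(keep) {
    tab <- table(tctu = tctu_classes[keep], semi = semi_classes[keep])
    n <- sum(tab)
    conc <- sum(diag(tab))
    list(table = tab, n = n, concordant = conc,
         rate = if (n > 0) 100 * conc / n else NA_real_)
  }
  res <- list(overall = one(rep(TRUE, length(semi_classes))))
  if (!is.null(strata)) {
    strata <- factor(strata, levels = .area_levels)
    if (length(strata) != length(semi_classes)) {
      stop("strata must match the class vectors in length")
    }
    res$by_stratum <- lapply(stats::setNames(.area_levels, .area_levels),
                             function(s) one(!is.na(strata) & strata == s))
  }
  rows <- c(res$by_stratum, list(overall = res$overall))
  res$summary <- data.frame(
    stratum = names(rows),
    n = vapply(rows, `[[`, numeric(1), "n"),
    concordant = vapply(rows, `[[`, numeric(1), "concordant"),
    rate = vapply(rows, `[[`, numeric(1), "rate"),
    row.names = NULL
  )
  structure(res, class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("concordance (semiquantitative class vs TcTU class)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Type the discordant cells of a 3x3 class cross-tab
#'
#' Each off-diagonal cell (TcTU class in rows, semiquantitative class in
#' columns) is an over- or underestimation by the semiquantitative
#' parameter: `overestimation` when the semiquantitative class is higher
#' than the TcTU class on the decreased < normal < increased ordering
#' (e.g. decreased TcTU read as normal uptake), `underestimation` when
#' it is lower.
#'
#' @param cross_tab a 3x3 table as produced by [concordance_table()].
#' @return a data frame with one row per discordant cell: `tctu_class`,
#'   `semi_class`, `type`, `count`, plus totals as attributes
#'   `n_overestimated` and `n_underestimated`.
#' @export
discordance_types <- function(cross_tab) {
  cross_tab <- as.table(cross_tab)
  if (!all(dim(cross_tab) == c(3L, 3L))) stop("expected a 3x3 cross-tab")
  rows <- expand.grid(tctu = 1:3, semi = 1:3)
  rows <- rows[rows$tctu != rows$semi, ]
  out <- data.frame(
    tctu_class = .uptake_levels[rows$tctu],
    semi_class = .uptake_levels[rows$semi],
    type = ifelse(rows$semi > rows$tctu, "overestimation", "underestimation"),
    count = cross_tab[cbind(rows$tctu, rows$semi)],
    row.names = NULL
  )
  attr(out, "n_overestimated") <- sum(out$count[out$type == "overestimation"])
  attr(out, "n_underestimated") <- sum(out$count[out$type == "underestimation"])
  out
}
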