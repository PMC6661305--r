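#' @title End-to-end pipeline: simulate, quantify, classify, compare
#' @description
#' `run_pipeline()` exercises the whole stack on a synthetic cohort:
#' phantom generation, per-study quantification (UR, CUR, TcTU),
#' control-based reference ranges, three-class labeling, area
#' stratification, concordance tables with chi-square comparisons of
#' the UR and CUR discordance rates, discordance typing, weighted
#' least-squares regressions of TcTU on S_T, UR and CUR, and
#' Mann-Whitney comparisons of every disease group against the
#' control group. The pipeline is a pure function of (config, seed).
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param s_t1 standardized thyroid area in cm^2; `NULL` uses the
#'   cohort's own control-group mean measured area (as the reference
#'   standard is defined), a number fixes it.
#' @param half_life_h isotope half-life in hours.
#' @param rounding_uptake,rounding_area decimals for reported
#'   reference-range limits.
#' @param use_rounded_limits classify against rounded limits.
#' @param chi_method chi-square flavor for rate comparisons
#'   (`"lr"`, `"pearson"`, `"yates"`).
#' @param weight_scheme WLS weighting (`"variance-function"` or
#'   `"unit"`).
#' @param design cohort design data frame ([cohort_group()] rows).
#' @param base_spec acquisition protocol [phantom_spec()].
#' @param seed cohort seed.
#' @param control_group name of the reference-range group in `design`.
#' @return a `run_config` list.
#' @export
run_config <- function(s_t1 = NULL,
                       half_life_h = TC99M_HALF_LIFE_H,
                       rounding_uptake = 2,
                       rounding_area = 1,
                       use_rounded_limits = TRUE,
                       chi_method = "lr",
                       weight_scheme = "variance-function",
                       design = default_cohort_design(),
                       base_spec = phantom_spec(),
                       seed = 1L,
                       control_group = "control") {
  if (!is.null(s_t1) && s_t1 <= 0) stop("s_t1 must be > 0")
  if (half_life_h <= 0) stop("half_life_h must be > 0")
  structure(list(s_t1 = s_t1, half_life_h = half_life_h,
                 rounding_uptake = rounding_uptake,
                 rounding_area = rounding_area,
                 use_rounded_limits = use_rounded_limits,
                 chi_method = chi_method, weight_scheme = weight_scheme,
                 design = design, base_spec = base_spec,
                 seed = as.integer(seed), control_group = control_group),
            class = "run_config")
}

#' Quantify a synthetic cohort subject by subject
#'
#' Generates one phantom per row of the ground-truth table and runs
#' [quantify_study()] on it, discarding each image after use so large
#' cohorts stay memory-light.
#'
#' @param truth cohort ground truth from [sample_cohort_truth()].
#' @param base_spec acquisition protocol [phantom_spec()].
#' @param s_t1 standardized thyroid area for CUR; `NULL` defers the CUR
#'   computation until the control mean is known (the returned table
#'   then carries `CUR = UR * S_T / s_t1` computed afterwards).
#' @param half_life_h isotope half-life in hours.
#' @return the truth table with measurement columns appended.
#' @export
quantify_cohort <- function(truth, base_spec = phantom_spec(),
                            s_t1 = DEFAULT_S_T1,
                            half_life_h = TC99M_HALF_LIFE_H) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    sp <- base_spec
    sp$gland_area <- truth$gland_area[i]
    sp$true_tctu <- truth$true_tctu[i]
    sp$seed <- truth$seed[i]
    ph <- generate_phantom(sp, half_life_h = half_life_h)
    quantify_study(ph$image, ph$truth$thyroid_mask, ph$truth$background_mask,
                   record = ph$truth$record, calib = ph$truth$calib,
                   s_t1 = if (is.null(s_t1)) DEFAULT_S_T1 else s_t1,
                   half_life_h = half_life_h)
  })
  cbind(truth, do.call(rbind, rows))
}

#' Run the full synthetic pipeline
#'
#' @param config a [run_config()].
#' @return an object of class `thyro_report` with elements `truth`,
#'   `measures`, `s_t1`, `ranges`, `classes`, `concordance` (UR and CUR
#'   [concordance_table()] results), `rate_tests` (per-stratum and
#'   overall UR-vs-CUR chi-squares), `discordance` (typed discordant
#'   cells per stratum for UR and CUR), `regressions` (TcTU on S_T, UR,
#'   CUR), and `group_tests` (Mann-Whitney per disease group vs
#'   control, for UR and CUR).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  truth <- sample_cohort_truth(config$design, config$seed)
  measures <- quantify_cohort(truth, config$base_spec, s_t1 = NULL,
                              half_life_h = config$half_life_h)
  is_ctrl <- measures$group == config$control_group
  if (!any(is_ctrl)) stop("control group '", config$control_group,
                          "' not found in the design")
  s_t1 <- if (is.null(config$s_t1)) mean(measures$S_T[is_ctrl]) else config$s_t1
  measures$CUR <- measures$UR * measures$S_T / s_t1
  measures$C_T1 <- measures$C_T / s_t1

  ru <- config$rounding_uptake
  ranges <- list(
    TcTU = fit_reference_range(measures$TcTU[is_ctrl], "TcTU", ru),
    UR = fit_reference_range(measures$UR[is_ctrl], "UR", ru),
    CUR = fit_reference_range(measures$CUR[is_ctrl], "CUR", ru),
    S_T = fit_reference_range(measures$S_T[is_ctrl], "thyroid area",
                              config$rounding_area)
  )
  ur_cls <- classify_value(measures$UR, ranges$UR, config$use_rounded_limits)
  cur_cls <- classify_value(measures$CUR, ranges$CUR, config$use_rounded_limits)
  tctu_cls <- classify_value(measures$TcTU, ranges$TcTU,
                             config$use_rounded_limits)
  strata <- area_stratum(measures$S_T, ranges$S_T, config$use_rounded_limits)
  classes <- data.frame(subject = measures$subject, group = measures$group,
                        UR_class = ur_cls, CUR_class = cur_cls,
                        TcTU_class = tctu_cls, area_stratum = strata)

  conc_ur <- concordance_table(ur_cls, tctu_cls, strata)
  conc_cur <- concordance_table(cur_cls, tctu_cls, strata)

  rate_test <- function(row_ur, row_cur) {
    .safe_compare_rates(row_ur$concordant, row_ur$n,
                        row_cur$concordant, row_cur$n,
                        method = config$chi_method)
  }
  rate_tests <- c(
    lapply(stats::setNames(names(conc_ur$by_stratum),
                           names(conc_ur$by_stratum)),
           function(s) rate_test(conc_ur$by_stratum[[s]],
                                 conc_cur$by_stratum[[s]])),
    list(overall = rate_test(conc_ur$overall, conc_cur$overall))
  )

  discordance <- list(
    UR = lapply(conc_ur$by_stratum, function(x) discordance_types(x$table)),
    CUR = lapply(conc_cur$by_stratum, function(x) discordance_types(x$table))
  )

  regressions <- list(
    S_T = wls_fit(measures$TcTU, data.frame(S_T = measures$S_T),
                  weight_scheme = config$weight_scheme),
    UR = wls_fit(measures$TcTU, data.frame(UR = measures$UR),
                 weight_scheme = config$weight_scheme),
    CUR = wls_fit(measures$TcTU, data.frame(CUR = measures$CUR),
                  weight_scheme = config$weight_scheme)
  )

  disease <- setdiff(unique(measures$group), config$control_group)
  group_tests <- lapply(stats::setNames(disease, disease), function(g) {
    list(UR = mann_whitney(measures$UR[measures$group == g],
                           measures$UR[is_ctrl]),
         CUR = mann_whitney(measures$CUR[measures$group == g],
                            measures$CUR[is_ctrl]))
  })

  structure(list(config = config, truth = truth, measures = measures,
                 s_t1 = s_t1, ranges = ranges, classes = classes,
                 concordance = list(UR = conc_ur, CUR = conc_cur),
                 rate_tests = rate_tests, discordance = discordance,
                 regressions = regressions, group_tests = group_tests),
            class = "thyro_report")
}

#' @export
print.thyro_report <- function(x, ...) {
  cat(sprintf("thyroid uptake pipeline report: %d subjects, S_T1 = %.2f cm^2\n",
              nrow(x$measures), x$s_t1))
  cat("\nreference ranges (control group):\n")
  for (r in x$ranges) print(r)
  cat("\nUR vs TcTU ")
  print(x$concordance$UR)
  cat("CUR vs TcTU ")
  print(x$concordance$CUR)
  cat("\nUR-vs-CUR concordance rate tests:\n")
  for (s in names(x$rate_tests)) {
    rt <- x$rate_tests[[s]]
    cat(sprintf("  %-8s %5.1f%% vs %5.1f%%  chi2 = %6.2f  p = %s\n",
                s, rt$rate_a, rt$rate_b, rt$statistic, format_p(rt$p.value)))
  }
  cat("\nregressions of TcTU on each parameter (WLS):\n")
  for (nm in names(x$regressions)) {
    f <- x$regressions[[nm]]
    cat(sprintf("  TcTU ~ %-4s R = %.3f  adj R^2 = %.3f  beta = %.3f\n",
                nm, f$R, f$adj.r.squared, f$coefficients$beta[2]))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `measures.csv` (per-subject ground truth + measurements),
#' `classes.csv` (per-subject class labels) and `report.json`
#' (reference ranges, concordance tables, chi-squares, regressions and
#' group tests).
#'
#' @param report a `thyro_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "thyro_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(report$classes, file.path(dir, "classes.csv"),
                   row.names = FALSE)
  rng <- lapply(report$ranges, function(r) {
    r[c("parameter", "mean", "sd", "n", "lower", "upper")]
  })
  conc <- lapply(report$concordance, function(cc) {
    list(summary = cc$summary,
         overall_table = as.data.frame.matrix(cc$overall$table))
  })
  tests <- lapply(report$rate_tests, function(t) {
    t[c("statistic", "df", "p.value", "rate_a", "rate_b")]
  })
  regs <- lapply(report$regressions, function(f) {
    list(coefficients = f$coefficients, R = f$R,
         adj.r.squared = f$adj.r.squared, F = f$F, p.value = f$p.value)
  })
  grp <- lapply(report$group_tests, function(g) {
    lapply(g, function(t) list(U = t$U, Z = t$Z, p.value = t$p.value,
                               summary = t$summary))
  })
  jsonlite::write_json(
    list(s_t1 = report$s_t1, seed = report$config$seed,
         reference_ranges = rng, concordance = conc, rate_tests = tests,
         regressions = regs, group_tests = grp),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
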