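#' Fit a calibration line and derive ICH detection limits
#'
#' Ordinary least squares of absorbance on concentration. Standard errors of
#' slope and intercept are residual-variance based; the limits of detection
#' and quantitation follow the ICH convention with sigma = standard
#' deviation of the intercept: LOD = 3.3 sigma/slope, LOQ = 10 sigma/slope.
#'
#' @param conc_uM concentrations (micromolar), at least 3 distinct values.
#' @param absorbance same-length absorbances (AU).
#' @return An object of class `ct_calibration`: list with `slope`,
#'   `intercept`, `sd_slope`, `sd_intercept`, `r`, `lod_uM`, `loq_uM`, `n`,
#'   `linear_range_uM`.
#' @export
fit_calibration <- function(conc_uM, absorbance) {
  x <- as.numeric(conc_uM); y <- as.numeric(absorbance)
  if (length(x) != length(y)) stop_input("lengths differ")
  if (length(unique(x)) < 3L)
    stop_input("need at least 3 distinct concentrations")
  if (stats::var(x) == 0) stop_input("zero concentration variance")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # perfect fits warn
  slope <- unname(sm["x", "Estimate"])
  intercept <- unname(sm["(Intercept)", "Estimate"])
  if (abs(slope) < .Machine$double.eps * max(abs(y), 1))
    stop_input("degenerate calibration: slope is zero")
  lims <- lod_loq(unname(sm["(Intercept)", "Std. Error"]), abs(slope))
  structure(list(slope = slope, intercept = intercept,
                 sd_slope = unname(sm["x", "Std. Error"]),
                 sd_intercept = unname(sm["(Intercept)", "Std. Error"]),
                 r = stats::cor(x, y),
                 lod_uM = lims$lod_uM, loq_uM = lims$loq_uM,
                 n = length(x), linear_range_uM = range(x)),
            class = "ct_calibration")
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf(paste0("<calibration> n = %d over %.4g-%.4g uM\n",
                     "  A = %.6g c + %.6g   (r = %.4f)\n",
                     "  sd(slope) = %.4g, sd(intercept) = %.4g\n",
                     "  LOD = %.4f uM, LOQ = %.4f uM\n"),
              x$n, x$linear_range_uM[1], x$linear_range_uM[2],
              x$slope, x$intercept, x$r, x$sd_slope, x$sd_intercept,
              x$lod_uM, x$loq_uM))
  invisible(x)
}

#' ICH limits of detection and quantitation
#'
#' `lod = 3.3 sigma/S`, `loq = 10 sigma/S` with sigma the standard deviation
#' of the calibration intercept and S the slope. The LOQ/LOD ratio is
#' exactly 10/3.3, and both limits are invariant under common rescaling of
#' sigma and S.
#'
#' @param sd_intercept nonnegative standard deviation of the intercept (AU).
#' @param slope positive calibration slope (AU/uM).
#' @return A list with `lod_uM` and `loq_uM`.
#' @examples
#' lod_loq(0.0009602, 0.002922)  # 1.0844 and 3.2861 uM
#' @export
lod_loq <- function(sd_intercept, slope) {
  check_number(sd_intercept, "sd_intercept", nonneg = TRUE)
  check_number(slope, "slope", positive = TRUE)
  list(lod_uM = ct_constants$ich_lod_factor * sd_intercept / slope,
       loq_uM = ct_constants$ich_loq_factor * sd_intercept / slope)
}

#' Relative standard deviation of replicates
#'
#' `100 * sd(values) / mean(values)` with the sample (n-1) standard
#' deviation. Invariant under multiplying all values by a positive constant.
#'
#' @param values at least 2 replicate measurements with nonzero mean.
#' @return RSD in percent.
#' @export
rsd_percent <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop_input("need at least 2 values")
  m <- mean(v)
  if (m == 0) stop_input("mean of values is zero")
  100 * stats::sd(v) / m
}

#' Recovery of a spiked concentration
#'
#' @param taken_uM positive nominal (spiked) concentration.
#' @param found_uM one or more back-calculated concentrations.
#' @return A list with `mean_pct` (`100 mean(found)/taken`) and `sd_pct`
#'   (`100 sd(found)/taken`; `NA` for a single replicate).
#' @export
recovery_percent <- function(taken_uM, found_uM) {
  check_number(taken_uM, "taken_uM", positive = TRUE)
  f <- as.numeric(found_uM)
  if (length(f) < 1L) stop_input("need at least one found value")
  list(mean_pct = 100 * mean(f) / taken_uM,
       sd_pct = if (length(f) > 1L) 100 * stats::sd(f) / taken_uM else NA_real_)
}

#' Precision and accuracy summary for replicate assay data
#'
#' Computes intra-assay RSD (pooled across days as the mean of per-day
#' RSDs), inter-assay RSD (across day means), and recovery, per
#' concentration level.
#'
#' @param replicates data frame with columns `taken_uM`, `found_uM`,
#'   `assay_day`.
#' @return A data frame with one row per level: `taken_uM`, `intra_rsd_pct`,
#'   `inter_rsd_pct`, `recovery_pct`, `recovery_sd`.
#' @export
precision_accuracy <- function(replicates) {
  need <- c("taken_uM", "found_uM", "assay_day")
  if (!all(need %in% names(replicates)))
    stop_input("replicates need columns %s", paste(need, collapse = ","))
  out <- lapply(split(replicates, replicates$taken_uM), function(d) {
    per_day <- split(d$found_uM, d$assay_day)
    intra <- mean(vapply(per_day, rsd_percent, numeric(1)))
    day_means <- vapply(per_day, mean, numeric(1))
    inter <- if (length(day_means) > 1L) rsd_percent(day_means) else NA_real_
    rec <- recovery_percent(d$taken_uM[1], d$found_uM)
    data.frame(taken_uM = d$taken_uM[1], intra_rsd_pct = intra,
               inter_rsd_pct = inter, recovery_pct = rec$mean_pct,
               recovery_sd = rec$sd_pct)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$taken_uM), , drop = FALSE]
}

#' Render a validation report
#'
#' Markdown tables mirroring the usual calibration/validation and
#' precision/accuracy layouts, with LOD/LOQ rounded to 4 decimals and RSD to
#' 3 (full precision is retained in the underlying objects).
#'
#' @param calibration a [fit_calibration()] result (or named list of them).
#' @param precision optional [precision_accuracy()] table (or named list).
#' @return A character vector of Markdown lines.
#' @export
validation_report_md <- function(calibration, precision = NULL) {
  cals <- if (inherits(calibration, "ct_calibration"))
    list(assay = calibration) else calibration
  lines <- c("| Parameter | " %+% paste(names(cals), collapse = " | ") %+% " |",
             "|---" %+% strrep("|---", length(cals)) %+% "|")
  row <- function(lab, fmt, field)
    "| " %+% lab %+% " | " %+%
      paste(vapply(cals, function(c) sprintf(fmt, c[[field]]), ""),
            collapse = " | ") %+% " |"
  lines <- c(lines,
    "| Linear range (uM) | " %+%
      paste(vapply(cals, function(c)
        sprintf("%g-%g", c$linear_range_uM[1], c$linear_range_uM[2]), ""),
        collapse = " | ") %+% " |",
    row("Intercept", "%.5g", "intercept"),
    row("SD of intercept", "%.4g", "sd_intercept"),
    row("Slope", "%.4g", "slope"),
    row("SD of slope", "%.4g", "sd_slope"),
    row("Correlation coefficient", "%.4f", "r"),
    row("LOD (uM)", "%.4f", "lod_uM"),
    row("LOQ (uM)", "%.4f", "loq_uM"))
  if (!is.null(precision)) {
    precs <- if (is.data.frame(precision)) list(assay = precision) else precision
    for (nm in names(precs)) {
      p <- precs[[nm]]
      lines <- c(lines, "", sprintf("**%s precision and accuracy**", nm), "",
        "| Taken (uM) | Intra-assay RSD (%) | Inter-assay RSD (%) | Recovery (% +/- SD) |",
        "|---|---|---|---|",
        sprintf("| %g | %.3f | %.3f | %.2f +/- %.2f |",
                p$taken_uM, p$intra_rsd_pct, p$inter_rsd_pct,
                p$recovery_pct, p$recovery_sd))
    }
  }
  lines
}

`%+%` <- function(a, b) paste0(a, b)
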