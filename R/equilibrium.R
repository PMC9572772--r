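#' Exact 1:1 complexation equilibrium
#'
#' For D + A <-> DA with association constant `kc` (L/mol), the complex
#' concentration is the physical root of
#' `c^2 - (d0 + a0 + 1/kc) c + d0 a0 = 0`, i.e. the branch with
#' `0 <= c <= min(d0, a0)`. Evaluated in the numerically stable form
#' `c = 2 d0 a0 / (b + sqrt(b^2 - 4 d0 a0))` to avoid cancellation when the
#' complex is weakly bound.
#'
#' @param d0_M,a0_M initial donor and acceptor concentrations (mol/L),
#'   vectors recycled to common length.
#' @param kc association constant (L/mol), > 0.
#' @return Complex concentration(s) in mol/L.
#' @examples
#' solve_equilibrium_1to1(5e-5, 5e-5, 1e6)
#' @export
solve_equilibrium_1to1 <- function(d0_M, a0_M, kc) {
  if (any(!is.finite(d0_M)) || any(d0_M < 0) ||
      any(!is.finite(a0_M)) || any(a0_M < 0))
    stop_input("concentrations must be finite and nonnegative")
  check_number(kc, "kc", positive = TRUE)
  b <- d0_M + a0_M + 1 / kc
  disc <- b^2 - 4 * d0_M * a0_M
  c <- 2 * d0_M * a0_M / (b + sqrt(pmax(disc, 0)))
  pmin(c, pmin(d0_M, a0_M))  # clip roundoff past the mass-balance bound
}

#' General m:n complexation equilibrium (numeric)
#'
#' Solves mD + nA <-> DmAn for the complex concentration by bisection on the
#' mass-action equation `kc (d0 - m c)^m (a0 - n c)^n = c`.
#'
#' @param d0_M,a0_M initial concentrations (mol/L).
#' @param kc overall association constant (appropriate power units).
#' @param m,n small positive integer stoichiometric coefficients.
#' @return Complex concentration in mol/L.
#' @export
solve_equilibrium_mn <- function(d0_M, a0_M, kc, m = 1L, n = 1L) {
  check_number(d0_M, "d0_M", nonneg = TRUE)
  check_number(a0_M, "a0_M", nonneg = TRUE)
  check_number(kc, "kc", positive = TRUE)
  if (m == 1L && n == 1L) return(solve_equilibrium_1to1(d0_M, a0_M, kc))
  cmax <- min(d0_M / m, a0_M / n)
  if (cmax <= 0) return(0)
  f <- function(c) kc * (d0_M - m * c)^m * (a0_M - n * c)^n - c
  stats::uniroot(f, c(0, cmax * (1 - 1e-13)), tol = cmax * 1e-14)$root
}

#' Job continuous-variation series
#'
#' Absorbance versus donor mole fraction at fixed total concentration.
#'
#' @param mole_fraction_donor strictly increasing values in `[0, 1]`.
#' @param absorbance same-length nonnegative absorbances (AU).
#' @param total_conc_M positive total concentration (mol/L).
#' @param lambda_nm monitoring wavelength (nm).
#' @return An object of class `ct_job_series`.
#' @export
job_series <- function(mole_fraction_donor, absorbance, total_conc_M,
                       lambda_nm = NA_real_) {
  x <- as.numeric(mole_fraction_donor)
  a <- as.numeric(absorbance)
  if (length(x) != length(a)) stop_input("lengths differ")
  if (any(x < 0 | x > 1)) stop_input("mole fractions must lie in [0, 1]")
  if (any(diff(x) <= 0)) stop_input("mole fractions must be strictly increasing")
  if (any(a < 0)) stop_input("absorbances must be nonnegative")
  check_number(total_conc_M, "total_conc_M", positive = TRUE)
  structure(list(mole_fraction_donor = x, absorbance = a,
                 total_conc_M = total_conc_M, lambda_nm = lambda_nm),
            class = "ct_job_series")
}

#' Photometric titration series at fixed donor concentration
#'
#' @param donor_conc_M fixed initial donor concentration (mol/L).
#' @param acceptor_conc_M strictly increasing acceptor concentrations (mol/L).
#' @param absorbance same-length positive absorbances (AU).
#' @param lambda_nm monitoring wavelength (nm).
#' @return An object of class `ct_titration_series`.
#' @export
titration_series <- function(donor_conc_M, acceptor_conc_M, absorbance,
                             lambda_nm = NA_real_) {
  check_number(donor_conc_M, "donor_conc_M", positive = TRUE)
  a0 <- as.numeric(acceptor_conc_M)
  ab <- as.numeric(absorbance)
  if (length(a0) != length(ab)) stop_input("lengths differ")
  if (any(a0 <= 0)) stop_input("acceptor concentrations must be positive")
  if (any(diff(a0) <= 0))
    stop_input("acceptor concentrations must be strictly increasing")
  structure(list(donor_conc_M = donor_conc_M, acceptor_conc_M = a0,
                 absorbance = ab, lambda_nm = lambda_nm),
            class = "ct_titration_series")
}

#' Job's continuous-variation analysis
#'
#' Locates the mole fraction of maximum absorbance by fitting a local
#' quadratic through the top `window` points (robust to noise, unlike a raw
#' argmax) and reports the nearest small-integer donor:acceptor
#' stoichiometry. A maximum `x_max` maps to m:n with
#' `n/m = (1 - x_max)/x_max`; candidates up to index 3 are considered and
#' anything farther than 0.06 in mole fraction is flagged indeterminate.
#'
#' @param series a [job_series()]; needs at least 5 points spanning both
#'   sides of the maximum.
#' @param window odd number of top points for the quadratic fit (default 5).
#' @return A list with `x_max`, `stoichiometry` (e.g. `"1:1"` or
#'   `"indeterminate"`), `donor` and `acceptor` integer parts (NA when
#'   indeterminate), and the fitted quadratic coefficients.
#' @export
job_analysis <- function(series, window = 5) {
  stopifnot(inherits(series, "ct_job_series"))
  x <- series$mole_fraction_donor
  a <- series$absorbance
  n <- length(x)
  if (n < 5L) stop_input("need at least 5 points")
  i_max <- which.max(a)
  if (i_max == 1L || i_max == n)
    stop_input("absorbance maximum at the series boundary: degenerate series")
  window <- min(window, n)
  half <- window %/% 2
  lo <- max(1L, i_max - half)
  hi <- min(n, i_max + half)
  lo <- max(1L, min(lo, hi - window + 1L))
  hi <- min(n, lo + window - 1L)
  xs <- x[lo:hi]; as <- a[lo:hi]
  fit <- stats::lm(as ~ xs + I(xs^2))
  co <- stats::coef(fit)
  if (!is.finite(co[3]) || co[3] >= 0)
    stop_input("local fit is not concave: cannot locate a maximum")
  x_max <- -co[2] / (2 * co[3])
  if (x_max <= min(x) || x_max >= max(x))
    stop_input("fitted maximum outside the sampled range: degenerate series")
  ratios <- expand.grid(m = 1:3, n = 1:3)
  ratios <- ratios[ratios$m == 1 | ratios$n == 1, ]
  ratios$x <- ratios$m / (ratios$m + ratios$n)
  k <- which.min(abs(ratios$x - x_max))
  if (abs(ratios$x[k] - x_max) > 0.06) {
    stoich <- "indeterminate"; m <- NA_integer_; nn <- NA_integer_
  } else {
    m <- ratios$m[k]; nn <- ratios$n[k]
    stoich <- sprintf("%d:%d", m, nn)
  }
  list(x_max = as.numeric(x_max), stoichiometry = stoich,
       donor = m, acceptor = nn, quad_coef = unname(co))
}

#' Molar-ratio (photometric titration) breakpoint
#'
#' Fits two unconstrained least-squares line segments over every admissible
#' split of the ordered data (each segment keeps at least 3 points), selects
#' the split with minimal total residual sum of squares, and returns the
#' abscissa where the two lines intersect — the stoichiometric break.
#'
#' @param ratio increasing acceptor/donor mole ratios (at least 6 points).
#' @param absorbance same-length absorbances.
#' @return A list with `ratio_at_break`, the chosen `split` index (last point
#'   of the first segment), segment coefficients and the total `rss`.
#' @export
molar_ratio_breakpoint <- function(ratio, absorbance) {
  r <- as.numeric(ratio); a <- as.numeric(absorbance)
  if (length(r) != length(a)) stop_input("lengths differ")
  n <- length(r)
  if (n < 6L) stop_input("need at least 6 points (3 per segment)")
  if (any(diff(r) <= 0)) stop_input("ratios must be strictly increasing")
  seg_fit <- function(idx) {
    f <- stats::lm(a[idx] ~ r[idx])
    list(coef = unname(stats::coef(f)), rss = sum(stats::resid(f)^2))
  }
  best <- NULL
  for (k in 3:(n - 3)) {
    f1 <- seg_fit(1:k); f2 <- seg_fit((k + 1):n)
    rss <- f1$rss + f2$rss
    if (is.null(best) || rss < best$rss)
      best <- list(split = k, rss = rss, left = f1$coef, right = f2$coef)
  }
  dm <- best$left[2] - best$right[2]
  if (abs(dm) < .Machine$double.eps * 100)
    stop_input("segments are parallel: no breakpoint")
  xb <- (best$right[1] - best$left[1]) / dm
  list(ratio_at_break = as.numeric(xb), split = best$split,
       left_coef = best$left, right_coef = best$right, rss = best$rss)
}

#' Benesi-Hildebrand fit for a 1:1 complex
#'
#' Ordinary least squares of `y = [D]/A` against `x = 1/[A]` (acceptor in
#' excess). The line has slope `1/(Kc eps_c)` and intercept `1/eps_c`, so
#' `Kc = intercept/slope` and `eps_c = 1/intercept`. The fit is unweighted; a
#' degenerate slope or intercept (<= 0) is carried as a warning flag on the
#' result rather than an error.
#'
#' @param series a [titration_series()] with at least 3 points and positive
#'   absorbances.
#' @param weighted if `TRUE`, weight by `A^4/[D]^2` (inverse-variance under
#'   constant absorbance noise); off by default.
#' @return An object of class `ct_bh_fit`: list with `slope`, `intercept`,
#'   `r` (Pearson), `kc_L_per_mol`, `epsilon_c`, `n_points`, `degenerate`.
#' @export
benesi_hildebrand_fit <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "ct_titration_series"))
  if (length(series$absorbance) < 3L) stop_input("need at least 3 points")
  if (any(series$absorbance <= 0)) stop_input("absorbances must be positive")
  x <- 1 / series$acceptor_conc_M
  y <- series$donor_conc_M / series$absorbance
  w <- if (weighted) series$absorbance^4 / series$donor_conc_M^2 else NULL
  fit <- stats::lm(y ~ x, weights = w)
  co <- unname(stats::coef(fit))
  intercept <- co[1]; slope <- co[2]
  degenerate <- slope <= 0 || intercept <= 0
  if (degenerate)
    warning("degenerate Benesi-Hildebrand fit: nonpositive slope or intercept")
  structure(list(slope = slope, intercept = intercept,
                 r = stats::cor(x, y),
                 kc_L_per_mol = intercept / slope,
                 epsilon_c = 1 / intercept,
                 n_points = length(x), degenerate = degenerate),
            class = "ct_bh_fit")
}

#' @export
print.ct_bh_fit <- function(x, ...) {
  cat(sprintf(paste0("<Benesi-Hildebrand fit> n = %d\n",
                     "  y = %.4g x + %.4g   (r = %.4f)\n",
                     "  Kc = %.4g L/mol, eps_c = %.4g L/(mol cm)%s\n"),
              x$n_points, x$slope, x$intercept, x$r, x$kc_L_per_mol,
              x$epsilon_c, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Standard Gibbs free energy of complexation
#'
#' `dG0 = -2.303 R T log10(Kc)` with R = 8.314 J/(mol K), reported in
#' kcal/mol (thermochemical calorie, 4184 J). By construction `dG0 < 0`
#' exactly when `Kc > 1`.
#'
#' @param kc association constant (L/mol), > 0.
#' @param temperature_K absolute temperature (default 298 K for 25 C).
#' @return An object of class `ct_thermo`: list with `delta_g_kcal_per_mol`,
#'   `temperature_K`, `kc_L_per_mol`.
#' @examples
#' gibbs_free_energy(1.47e12, 298)  # about -16.59 kcal/mol
#' @export
gibbs_free_energy <- function(kc, temperature_K = 298) {
  check_number(kc, "kc", positive = TRUE)
  check_number(temperature_K, "temperature_K", positive = TRUE)
  dg_j <- -2.303 * ct_constants$gas_constant_J * temperature_K * log10(kc)
  structure(list(delta_g_kcal_per_mol = dg_j / ct_constants$joule_per_kcal,
                 temperature_K = temperature_K, kc_L_per_mol = kc),
            class = "ct_thermo")
}

#' @export
print.ct_thermo <- function(x, ...) {
  cat(sprintf("<thermo> Kc = %.4g L/mol at %g K: dG0 = %.4f kcal/mol\n",
              x$kc_L_per_mol, x$temperature_K, x$delta_g_kcal_per_mol))
  invisible(x)
}

# CSV interfaces -------------------------------------------------------------

read_meta_comments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.+)$", meta))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- as.numeric(m[3])
  out
}

#' Read titration and Job CSV files
#'
#' Titration files have columns `acceptor_conc_M,absorbance` plus metadata
#' comment lines `# donor_conc_M=...` and `# lambda_nm=...`; Job files have
#' `mole_fraction_donor,absorbance` plus `# total_conc_M=...`.
#'
#' @param path file path.
#' @return A [titration_series()] or [job_series()].
#' @export
read_titration_csv <- function(path) {
  meta <- read_meta_comments(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(meta$donor_conc_M))
    stop_input("titration CSV missing `# donor_conc_M=` metadata line")
  titration_series(meta$donor_conc_M, df$acceptor_conc_M, df$absorbance,
                   lambda_nm = if (is.null(meta$lambda_nm)) NA_real_
                               else meta$lambda_nm)
}

#' @rdname read_titration_csv
#' @export
read_job_csv <- function(path) {
  meta <- read_meta_comments(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(meta$total_conc_M))
    stop_input("Job CSV missing `# total_conc_M=` metadata line")
  job_series(df$mole_fraction_donor, df$absorbance, meta$total_conc_M,
             lambda_nm = if (is.null(meta$lambda_nm)) NA_real_
                         else meta$lambda_nm)
}

#' @rdname read_titration_csv
#' @param series series object to write.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "ct_titration_series"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# donor_conc_M=%.10g", series$donor_conc_M), con)
  if (is.finite(series$lambda_nm))
    writeLines(sprintf("# lambda_nm=%.10g", series$lambda_nm), con)
  utils::write.table(data.frame(acceptor_conc_M = series$acceptor_conc_M,
                                absorbance = series$absorbance),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_titration_csv
#' @export
write_job_csv <- function(series, path) {
  stopifnot(inherits(series, "ct_job_series"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# total_conc_M=%.10g", series$total_conc_M), con)
  if (is.finite(series$lambda_nm))
    writeLines(sprintf("# lambda_nm=%.10g", series$lambda_nm), con)
  utils::write.table(data.frame(mole_fraction_donor = series$mole_fraction_donor,
                                absorbance = series$absorbance),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
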