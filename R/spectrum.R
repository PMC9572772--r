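#' Construct an absorption spectrum
#'
#' A spectrum is a sampled absorbance curve with solvent and pathlength
#' metadata. Wavelengths must be strictly increasing and the same length as
#' the absorbance vector.
#'
#' @param wavelength_nm strictly increasing numeric vector of wavelengths (nm).
#' @param absorbance numeric vector of absorbances (AU), same length.
#' @param label character label for the curve (e.g. the complex name).
#' @param solvent character solvent name.
#' @param pathlength_cm positive cuvette pathlength in cm (default 1).
#' @return An object of class `ct_spectrum`: a list with the fields above.
#' @examples
#' sp <- ct_spectrum(400:700, exp(-((400:700 - 487.5) / 30)^2))
#' find_lambda_max(sp, c(400, 600))
#' @export
ct_spectrum <- function(wavelength_nm, absorbance, label = "",
                        solvent = "", pathlength_cm = 1) {
  wavelength_nm <- as.numeric(wavelength_nm)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength_nm) != length(absorbance))
    stop_input("wavelength and absorbance must have equal length")
  if (length(wavelength_nm) < 1L)
    stop_input("spectrum must contain at least one point")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(absorbance)))
    stop_input("spectrum values must be finite")
  if (any(diff(wavelength_nm) <= 0))
    stop_input("wavelengths must be strictly increasing")
  check_number(pathlength_cm, "pathlength_cm", positive = TRUE)
  structure(list(wavelength_nm = wavelength_nm, absorbance = absorbance,
                 label = as.character(label), solvent = as.character(solvent),
                 pathlength_cm = pathlength_cm),
            class = "ct_spectrum")
}

#' @export
print.ct_spectrum <- function(x, ...) {
  cat(sprintf("<ct_spectrum> %s%s: %d points, %.1f-%.1f nm, pathlength %g cm\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              if (nzchar(x$solvent)) paste0(" in ", x$solvent) else "",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$pathlength_cm))
  invisible(x)
}

#' Locate the absorbance maximum within a wavelength window
#'
#' Returns the sampled wavelength of maximum absorbance inside `window_nm`.
#' Ties are broken toward the longer wavelength, since the charge-transfer
#' band is the red-most feature of interest.
#'
#' @param spectrum a [ct_spectrum()].
#' @param window_nm numeric `c(low, high)` window; must contain at least 3
#'   sampled points.
#' @return A list with `lambda_max_nm` and `a_max`.
#' @export
find_lambda_max <- function(spectrum, window_nm = range(spectrum$wavelength_nm)) {
  stopifnot(inherits(spectrum, "ct_spectrum"))
  if (length(window_nm) != 2L || !all(is.finite(window_nm)) ||
      window_nm[1] >= window_nm[2])
    stop_input("window_nm must be c(low, high) with low < high")
  keep <- spectrum$wavelength_nm >= window_nm[1] &
          spectrum$wavelength_nm <= window_nm[2]
  if (sum(keep) < 3L)
    stop_input("window must contain at least 3 sampled points (has %d)",
               sum(keep))
  wl <- spectrum$wavelength_nm[keep]
  ab <- spectrum$absorbance[keep]
  idx <- max(which(ab == max(ab)))   # tie-break: longest wavelength
  list(lambda_max_nm = wl[idx], a_max = ab[idx])
}

#' Convert wavelength to photon energy and back
#'
#' Uses hc = 1239.84 eV nm (see [ct_constants]). `ev_to_wavelength` is the
#' exact inverse.
#'
#' @param lambda_nm positive wavelength(s) in nm.
#' @param energy_ev positive photon energy(ies) in eV.
#' @return Numeric vector of energies (eV) or wavelengths (nm).
#' @examples
#' wavelength_to_ev(487.5)  # 2.54 eV at 2 dp
#' @export
wavelength_to_ev <- function(lambda_nm) {
  if (!is.numeric(lambda_nm) || any(!is.finite(lambda_nm)) ||
      any(lambda_nm <= 0))
    stop_input("lambda_nm must be positive and finite")
  ct_constants$hc_ev_nm / lambda_nm
}

#' @rdname wavelength_to_ev
#' @export
ev_to_wavelength <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) ||
      any(energy_ev <= 0))
    stop_input("energy_ev must be positive and finite")
  ct_constants$hc_ev_nm / energy_ev
}

#' Build a table of electronic excited states
#'
#' Each state carries a transition wavelength, the corresponding photon
#' energy, an oscillator strength and an optional assignment (e.g.
#' `"HOMO -> LUMO (99%)"`). If `energy_ev` is supplied it must agree with
#' `hc / lambda_nm` to within 0.5%; otherwise it is computed.
#'
#' @param lambda_nm positive wavelengths (nm).
#' @param osc_strength nonnegative oscillator strengths (dimensionless f).
#' @param assignment character vector of transition assignments.
#' @param energy_ev optional energies (eV), checked against `lambda_nm`.
#' @return A `data.frame` of class `ct_excited_states` with columns
#'   `lambda_nm`, `energy_ev`, `osc_strength`, `assignment`.
#' @export
excited_states <- function(lambda_nm, osc_strength,
                           assignment = "", energy_ev = NULL) {
  if (!is.numeric(lambda_nm) || length(lambda_nm) < 1L ||
      any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop_input("lambda_nm must be positive")
  if (length(osc_strength) != length(lambda_nm) ||
      any(!is.finite(osc_strength)) || any(osc_strength < 0))
    stop_input("osc_strength must be nonnegative, one per state")
  if (is.null(energy_ev)) {
    energy_ev <- wavelength_to_ev(lambda_nm)
  } else {
    rel <- abs(energy_ev * lambda_nm / ct_constants$hc_ev_nm - 1)
    if (any(rel > 0.005))
      stop_input("energy_ev x lambda_nm deviates from hc by more than 0.5%%")
  }
  out <- data.frame(lambda_nm = lambda_nm, energy_ev = energy_ev,
                    osc_strength = osc_strength,
                    assignment = rep_len(as.character(assignment),
                                         length(lambda_nm)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_excited_states", "data.frame")
  out
}

#' Convolve excited states into a simulated UV-Vis spectrum
#'
#' Sums one Gaussian band per state in energy space, centred at the state's
#' transition energy, with a common full width at half maximum and amplitude
#' equal to the oscillator strength (arbitrary units). The default FWHM of
#' 0.333 eV follows the usual spectral-convolution convention for
#' time-dependent DFT state lists.
#'
#' @param states a [excited_states()] table (or data frame with `lambda_nm`
#'   and `osc_strength`).
#' @param fwhm_ev positive Gaussian full width at half maximum in eV.
#' @param grid_nm wavelengths (nm) on which to sample the simulated curve.
#' @param label,solvent metadata passed to [ct_spectrum()].
#' @return A [ct_spectrum()] sampled on `grid_nm`.
#' @export
simulate_uv_spectrum <- function(states, fwhm_ev = 0.333,
                                 grid_nm = seq(200, 700, by = 1),
                                 label = "simulated", solvent = "") {
  if (NROW(states) < 1L) stop_input("need at least one excited state")
  check_number(fwhm_ev, "fwhm_ev", positive = TRUE)
  if (is.null(states$energy_ev)) states$energy_ev <- wavelength_to_ev(states$lambda_nm)
  grid_nm <- sort(as.numeric(grid_nm))
  e_grid <- wavelength_to_ev(grid_nm)
  sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
  a <- rep(0, length(e_grid))
  for (i in seq_len(NROW(states))) {
    a <- a + states$osc_strength[i] *
      exp(-(e_grid - states$energy_ev[i])^2 / (2 * sigma^2))
  }
  ct_spectrum(grid_nm, a, label = label, solvent = solvent)
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Optional preprocessing; never applied implicitly by any other function.
#'
#' @param spectrum a [ct_spectrum()].
#' @param p polynomial order (default 3).
#' @param n odd window length in points (default 11).
#' @return The smoothed [ct_spectrum()].
#' @export
smooth_spectrum <- function(spectrum, p = 3, n = 11) {
  stopifnot(inherits(spectrum, "ct_spectrum"))
  if (n %% 2 == 0) stop_input("window length n must be odd")
  if (length(spectrum$absorbance) < n)
    stop_input("spectrum shorter than smoothing window")
  spectrum$absorbance <- as.numeric(
    signal::sgolayfilt(spectrum$absorbance, p = p, n = n))
  spectrum
}

# CSV input/output -----------------------------------------------------------

#' Read and write spectrum and excited-state CSV files
#'
#' Spectrum files have header `wavelength_nm,absorbance`; excited-state files
#' have `lambda_nm,osc_strength,assignment`. Lines starting with `#` are
#' treated as comments.
#'
#' @param path file path.
#' @param ... passed to [ct_spectrum()] (metadata fields).
#' @return `read_spectrum_csv` returns a [ct_spectrum()];
#'   `read_excited_states_csv` a [excited_states()] table.
#' @export
read_spectrum_csv <- function(path, ...) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "absorbance")
  if (!all(need %in% names(df)))
    stop_input("spectrum CSV must have columns %s", paste(need, collapse = ","))
  ct_spectrum(df$wavelength_nm, df$absorbance, ...)
}

#' @rdname read_spectrum_csv
#' @param spectrum a [ct_spectrum()] to write.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ct_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                              absorbance = spectrum$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_spectrum_csv
#' @export
read_excited_states_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("lambda_nm", "osc_strength")
  if (!all(need %in% names(df)))
    stop_input("excited-state CSV must have columns %s",
               paste(need, collapse = ","))
  excited_states(df$lambda_nm, df$osc_strength,
                 assignment = if (is.null(df$assignment)) "" else df$assignment)
}
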