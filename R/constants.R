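#' Physical constants and conversion factors
#'
#' Conversion factors used throughout the package. `hc` is fixed at
#' 1239.84 eV nm, which reproduces all wavelength/band-gap pairs of the
#' reference tables at two-decimal rounding. Energies printed in hartree are
#' converted at 627.5095 kcal/mol; the thermochemical calorie (4184 J) is
#' used for Gibbs energies.
#'
#' @format A named list:
#' \describe{
#'   \item{hc_ev_nm}{Planck constant times speed of light, 1239.84 eV nm.}
#'   \item{hartree_kcal}{627.5095 kcal/mol per hartree.}
#'   \item{bohr_per_angstrom}{1.8897259886 bohr per angstrom.}
#'   \item{gas_constant_J}{R = 8.314 J mol^-1 K^-1.}
#'   \item{joule_per_kcal}{4184 J per thermochemical kcal.}
#'   \item{ich_lod_factor, ich_loq_factor}{ICH factors 3.3 and 10.}
#' }
#' @export
ct_constants <- list(
  hc_ev_nm           = 1239.84,
  hartree_kcal       = 627.5095,
  bohr_per_angstrom  = 1.8897259886,
  gas_constant_J     = 8.314,
  joule_per_kcal     = 4184,
  ich_lod_factor     = 3.3,
  ich_loq_factor     = 10
)

# internal argument checkers -------------------------------------------------

stop_input <- function(...) {
  stop(structure(class = c("ctclab_input_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_input("`%s` must be > 0", name)
  if (nonneg && x < 0) stop_input("`%s` must be >= 0", name)
  invisible(x)
}
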