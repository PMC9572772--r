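# shared fixtures built in code

cp_fixture_path <- function() {
  system.file("extdata", "lgn_complex_bcps.csv", package = "ctclab")
}

# independent mass-action oracle for the 1:1 equilibrium (bisection, not the
# closed-form quadratic used by the implementation)
oracle_equilibrium_1to1 <- function(d0, a0, kc) {
  if (d0 == 0 || a0 == 0) return(0)
  f <- function(c) kc * (d0 - c) * (a0 - c) - c
  uniroot(f, c(0, min(d0, a0) * (1 - 1e-14)), tol = min(d0, a0) * 1e-14)$root
}

# gaussian absorption band on a regular wavelength grid
gaussian_band <- function(center, width = 30, grid = seq(350, 650, by = 0.5),
                          height = 1) {
  ct_spectrum(grid, height * exp(-((grid - center) / width)^2))
}
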