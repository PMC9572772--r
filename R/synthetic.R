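# Synthetic data with known ground truth for every analysis stage.

# run expr with a temporary RNG state seeded from `seed`, restoring on exit
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a simulated binding experiment
#'
#' Ground-truth parameters for the titration and Job generators. The noise
#' model is multiplicative on absorbance by default (photometric noise
#' scales with signal at these absorbances); set `noise_additive = TRUE`
#' for additive noise at the same sigma.
#'
#' @param kc_true true association constant (L/mol or the m:n analogue).
#' @param epsilon_c true molar absorptivity of the complex (L/(mol cm)).
#' @param stoichiometry integer `c(m, n)` for the DmAn complex; one of
#'   1:1, 1:2, 2:1.
#' @param noise_rel relative noise level (< 0.5).
#' @param seed integer RNG seed; generators are pure functions of
#'   (spec, seed).
#' @param donor_conc_M fixed donor concentration for titrations (mol/L).
#' @param acceptor_conc_M acceptor design for titrations (mol/L).
#' @param total_conc_M total concentration for Job series (mol/L).
#' @param pathlength_cm cuvette pathlength.
#' @param lambda_nm nominal monitoring wavelength.
#' @param noise_additive use additive instead of multiplicative noise.
#' @return An object of class `ct_sim_spec`.
#' @export
simulation_spec <- function(kc_true, epsilon_c, stoichiometry = c(1L, 1L),
                            noise_rel = 0, seed = 1L,
                            donor_conc_M = 3e-6,
                            acceptor_conc_M = seq(1e-6, 4e-6, length.out = 7),
                            total_conc_M = 1e-4, pathlength_cm = 1,
                            lambda_nm = 487.5, noise_additive = FALSE) {
  check_number(kc_true, "kc_true", positive = TRUE)
  check_number(epsilon_c, "epsilon_c", positive = TRUE)
  check_number(noise_rel, "noise_rel", nonneg = TRUE)
  if (noise_rel >= 0.5) stop_input("noise_rel must be < 0.5")
  stoichiometry <- as.integer(stoichiometry)
  if (length(stoichiometry) != 2L || any(stoichiometry < 1L) ||
      !(paste(stoichiometry, collapse = ":") %in% c("1:1", "1:2", "2:1")))
    stop_input("stoichiometry must be one of 1:1, 1:2, 2:1")
  if (any(acceptor_conc_M <= 0) || donor_conc_M <= 0 || total_conc_M <= 0)
    stop_input("concentrations must be positive")
  structure(list(kc_true = kc_true, epsilon_c = epsilon_c,
                 stoichiometry = stoichiometry, noise_rel = noise_rel,
                 seed = as.integer(seed), donor_conc_M = donor_conc_M,
                 acceptor_conc_M = as.numeric(acceptor_conc_M),
                 total_conc_M = total_conc_M, pathlength_cm = pathlength_cm,
                 lambda_nm = lambda_nm, noise_additive = noise_additive),
            class = "ct_sim_spec")
}

sim_complex_conc <- function(spec, d0, a0) {
  m <- spec$stoichiometry[1]; n <- spec$stoichiometry[2]
  if (m == 1L && n == 1L) return(solve_equilibrium_1to1(d0, a0, spec$kc_true))
  mapply(function(d, a) solve_equilibrium_mn(d, a, spec$kc_true, m, n), d0, a0)
}

apply_noise <- function(spec, a_clean) {
  if (spec$noise_rel == 0) return(a_clean)
  eps <- stats::rnorm(length(a_clean), 0, spec$noise_rel)
  if (spec$noise_additive) a_clean + mean(a_clean) * eps
  else a_clean * (1 + eps)
}

#' Simulate a photometric titration series
#'
#' Absorbance is Beer-Lambert from the exact equilibrium complex
#' concentration: `A = eps_c * [complex] * pathlength * (1 + noise)`.
#' Deterministic under a fixed seed.
#'
#' @param spec a [simulation_spec()].
#' @return A [titration_series()].
#' @export
gen_titration <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  cc <- sim_complex_conc(spec, rep(spec$donor_conc_M,
                                   length(spec$acceptor_conc_M)),
                         spec$acceptor_conc_M)
  a <- spec$epsilon_c * cc * spec$pathlength_cm
  a <- with_seed(spec$seed, apply_noise(spec, a))
  titration_series(spec$donor_conc_M, spec$acceptor_conc_M, a,
                   lambda_nm = spec$lambda_nm)
}

#' Simulate a Job continuous-variation series
#'
#' Mole fractions equally spaced in (0, 1) at fixed total concentration;
#' absorbance proportional to the equilibrium complex concentration.
#'
#' @param spec a [simulation_spec()].
#' @param n_points number of mole fractions (>= 5).
#' @return A [job_series()].
#' @export
gen_job_series <- function(spec, n_points = 11) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  if (n_points < 5L) stop_input("need at least 5 points")
  x <- seq_len(n_points) / (n_points + 1)
  d0 <- x * spec$total_conc_M
  a0 <- (1 - x) * spec$total_conc_M
  cc <- sim_complex_conc(spec, d0, a0)
  a <- spec$epsilon_c * cc * spec$pathlength_cm
  a <- with_seed(spec$seed, apply_noise(spec, a))
  job_series(x, pmax(a, 0), spec$total_conc_M, lambda_nm = spec$lambda_nm)
}

#' Simulate a calibration line
#'
#' `A = slope * c + intercept + Normal(0, sigma)`, deterministic under the
#' seed.
#'
#' @param slope,intercept line parameters (AU/uM and AU).
#' @param sigma nonnegative residual standard deviation (AU).
#' @param conc_design concentrations in uM.
#' @param seed RNG seed.
#' @return A list with `conc_uM` and `absorbance`.
#' @export
gen_calibration <- function(slope, intercept, sigma, conc_design, seed = 1L) {
  check_number(sigma, "sigma", nonneg = TRUE)
  a <- slope * conc_design + intercept
  if (sigma > 0)
    a <- with_seed(seed, a + stats::rnorm(length(conc_design), 0, sigma))
  list(conc_uM = as.numeric(conc_design), absorbance = a)
}

#' Simulate replicate assay measurements
#'
#' Found concentrations are Normal around `taken * recovery` with relative
#' within-day scatter `rsd_rel` plus a day-level shift `day_rel`.
#'
#' @param taken_uM nominal concentration levels.
#' @param n_rep replicates per level per day.
#' @param n_day assay days.
#' @param rsd_rel within-day relative SD.
#' @param day_rel between-day relative SD.
#' @param recovery true mean recovery fraction.
#' @param seed RNG seed.
#' @return A data frame with `taken_uM`, `found_uM`, `assay_day`.
#' @export
gen_assay_replicates <- function(taken_uM, n_rep = 3, n_day = 3,
                                 rsd_rel = 0.01, day_rel = 0.005,
                                 recovery = 1, seed = 1L) {
  with_seed(seed, {
    out <- lapply(taken_uM, function(tk) {
      days <- lapply(seq_len(n_day), function(d) {
        shift <- stats::rnorm(1, 0, day_rel)
        data.frame(taken_uM = tk,
                   found_uM = tk * recovery * (1 + shift +
                     stats::rnorm(n_rep, 0, rsd_rel)),
                   assay_day = d)
      })
      do.call(rbind, days)
    })
    do.call(rbind, out)
  })
}

#' Toy hydrogen-bonded dimer geometries
#'
#' A water dimer with a linear O-H...O hydrogen bond whose H...O distance is
#' set to `separation_A`; all other internal coordinates are fixed at the
#' standard monomer values (O-H 0.9572 angstrom, H-O-H 104.52 degrees). The
#' two monomers are attached as fragments, enabling intermolecular NCI
#' filtering.
#'
#' @param separation_A H...O distance in angstrom (>= 1.2).
#' @return A [molecular_geometry()] of 6 atoms with a 2-fragment partition.
#' @export
gen_hbond_dimer <- function(separation_A = 1.9) {
  check_number(separation_A, "separation_A", positive = TRUE)
  if (separation_A < 1.2) stop_input("separation must be >= 1.2 angstrom")
  r_oh <- 0.9572
  ang <- 104.52 * pi / 180
  half <- ang / 2
  o_a <- r_oh + separation_A
  coords <- rbind(
    c(0, 0, 0),                                        # donor O
    c(r_oh, 0, 0),                                     # bridging H
    c(r_oh * cos(ang), r_oh * sin(ang), 0),            # donor H
    c(o_a, 0, 0),                                      # acceptor O
    c(o_a + r_oh * cos(half), 0,  r_oh * sin(half)),   # acceptor H
    c(o_a + r_oh * cos(half), 0, -r_oh * sin(half)))   # acceptor H
  molecular_geometry(c("O", "H", "H", "O", "H", "H"), coords,
                     fragments = list(1:3, 4:6))
}

#' Named experiment presets
#'
#' Designs mirroring the study's experimental conditions: `"bh_paper"`
#' (donor 3 uM, acceptor 1-4 uM), `"job_paper"` (total 1e-4 M, 11 mole
#' fractions), `"calibration_ddq"` and `"calibration_cha"` (the two
#' reported calibration lines over their linear ranges).
#'
#' @param name preset name.
#' @return A named list of design parameters.
#' @export
preset_design <- function(name = c("bh_paper", "job_paper",
                                   "calibration_ddq", "calibration_cha")) {
  switch(match.arg(name),
    bh_paper = list(donor_conc_M = 3e-6,
                    acceptor_conc_M = seq(1e-6, 4e-6, length.out = 7),
                    lambda_nm = 487.5),
    job_paper = list(total_conc_M = 1e-4, n_points = 11, lambda_nm = 487.52),
    calibration_ddq = list(slope = 0.002922, intercept = 0.04729,
                           conc_design = c(2.5, 5, 10, 20, 40, 60, 80, 100)),
    calibration_cha = list(slope = 0.001234, intercept = 0.01416,
                           conc_design = c(5, 10, 20, 40, 60, 80, 100)))
}

#' Benesi-Hildebrand parameter-recovery harness
#'
#' Simulates excess-acceptor titrations over a grid of true association
#' constants, noise levels and seeds, fits each with
#' [benesi_hildebrand_fit()], and summarises the relative error of the
#' recovered constant. The excess-acceptor design (donor 1e-6 M, acceptor
#' 1e-4 to 1e-3 M) keeps the linearisation's free-acceptor approximation
#' valid.
#'
#' @param kc_values true constants to scan.
#' @param noise_levels relative noise levels.
#' @param n_seeds seeds per cell.
#' @param epsilon_c true molar absorptivity.
#' @return A data frame with one row per (kc, noise, seed):
#'   `kc_true`, `noise`, `seed`, `kc_fit`, `rel_error`.
#' @export
bh_recovery <- function(kc_values = c(1e3, 1e4, 1e5),
                        noise_levels = c(0, 0.01), n_seeds = 20,
                        epsilon_c = 5e3) {
  grid <- expand.grid(kc_true = kc_values, noise = noise_levels,
                      seed = seq_len(n_seeds))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    spec <- simulation_spec(kc_true = g$kc_true, epsilon_c = epsilon_c,
                            noise_rel = g$noise, seed = g$seed,
                            donor_conc_M = 1e-6,
                            acceptor_conc_M = seq(1e-4, 1e-3,
                                                  length.out = 8))
    fit <- benesi_hildebrand_fit(gen_titration(spec))
    data.frame(kc_true = g$kc_true, noise = g$noise, seed = g$seed,
               kc_fit = fit$kc_L_per_mol,
               rel_error = abs(fit$kc_L_per_mol / g$kc_true - 1))
  })
  do.call(rbind, res)
}
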