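test_that("1:1 equilibrium solver matches the mass-action oracle", {
  expect_equal(solve_equilibrium_1to1(0, 3e-5, 1e6), 0)
  # saturation: huge kc binds the limiting reagent completely
  expect_equal(solve_equilibrium_1to1(1e-5, 3e-5, 1e12), 1e-5,
               tolerance = 1e-6)
  # frozen value from the independent bisection oracle
  expect_equal(solve_equilibrium_1to1(5e-5, 5e-5, 1e6), 4.341128e-05,
               tolerance = 1e-6)

  set.seed(11)
  for (i in 1:25) {
    d0 <- 10^runif(1, -7, -3); a0 <- 10^runif(1, -7, -3)
    kc <- 10^runif(1, 2, 9)
    c_impl <- solve_equilibrium_1to1(d0, a0, kc)
    expect_equal(c_impl, oracle_equilibrium_1to1(d0, a0, kc),
                 tolerance = 1e-8)
    # mass conservation with nonnegative free species
    expect_gte(d0 - c_impl, -1e-20)
    expect_gte(a0 - c_impl, -1e-20)
  }
  expect_error(solve_equilibrium_1to1(-1e-5, 1e-5, 1e4), "nonnegative")
})

test_that("complex concentration is monotone in kc, d0 and a0", {
  kcs <- 10^seq(2, 8, by = 0.5)
  cc <- solve_equilibrium_1to1(rep(5e-5, length(kcs)), 5e-5, 1e4)
  cc_kc <- vapply(kcs, function(k) solve_equilibrium_1to1(5e-5, 5e-5, k),
                  numeric(1))
  expect_true(all(diff(cc_kc) > 0))
  d0s <- seq(1e-6, 1e-4, length.out = 20)
  expect_true(all(diff(solve_equilibrium_1to1(d0s, 5e-5, 1e5)) > 0))
  expect_true(all(diff(solve_equilibrium_1to1(5e-5, d0s, 1e5)) > 0))
})

test_that("m:n numeric solver agrees with the 1:1 closed form and conserves mass", {
  expect_equal(solve_equilibrium_mn(5e-5, 5e-5, 1e6, 1, 1),
               solve_equilibrium_1to1(5e-5, 5e-5, 1e6))
  c12 <- solve_equilibrium_mn(3e-5, 8e-5, 1e9, 1, 2)
  expect_gte(c12, 0)
  expect_lte(c12, min(3e-5, 8e-5 / 2))
  # mass action holds at the root
  expect_equal(1e9 * (3e-5 - c12) * (8e-5 - 2 * c12)^2 / c12, 1,
               tolerance = 1e-6)
})

test_that("Job analysis recovers 1:1 and 1:2 stoichiometry from simulations", {
  spec <- simulation_spec(kc_true = 1e6, epsilon_c = 1e4,
                          total_conc_M = 1e-4, noise_rel = 0)
  ja <- job_analysis(gen_job_series(spec, 11))
  expect_equal(ja$x_max, 0.5, tolerance = 1e-6)
  expect_identical(ja$stoichiometry, "1:1")

  # 1:1 series are symmetric about x = 0.5
  js <- gen_job_series(spec, 11)
  expect_equal(js$absorbance, rev(js$absorbance), tolerance = 1e-9)

  spec12 <- simulation_spec(kc_true = 1e10, epsilon_c = 1e4,
                            stoichiometry = c(1, 2), total_conc_M = 1e-4)
  ja12 <- job_analysis(gen_job_series(spec12, 17))
  expect_identical(ja12$stoichiometry, "1:2")
  expect_lt(abs(ja12$x_max - 1 / 3), 0.03)

  # boundary maximum is degenerate
  bad <- job_series(seq(0.1, 0.9, by = 0.1), seq(0.1, 0.9, by = 0.1), 1e-4)
  expect_error(job_analysis(bad), "boundary|degenerate")
})

test_that("molar-ratio breakpoint recovers the elbow", {
  r <- seq(0.2, 2.0, by = 0.2)
  expect_equal(molar_ratio_breakpoint(r, pmin(r, 1))$ratio_at_break, 1,
               tolerance = 1e-9)

  d0 <- 6e-5
  ratios <- seq(0.25, 3, length.out = 12)
  cc <- solve_equilibrium_1to1(d0, ratios * d0, 1e7)
  br <- molar_ratio_breakpoint(ratios, 1e4 * cc)
  expect_gt(br$ratio_at_break, 0.9)
  expect_lt(br$ratio_at_break, 1.1)

  expect_error(molar_ratio_breakpoint(1:5, 1:5), "at least 6")
  expect_error(molar_ratio_breakpoint(c(1, 2, 2, 3, 4, 5), rep(1, 6)),
               "strictly increasing")
})

test_that("Benesi-Hildebrand fit inverts the 1:1 linearisation", {
  # exact line y = 2e-5 x + 1e-4 -> kc = 5, eps_c = 1e4
  a0 <- seq(1e-4, 1e-3, length.out = 6)
  d0 <- 1e-6
  y <- 2e-5 / a0 + 1e-4        # [D]/A on the exact line
  ts <- titration_series(d0, a0, d0 / y)
  fit <- benesi_hildebrand_fit(ts)
  expect_equal(fit$kc_L_per_mol, 5, tolerance = 1e-9)
  expect_equal(fit$epsilon_c, 1e4, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$kc_L_per_mol, fit$intercept / fit$slope)
  expect_equal(fit$epsilon_c, 1 / fit$intercept)

  # oracle-simulated excess-acceptor series recovers kc within 2%
  spec <- simulation_spec(kc_true = 1e4, epsilon_c = 5e3, noise_rel = 0,
                          donor_conc_M = 1e-6,
                          acceptor_conc_M = seq(1e-4, 1e-3, length.out = 8))
  f2 <- benesi_hildebrand_fit(gen_titration(spec))
  expect_lt(abs(f2$kc_L_per_mol / 1e4 - 1), 0.02)

  expect_error(benesi_hildebrand_fit(
    titration_series(1e-6, a0, c(-1, 1, 1, 1, 1, 1))), "positive")
  # decreasing absorbance gives a degenerate (flagged) fit
  expect_warning(fd <- benesi_hildebrand_fit(
    titration_series(1e-6, a0, rev(seq(0.1, 0.6, length.out = 6)))),
    "degenerate")
  expect_true(fd$degenerate)
})

test_that("Gibbs free energy reproduces the reported values and sign law", {
  expect_equal(round(gibbs_free_energy(1.47e12, 298)$delta_g_kcal_per_mol, 2),
               -16.59)
  expect_equal(gibbs_free_energy(1.47e12, 298)$delta_g_kcal_per_mol,
               -16.593, tolerance = 1e-4)
  expect_equal(round(gibbs_free_energy(4.91e10, 298)$delta_g_kcal_per_mol, 2),
               -14.58)
  expect_equal(gibbs_free_energy(1, 298)$delta_g_kcal_per_mol, 0)
  # dG < 0 iff kc > 1; strictly decreasing in kc
  kcs <- 10^seq(-3, 12, by = 1)
  dg <- vapply(kcs, function(k)
    gibbs_free_energy(k, 298)$delta_g_kcal_per_mol, numeric(1))
  expect_true(all(diff(dg) < 0))
  expect_true(all((dg < 0) == (kcs > 1)))
})

test_that("titration and Job CSV round-trip with metadata", {
  spec <- simulation_spec(kc_true = 1e4, epsilon_c = 5e3, noise_rel = 0.01,
                          seed = 3)
  tit <- gen_titration(spec)
  job <- gen_job_series(spec, 9)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(tit, f1)
  write_job_csv(job, f2)
  rt <- read_titration_csv(f1)
  rj <- read_job_csv(f2)
  expect_equal(rt$donor_conc_M, tit$donor_conc_M)
  expect_equal(rt$absorbance, tit$absorbance, tolerance = 1e-9)
  expect_equal(rj$total_conc_M, job$total_conc_M)
  expect_equal(rj$mole_fraction_donor, job$mole_fraction_donor,
               tolerance = 1e-9)
})
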