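test_that("derived critical-point fields follow the defining identities", {
  # O...H contact: V = -3.16e-3, H = +6.84e-4 => G = 3.844e-3
  cp <- derive_cp_fields(rho = 5.15e-3, laplacian = 1.81e-2,
                         g = 3.844e-3, v = -3.16e-3)
  expect_gte(cp$ratio_vg, 0.822)
  expect_lte(cp$ratio_vg, 0.823)
  expect_equal(cp$h, cp$g + cp$v)
  expect_equal(cp$k, -cp$h)

  # Cl...H contact: V = -2.49e-3, H = +1.04e-3 => G = 3.53e-3
  cp2 <- derive_cp_fields(rho = 5.43e-3, laplacian = 1.83e-2,
                          g = 3.53e-3, v = -2.49e-3)
  expect_equal(round(cp2$ratio_vg, 3), 0.705)
  expect_equal(cp2$e_int_kcal, -2.49e-3 / 2 * 627.5095)

  z <- derive_cp_fields(rho = 1e-2, laplacian = 1e-2, g = 1e-3, v = 0)
  expect_equal(z$h, 1e-3)
  expect_equal(z$k, -1e-3)
  expect_equal(z$ratio_vg, 0)
  expect_equal(z$e_int_kcal, 0)

  # g = 0 with v != 0: ratio undefined and flagged
  u <- derive_cp_fields(rho = 1e-2, laplacian = 1e-2, g = 0, v = -1e-3)
  expect_true(is.na(u$ratio_vg))
  expect_false(u$ratio_defined)
})

test_that("virial consistency flags violations and passes printed rows", {
  # O...H row: 1/4 * 1.81e-2 vs 2G + V
  ok <- check_virial_consistency(
    derive_cp_fields(5.15e-3, 1.81e-2, g = 3.844e-3, v = -3.16e-3))
  expect_true(ok$virial_consistent)
  expect_lt(ok$virial_rel_dev, 0.01)

  # second printed row: 1/4 * 3.42e-2 = 8.55e-3 = 2(7.41e-3) - 6.27e-3
  ok2 <- check_virial_consistency(
    derive_cp_fields(9.95e-3, 3.42e-2, g = 7.41e-3, v = -6.27e-3))
  expect_true(ok2$virial_consistent)

  # fabricated violation: flip the sign of v
  bad <- check_virial_consistency(
    derive_cp_fields(5.15e-3, 1.81e-2, g = 3.844e-3, v = 3.16e-3))
  expect_false(bad$virial_consistent)
})

test_that("reference descriptor table classifies and counts as reported", {
  cp <- read_cp_csv(cp_fixture_path())
  expect_equal(nrow(cp), 5)
  # recomputed ratios agree with the printed column at 3 decimals
  expect_equal(round(cp$ratio_vg[cp$cp_id == 163], 3), 0.705)
  expect_false(any(cp$print_mismatch))

  cls <- setNames(cp$strength, cp$cp_id)
  expect_identical(cls[["149"]], "moderate")
  expect_identical(cls[["121"]], "weak")
  expect_identical(cls[["126"]], "moderate")
  expect_identical(cls[["150"]], "weak")
  expect_identical(cls[["163"]], "weak")
  expect_identical(cp$regime[cp$cp_id == 163], "closed_shell")
  expect_identical(cp$regime[cp$cp_id == 149], "intermediate")

  expect_equal(count_hbonds(cp, "LGN-DDQ"), 3)
  expect_equal(count_hbonds(cp, "LGN-CHA"), 2)
  rcp <- cp[1, ]; rcp$kind <- "RCP"   # ring critical points never count
  expect_equal(count_hbonds(rcp), 0)

  # virial self-consistency of the printed rows: four of five hold at 2%;
  # the N-H...O row's printed Laplacian is internally inconsistent with its
  # energy densities and must be flagged, not repaired
  vc <- check_virial_consistency(cp, rel_tol = 0.02)
  expect_equal(sum(vc$virial_consistent), 4)
  expect_false(vc$virial_consistent[vc$cp_id == 126])
  expect_identical(cp$rho, read_cp_csv(cp_fixture_path())$rho)  # no repair
})

test_that("classification is total with deterministic boundaries", {
  grid <- expand.grid(lap = c(-1e-3, 0, 1e-3), h = c(-1e-4, 0, 1e-4))
  cp <- derive_cp_fields(rho = rep(0.01, nrow(grid)), laplacian = grid$lap,
                         g = pmax(1e-4 - grid$h * 0, 1e-4),
                         v = grid$h - 1e-4)
  cl <- classify_hbond(cp)
  expect_false(any(is.na(cl$strength)))
  expect_true(all(cl$strength[cl$h > 0] == "weak"))
  expect_true(all(cl$strength[cl$h == 0] == "weak"))        # boundary branch
  expect_true(all(cl$boundary[cl$h == 0 | cl$laplacian == 0]))
  expect_true(all(cl$strength[cl$h < 0 & cl$laplacian > 0] == "moderate"))
  expect_true(all(cl$strength[cl$h < 0 & cl$laplacian <= 0] == "strong"))

  # Popelier window flag
  pop <- classify_hbond(derive_cp_fields(c(0.001, 0.02, 0.05),
                                         rep(0.01, 3), rep(1e-3, 3),
                                         rep(-5e-4, 3)))
  expect_identical(pop$popelier, c(FALSE, TRUE, FALSE))
})

test_that("counterpoise correction reproduces reported energies and is additive", {
  expect_equal(round(bsse_correct(-75.32, 0.00338)$corrected_kcal, 2), -73.20)
  expect_equal(round(bsse_correct(-77.30, 0.00638)$corrected_kcal, 2), -73.30)
  expect_equal(bsse_correct(-10, 0)$corrected_kcal, -10)

  two_step <- bsse_correct(bsse_correct(-75.32, 0.002)$corrected_kcal, 0.00138)
  one_step <- bsse_correct(-75.32, 0.00338)
  expect_equal(two_step$corrected_kcal, one_step$corrected_kcal,
               tolerance = 1e-12)

  # kcal units bypass the hartree conversion
  expect_equal(bsse_correct(-75.32, 2.121, "kcal")$corrected_kcal,
               -73.199, tolerance = 1e-3)
  expect_error(bsse_correct(-75, -0.001), ">= 0")
})

test_that("cp JSON report carries classes, flags and both energy units", {
  js <- cp_report_json(read_cp_csv(cp_fixture_path()))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed), 5)
  expect_true(all(c("strength", "regime", "virial_consistent",
                    "e_int_au", "e_int_kcal") %in% names(parsed)))
  expect_equal(parsed$e_int_kcal, parsed$e_int_au * 627.5095,
               tolerance = 1e-9)
})
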