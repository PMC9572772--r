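test_that("geometry constructor and XYZ round-trip", {
  g <- gen_hbond_dimer(1.9)
  expect_s3_class(g, "ct_geometry")
  expect_error(molecular_geometry("X", matrix(0, 1, 3)), "unsupported")
  expect_error(molecular_geometry(c("H", "H"),
                                  rbind(c(0, 0, 0), c(0.3, 0, 0))),
               "closer than 0.5")
  tmp <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, tmp, comment = "water dimer")
  rt <- read_xyz(tmp)
  expect_identical(rt$elements, g$elements)
  expect_equal(rt$coords_A, g$coords_A, tolerance = 1e-7)
})

test_that("promolecular density is spherical per atom and additive", {
  h1 <- molecular_geometry("H", matrix(0, 1, 3))
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  rho <- promolecular_at_points(h1, pts)$rho
  expect_lt(max(abs(rho - rho[1])), 1e-12)

  two <- molecular_geometry(c("O", "H"),
                            rbind(c(0, 0, 0), c(2, 0, 0)))
  o1 <- molecular_geometry("O", matrix(c(0, 0, 0), 1))
  hh <- molecular_geometry("H", matrix(c(2, 0, 0), 1))
  p <- rbind(c(0.7, 0.2, -0.4), c(3.1, -1, 0.5), c(1.5, 0, 0))
  expect_equal(promolecular_at_points(two, p)$rho,
               promolecular_at_points(o1, p)$rho +
                 promolecular_at_points(hh, p)$rho, tolerance = 1e-14)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(14)
  geom <- gen_hbond_dimer(1.9)
  b <- ct_constants$bohr_per_angstrom
  lo <- apply(geom$coords_A * b, 2, min) - 3
  hi <- apply(geom$coords_A * b, 2, max) + 3
  n <- 100
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  ev <- promolecular_at_points(geom, pts)
  h <- 1e-4
  fd <- sapply(1:3, function(k) {
    pp <- pts; pp[, k] <- pp[, k] + h
    pm <- pts; pm[, k] <- pm[, k] - h
    (promolecular_at_points(geom, pp)$rho -
       promolecular_at_points(geom, pm)$rho) / (2 * h)
  })
  rel <- sqrt(rowSums((ev$grad - fd)^2)) / sqrt(rowSums(ev$grad^2))
  expect_lt(max(rel), 1e-5)

  # density strictly positive, decaying monotonically beyond 5 A
  ray <- cbind(seq(5, 12, by = 0.5) * b, 0, 0) +
    matrix(rep(geom$coords_A[4, ] * b, 15), ncol = 3, byrow = TRUE)
  rray <- promolecular_at_points(geom, ray)$rho
  expect_true(all(rray > 0))
  expect_true(all(diff(rray) < 0))
})

test_that("closed-form 3x3 eigenvalues agree with LAPACK and sum to the trace", {
  set.seed(3)
  for (i in 1:50) {
    m <- matrix(rnorm(9), 3); s <- (m + t(m)) / 2
    ours <- sym3_eigenvalues(s[1, 1], s[2, 2], s[3, 3],
                             s[1, 2], s[1, 3], s[2, 3])
    ref <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(as.numeric(ours), ref, tolerance = 1e-10)
    expect_equal(sum(ours), sum(diag(s)), tolerance = 1e-8)
  }
  # isotropic case: triple eigenvalue, no NaN
  iso <- sym3_eigenvalues(2, 2, 2, 0, 0, 0)
  expect_equal(as.numeric(iso), c(2, 2, 2))
})

test_that("RDG matches the single-exponential closed form", {
  # rho = exp(-2 r): RDG = (3 pi^2)^(-1/3) * exp(2 r / 3)
  r <- seq(0, 2, by = 0.1)
  rho <- exp(-2 * r)
  gnorm <- 2 * exp(-2 * r)
  s <- compute_rdg(rho, gnorm)
  expect_equal(s[1], (3 * pi^2)^(-1 / 3), tolerance = 1e-12)
  expect_equal(s[1], 0.3233, tolerance = 1e-3)
  expect_equal(s, (3 * pi^2)^(-1 / 3) * exp(2 * r / 3), tolerance = 1e-12)

  # uniform density has zero gradient hence zero RDG
  expect_true(all(compute_rdg(rep(0.3, 10), rep(0, 10)) == 0))
})

test_that("signed density takes the sign of the middle Hessian eigenvalue", {
  # spherical exponential at r = 1: tangential curvatures negative
  h1 <- molecular_geometry("H", matrix(0, 1, 3))
  ev <- promolecular_at_points(h1, matrix(c(1, 0, 0), 1))
  l <- sym3_eigenvalues(ev$hess[, "xx"], ev$hess[, "yy"], ev$hess[, "zz"],
                        ev$hess[, "xy"], ev$hess[, "xz"], ev$hess[, "yz"])
  expect_lt(l[, "l2"], 0)
  sr <- signed_density(list(rho = ev$rho, hess = ev$hess))
  expect_equal(sr, -ev$rho)

  # pair midpoint: degenerate tangential curvatures 2 f'(R)/R < 0, so
  # lambda2 < 0 (bond-path-like saddle) at any separation
  hh <- molecular_geometry(c("H", "H"),
                           rbind(c(0, 0, 0), c(4, 0, 0)))
  b <- ct_constants$bohr_per_angstrom
  evm <- promolecular_at_points(hh, matrix(c(2 * b, 0, 0), 1))
  lm <- sym3_eigenvalues(evm$hess[, "xx"], evm$hess[, "yy"], evm$hess[, "zz"],
                         evm$hess[, "xy"], evm$hess[, "xz"], evm$hess[, "yz"])
  expect_lt(lm[, "l2"], 0)
  expect_equal(signed_density(list(rho = evm$rho, hess = evm$hess)),
               -evm$rho)

  # centre of an H3 ring: two in-plane curvatures positive (density rises
  # toward each atom), so lambda2 > 0 — the steric/nonbonded signature
  side <- 2
  tri <- molecular_geometry(rep("H", 3),
                            rbind(c(0, 0, 0), c(side, 0, 0),
                                  c(side / 2, side * sqrt(3) / 2, 0)))
  centre <- matrix(c(side / 2, side / (2 * sqrt(3)), 0) * b, 1)
  evr <- promolecular_at_points(tri, centre)
  lr <- sym3_eigenvalues(evr$hess[, "xx"], evr$hess[, "yy"], evr$hess[, "zz"],
                         evr$hess[, "xy"], evr$hess[, "xz"], evr$hess[, "yz"])
  expect_gt(lr[, "l2"], 0)
  expect_gt(signed_density(list(rho = evr$rho, hess = evr$hess)), 0)

  # lambda2 = 0 gives signed value 0
  expect_equal(signed_density(list(rho = 0.5,
                                   hess = list(xx = 1, yy = 0, zz = -1,
                                               xy = 0, xz = 0, yz = 0))), 0)
})

test_that("water-dimer field shows the hydrogen-bond trough that vanishes on stretching", {
  # coarse grid keeps this fast; the acceptance suite re-runs at 0.1 bohr
  f19 <- promolecular_field(gen_hbond_dimer(1.9), spacing_bohr = 0.2)
  rf19 <- rdg_field(f19)
  expect_true(all(rf19$rdg >= 0))
  expect_equal(abs(rf19$signed_rho), rf19$rho, tolerance = 1e-12)
  sc19 <- nci_scatter(rf19, rho_cut = 0.05, intermolecular = TRUE)
  expect_true(all(abs(sc19$signed_rho) <= 0.05))
  expect_true(!is.unsorted(sc19$signed_rho))
  tr19 <- nci_trough(sc19)
  expect_true(tr19$trough)

  # low-RDG point on the O...H axis near the bond midpoint
  g <- gen_hbond_dimer(1.9)
  b <- ct_constants$bohr_per_angstrom
  ax <- cbind(seq(0.9572 + 0.5, 0.9572 + 1.4, length.out = 80) * b, 0, 0)
  pv <- promolecular_at_points(g, ax)
  expect_lt(min(compute_rdg(pv$rho, sqrt(rowSums(pv$grad^2)))), 0.6)

  f40 <- promolecular_field(gen_hbond_dimer(4.0), spacing_bohr = 0.2)
  sc40 <- nci_scatter(rdg_field(f40), rho_cut = 0.05, intermolecular = TRUE)
  expect_false(nci_trough(sc40)$trough)

  # filtering requires fragments
  nofrag <- promolecular_field(
    molecular_geometry(c("H", "H"), rbind(c(0, 0, 0), c(4, 0, 0))),
    spacing_bohr = 0.5)
  expect_error(nci_scatter(rdg_field(nofrag), intermolecular = TRUE),
               "fragments")
})

test_that("cube files round-trip and scatter CSV parses", {
  g <- gen_hbond_dimer(1.9)
  f <- promolecular_field(g, spacing_bohr = 0.55, margin_A = 1.0)
  tmp <- withr::local_tempfile(fileext = ".cube")
  export_cube(f$rho, f, tmp)
  rc <- read_cube(tmp)
  expect_identical(as.integer(rc$shape), as.integer(f$shape))
  expect_identical(rc$elements, g$elements)
  expect_lt(max(abs(rc$values - f$rho) / pmax(abs(f$rho), 1e-30)), 1e-6)
  # header geometry in bohr
  expect_equal(rc$coords_bohr, g$coords_A * ct_constants$bohr_per_angstrom,
               tolerance = 1e-5)
  # at most 6 values per line
  body <- readLines(tmp)[-(1:(6 + 6))]
  expect_lte(max(lengths(strsplit(trimws(body), "\\s+"))), 6)

  sc <- nci_scatter(rdg_field(f), rho_cut = 0.05)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_scatter_csv(sc, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("signed_rho", "rdg"))
  expect_true(is.numeric(back$signed_rho) && is.numeric(back$rdg))
})
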