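# Promolecular atomic densities from Slater-rule exponential shells.
#
# Each atom contributes a spherically averaged density built from
# single-zeta Slater-type shells with Slater's-rules exponents:
#   rho_shell(r) = occ * N^2 * r^(2n-2) * exp(-2 zeta r) / (4 pi),
#   N^2 = (2 zeta)^(2n+1) / (2n)!.
# The shell sum is a closed-form function of r, so the gradient and Hessian
# of the promolecular density are accumulated analytically.
# zeta = (Z - s)/n* with Slater screening s; shells grouped as (1s)(2s2p)(3s3p).

slater_shell <- function(n, zeta, occ) {
  list(n = n, zeta = zeta, occ = occ,
       norm2 = (2 * zeta)^(2 * n + 1) / factorial(2 * n))
}

slater_shell_table <- list(
  H  = list(slater_shell(1, 1.0,    1)),
  C  = list(slater_shell(1, 5.70,   2), slater_shell(2, 1.625,  4)),
  N  = list(slater_shell(1, 6.70,   2), slater_shell(2, 1.95,   5)),
  O  = list(slater_shell(1, 7.70,   2), slater_shell(2, 2.275,  6)),
  Cl = list(slater_shell(1, 16.70,  2), slater_shell(2, 6.425,  8),
            slater_shell(3, 2.0333, 7))
)

# radial density f(r) of one element, with first and second derivatives.
# f(r) = sum_j a_j r^(p_j) exp(-alpha_j r), p = 2n-2, alpha = 2 zeta.
atomic_radial <- function(element, r) {
  shells <- slater_shell_table[[element]]
  if (is.null(shells)) stop_input("unsupported element: %s", element)
  f <- fp <- fpp <- 0
  for (s in shells) {
    a <- s$occ * s$norm2 / (4 * pi)
    p <- 2 * s$n - 2
    al <- 2 * s$zeta
    e <- exp(-al * r)
    rp <- if (p == 0) 1 else r^p
    f <- f + a * rp * e
    rpm1 <- if (p == 0) 0 else if (p == 1) 1 else p * r^(p - 1)
    fp <- fp + a * (rpm1 - al * rp) * e
    rpm2 <- if (p < 2) 0 else p * (p - 1) * (if (p == 2) 1 else r^(p - 2))
    fpp <- fpp + a * (rpm2 - 2 * al * rpm1 + al^2 * rp) * e
  }
  list(f = f, fp = fp, fpp = fpp)
}

#' Promolecular density, gradient and Hessian on a regular grid
#'
#' Builds the promolecular electron density (sum of unrelaxed spherical
#' atomic densities) on a regular 3-D grid enclosing the molecule with the
#' requested margin, together with the analytic gradient and Hessian
#' accumulated from the same exponential shells. When the geometry carries a
#' fragment partition, per-fragment densities are stored as well (needed for
#' intermolecular NCI filtering).
#'
#' @param geom a [molecular_geometry()].
#' @param spacing_bohr grid step in bohr (default 0.1).
#' @param margin_A box margin beyond the atoms in angstrom (default 2).
#' @return An object of class `ct_density_grid`: list with `origin_bohr`,
#'   `step_bohr`, `shape`, `rho` (3-D array, a.u.), `grad` (list `gx`, `gy`,
#'   `gz`), `hess` (list `xx`, `yy`, `zz`, `xy`, `xz`, `yz`), optional
#'   `frag_rho`, and `geom`.
#' @export
promolecular_field <- function(geom, spacing_bohr = 0.1, margin_A = 2.0) {
  stopifnot(inherits(geom, "ct_geometry"))
  check_number(spacing_bohr, "spacing_bohr", positive = TRUE)
  check_number(margin_A, "margin_A", nonneg = TRUE)
  b <- ct_constants$bohr_per_angstrom
  coords <- geom$coords_A * b
  margin <- margin_A * b
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing_bohr)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + spacing_bohr * (seq_len(shape[k]) - 1L))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  zero <- array(0, dim = shape)
  rho <- zero
  gx <- zero; gy <- zero; gz <- zero
  hxx <- zero; hyy <- zero; hzz <- zero; hxy <- zero; hxz <- zero; hyz <- zero
  n_frag <- if (is.null(geom$fragments)) 0L else length(geom$fragments)
  frag_rho <- if (n_frag) lapply(seq_len(n_frag), function(i) zero) else NULL
  frag_of <- integer(length(geom$elements))
  if (n_frag) for (i in seq_len(n_frag)) frag_of[geom$fragments[[i]]] <- i
  for (at in seq_along(geom$elements)) {
    dx <- ax[[1]] - coords[at, 1]
    dy <- ax[[2]] - coords[at, 2]
    dz <- ax[[3]] - coords[at, 3]
    DX <- array(dx, dim = shape)
    DY <- array(rep(dy, each = nx), dim = shape)
    DZ <- array(rep(dz, each = nx * ny), dim = shape)
    r <- sqrt(DX^2 + DY^2 + DZ^2)
    r <- pmax(r, 1e-6)               # guard the nuclear cusp
    rad <- atomic_radial(geom$elements[at], r)
    rho <- rho + rad$f
    if (n_frag) {
      i <- frag_of[at]
      frag_rho[[i]] <- frag_rho[[i]] + rad$f
    }
    fp_r <- rad$fp / r
    gx <- gx + fp_r * DX
    gy <- gy + fp_r * DY
    gz <- gz + fp_r * DZ
    cc <- (rad$fpp - fp_r) / r^2     # (f'' - f'/r)/r^2
    hxx <- hxx + cc * DX * DX + fp_r
    hyy <- hyy + cc * DY * DY + fp_r
    hzz <- hzz + cc * DZ * DZ + fp_r
    hxy <- hxy + cc * DX * DY
    hxz <- hxz + cc * DX * DZ
    hyz <- hyz + cc * DY * DZ
  }
  structure(list(origin_bohr = lo, step_bohr = rep(spacing_bohr, 3),
                 shape = shape, axes_bohr = ax, rho = rho,
                 grad = list(gx = gx, gy = gy, gz = gz),
                 hess = list(xx = hxx, yy = hyy, zz = hzz,
                             xy = hxy, xz = hxz, yz = hyz),
                 frag_rho = frag_rho, geom = geom),
            class = "ct_density_grid")
}

#' @export
print.ct_density_grid <- function(x, ...) {
  cat(sprintf("<ct_density_grid> %d x %d x %d points, step %.3g bohr, %d atoms\n",
              x$shape[1], x$shape[2], x$shape[3], x$step_bohr[1],
              length(x$geom$elements)))
  invisible(x)
}

#' Promolecular density at arbitrary points
#'
#' Point-wise evaluation of the same density model as
#' [promolecular_field()], used for finite-difference validation and axis
#' scans.
#'
#' @param geom a [molecular_geometry()].
#' @param points_bohr numeric matrix (n x 3) of evaluation points in bohr.
#' @return A list with `rho` (length n), `grad` (n x 3), `hess` (n x 6,
#'   columns xx, yy, zz, xy, xz, yz) and `laplacian` (length n).
#' @export
promolecular_at_points <- function(geom, points_bohr) {
  stopifnot(inherits(geom, "ct_geometry"))
  pts <- matrix(as.numeric(points_bohr), ncol = 3)
  coords <- geom$coords_A * ct_constants$bohr_per_angstrom
  n <- nrow(pts)
  rho <- numeric(n)
  grad <- matrix(0, n, 3)
  hess <- matrix(0, n, 6,
                 dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
  for (at in seq_along(geom$elements)) {
    d <- sweep(pts, 2, coords[at, ])
    r <- pmax(sqrt(rowSums(d^2)), 1e-6)
    rad <- atomic_radial(geom$elements[at], r)
    rho <- rho + rad$f
    fp_r <- rad$fp / r
    grad <- grad + d * fp_r
    cc <- (rad$fpp - fp_r) / r^2
    hess[, "xx"] <- hess[, "xx"] + cc * d[, 1]^2 + fp_r
    hess[, "yy"] <- hess[, "yy"] + cc * d[, 2]^2 + fp_r
    hess[, "zz"] <- hess[, "zz"] + cc * d[, 3]^2 + fp_r
    hess[, "xy"] <- hess[, "xy"] + cc * d[, 1] * d[, 2]
    hess[, "xz"] <- hess[, "xz"] + cc * d[, 1] * d[, 3]
    hess[, "yz"] <- hess[, "yz"] + cc * d[, 2] * d[, 3]
  }
  list(rho = rho, grad = grad, hess = hess,
       laplacian = hess[, "xx"] + hess[, "yy"] + hess[, "zz"])
}
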