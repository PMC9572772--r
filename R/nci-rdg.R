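#' Reduced density gradient
#'
#' `RDG = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))`, evaluated point-wise.
#' A density floor (default 1e-10 a.u.) is applied before the `rho^(4/3)`
#' division so vacuum regions cannot overflow; floored points carry RDG
#' values that are meaningless and are excluded from scatter output by
#' [nci_scatter()].
#'
#' @param rho density values (any shape).
#' @param grad_norm matching `|grad rho|` values. Alternatively pass a
#'   `ct_density_grid` as `rho` and leave `grad_norm` missing.
#' @param rho_floor density floor in a.u.
#' @return Array of RDG values shaped like the input.
#' @export
compute_rdg <- function(rho, grad_norm = NULL, rho_floor = 1e-10) {
  if (inherits(rho, "ct_density_grid")) {
    field <- rho
    grad_norm <- sqrt(field$grad$gx^2 + field$grad$gy^2 + field$grad$gz^2)
    rho <- field$rho
  }
  if (is.null(grad_norm)) stop_input("grad_norm required")
  if (!identical(dim(rho), dim(grad_norm)) &&
      length(rho) != length(grad_norm))
    stop_input("rho and grad_norm shapes differ")
  cs <- 2 * (3 * pi^2)^(1 / 3)
  grad_norm / (cs * pmax(rho, rho_floor)^(4 / 3))
}

#' Eigenvalues of symmetric 3x3 matrices (closed form, vectorised)
#'
#' Trigonometric solution of the characteristic polynomial; no iteration.
#' Returns eigenvalues sorted ascending, so column 2 is lambda_2. The three
#' values sum to the trace to machine precision.
#'
#' @param xx,yy,zz,xy,xz,yz matrix components (equal-length vectors).
#' @return An n x 3 matrix with columns `l1 <= l2 <= l3`.
#' @export
sym3_eigenvalues <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (xx - q) / safe_p; byy <- (yy - q) / safe_p; bzz <- (zz - q) / safe_p
  bxy <- xy / safe_p; bxz <- xz / safe_p; byz <- yz / safe_p
  detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  l3 <- q + 2 * p * cos(phi)
  l1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1 = pmin(l1, l2, l3),
               l2 = pmax(pmin(l1, l2), pmin(pmax(l1, l2), l3)),
               l3 = pmax(l1, l2, l3))
  out[p == 0, ] <- q[p == 0]   # isotropic case: triple eigenvalue
  out
}

#' Density signed by the middle Hessian eigenvalue
#'
#' `sign(lambda_2) * rho` distinguishes attractive (bonded, lambda_2 < 0)
#' from repulsive (nonbonded, lambda_2 > 0) low-density regions. Exact
#' `lambda_2 = 0` yields 0.
#'
#' @param field a `ct_density_grid` from [promolecular_field()], or a list
#'   with `rho` and `hess` components.
#' @return Array of `sign(lambda_2) * rho`, shaped like `field$rho`.
#' @export
signed_density <- function(field) {
  h <- field$hess
  comp <- function(nm) {
    v <- if (is.list(h)) h[[nm]] else h[, nm]
    as.vector(v)
  }
  ev <- sym3_eigenvalues(comp("xx"), comp("yy"), comp("zz"),
                         comp("xy"), comp("xz"), comp("yz"))
  l2 <- unname(ev[, "l2"])
  scale <- pmax(abs(ev[, "l1"]), abs(ev[, "l3"]))
  l2[abs(l2) <= 1e-12 * scale] <- 0   # exact-zero convention for lambda2
  out <- sign(l2) * as.vector(field$rho)
  if (!is.null(dim(field$rho))) dim(out) <- dim(field$rho)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combined RDG + signed-density field
#'
#' Convenience wrapper computing both NCI scalar fields from a density grid.
#'
#' @param field a `ct_density_grid`.
#' @param rho_floor density floor passed to [compute_rdg()].
#' @return An object of class `ct_rdg_field`: list with `rdg`, `signed_rho`,
#'   `rho`, `rho_floor`, `frag_rho`, grid metadata and `geom`.
#' @export
rdg_field <- function(field, rho_floor = 1e-10) {
  stopifnot(inherits(field, "ct_density_grid"))
  structure(list(rdg = compute_rdg(field, rho_floor = rho_floor),
                 signed_rho = signed_density(field),
                 rho = field$rho, rho_floor = rho_floor,
                 frag_rho = field$frag_rho,
                 origin_bohr = field$origin_bohr,
                 step_bohr = field$step_bohr, shape = field$shape,
                 geom = field$geom),
            class = "ct_rdg_field")
}

#' NCI scatter data
#'
#' Retains grid points with density above the floor and
#' `|sign(lambda_2) rho| <= rho_cut`, sorted by the signed density —
#' the data behind the 2-D NCI plot. With `intermolecular = TRUE` (requires
#' a fragment partition on the geometry) points dominated by a single
#' fragment are dropped: a point is kept only when no fragment contributes
#' more than `frag_threshold` of the total density there, the standard way
#' to isolate intermolecular interactions from intramolecular background.
#'
#' @param rf a [rdg_field()] (or `ct_density_grid`, converted on the fly).
#' @param rho_cut positive density cutoff in a.u. (default 0.05, the usual
#'   NCI axis range).
#' @param intermolecular drop single-fragment-dominated points.
#' @param frag_threshold dominance threshold (default 0.95).
#' @return A data frame with columns `signed_rho` and `rdg`, sorted by
#'   `signed_rho`.
#' @export
nci_scatter <- function(rf, rho_cut = 0.05, intermolecular = FALSE,
                        frag_threshold = 0.95) {
  if (inherits(rf, "ct_density_grid")) rf <- rdg_field(rf)
  stopifnot(inherits(rf, "ct_rdg_field"))
  check_number(rho_cut, "rho_cut", positive = TRUE)
  keep <- as.vector(rf$rho) > rf$rho_floor &
    abs(as.vector(rf$signed_rho)) <= rho_cut
  if (intermolecular) {
    if (is.null(rf$frag_rho) || length(rf$frag_rho) < 2L)
      stop_input("intermolecular filtering needs >= 2 fragments on the geometry")
    dom <- Reduce(pmax, lapply(rf$frag_rho, as.vector))
    keep <- keep & dom <= frag_threshold * as.vector(rf$rho)
  }
  out <- data.frame(signed_rho = as.vector(rf$signed_rho)[keep],
                    rdg = as.vector(rf$rdg)[keep])
  out[order(out$signed_rho), , drop = FALSE]
}

#' Detect the hydrogen-bond trough in NCI scatter data
#'
#' A hydrogen-bond signature is a low-RDG point at negative signed density
#' of hydrogen-bond magnitude. Returns the minimum RDG over scatter points
#' with `signed_rho` in `[-rho_cut, -rho_min]`, and whether that minimum
#' falls below `rdg_max` (trough present).
#'
#' @param scatter a data frame from [nci_scatter()].
#' @param rho_min,rho_cut magnitude window for the signed density (a.u.).
#' @param rdg_max RDG threshold declaring a trough.
#' @return A list with `min_rdg` (Inf when no point is in the window) and
#'   logical `trough`.
#' @export
nci_trough <- function(scatter, rho_min = 0.01, rho_cut = 0.05,
                       rdg_max = 0.5) {
  sel <- scatter$signed_rho <= -rho_min & scatter$signed_rho >= -rho_cut
  min_rdg <- if (any(sel)) min(scatter$rdg[sel]) else Inf
  list(min_rdg = min_rdg, trough = is.finite(min_rdg) && min_rdg < rdg_max)
}

#' Write NCI scatter data as CSV
#'
#' Columns `signed_rho,rdg`.
#'
#' @param scatter data frame from [nci_scatter()].
#' @param path output path.
#' @export
export_scatter_csv <- function(scatter, path) {
  utils::write.csv(scatter[, c("signed_rho", "rdg")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
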