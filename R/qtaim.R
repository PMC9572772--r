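#' Complete the derived fields of QTAIM critical-point descriptors
#'
#' From the density `rho`, its Laplacian, the Lagrangian kinetic energy
#' `G(r)` and the potential energy density `V(r)` (all atomic units), the
#' remaining descriptors follow by definition: the energy density
#' `H = G + V`, `K = -H`, the ratio `|V|/G`, and the interaction energy
#' estimate `E_int = V/2` converted to kcal/mol.
#'
#' All arguments are vectorised; scalars describe one critical point.
#'
#' @param rho positive electron density at the critical point (a.u.).
#' @param laplacian Laplacian of the density (a.u.).
#' @param g nonnegative Lagrangian kinetic energy density G(r) (a.u.).
#' @param v nonpositive potential energy density V(r) (a.u.).
#' @param cp_id,kind,bond_label,distance_A optional identification fields
#'   (`kind` is `"BCP"` or `"RCP"`).
#' @return A data frame of class `ct_cp_table` with columns `cp_id`, `kind`,
#'   `bond_label`, `distance_A`, `rho`, `laplacian`, `g`, `v`, `h`, `k`,
#'   `ratio_vg`, `e_int_kcal`, `ratio_defined`.
#' @examples
#' derive_cp_fields(rho = 5.15e-3, laplacian = 1.81e-2,
#'                  g = 3.844e-3, v = -3.16e-3)
#' @export
derive_cp_fields <- function(rho, laplacian, g, v,
                             cp_id = seq_along(rho), kind = "BCP",
                             bond_label = "", distance_A = NA_real_) {
  if (any(!is.finite(rho)) || any(rho <= 0)) stop_input("rho must be > 0")
  if (any(!is.finite(g)) || any(g < 0)) stop_input("g must be >= 0")
  if (any(!is.finite(v)) || any(!is.finite(laplacian)))
    stop_input("v and laplacian must be finite")
  h <- g + v
  ratio_defined <- g > 0 | v == 0
  ratio <- ifelse(g > 0, abs(v) / g, ifelse(v == 0, 0, NA_real_))
  out <- data.frame(cp_id = cp_id, kind = rep_len(kind, length(rho)),
                    bond_label = rep_len(bond_label, length(rho)),
                    distance_A = rep_len(distance_A, length(rho)),
                    rho = rho, laplacian = laplacian, g = g, v = v,
                    h = h, k = -h, ratio_vg = ratio,
                    e_int_kcal = (v / 2) * ct_constants$hartree_kcal,
                    ratio_defined = ratio_defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_cp_table", "data.frame")
  out
}

#' Local virial self-consistency of critical-point rows
#'
#' In atomic units the local virial theorem ties the descriptors together:
#' `(1/4) laplacian = 2 G + V`. Rows whose printed values violate this
#' beyond `rel_tol` (relative to `|laplacian/4|`, floored at `eps`) are
#' flagged — and reported, never repaired.
#'
#' @param cp a `ct_cp_table` (see [derive_cp_fields()] / [read_cp_csv()]).
#' @param rel_tol relative tolerance; the default 0.02 corresponds to about
#'   2 units in the last digit of 3-significant-figure tables.
#' @param eps denominator floor.
#' @return `cp` with added columns `virial_rel_dev` and `virial_consistent`.
#' @export
check_virial_consistency <- function(cp, rel_tol = 0.02, eps = 1e-12) {
  stopifnot(is.data.frame(cp))
  need <- c("laplacian", "g", "v")
  if (!all(need %in% names(cp)))
    stop_input("cp table needs columns %s", paste(need, collapse = ","))
  lhs <- cp$laplacian / 4
  rhs <- 2 * cp$g + cp$v
  dev <- abs(lhs - rhs) / pmax(abs(lhs), eps)
  cp$virial_rel_dev <- dev
  cp$virial_consistent <- dev <= rel_tol
  cp
}

#' Rozas classification of hydrogen-bond critical points
#'
#' Strength class from the signs of the Laplacian and the energy density:
#' weak (`laplacian > 0`, `H > 0`), moderate (`laplacian > 0`, `H < 0`),
#' strong (`laplacian < 0`, `H < 0`). Interaction regime from the `|V|/G`
#' ratio: closed-shell (< 1), intermediate (1 to 2), shared (>= 2). The
#' classification is total: `H = 0` falls in the weak (nonnegative-H)
#' branch and `laplacian = 0` is classed by the sign of `H`, both with a
#' boundary flag. Rows with density inside the Popelier range
#' (`[0.002, 0.040]` a.u. by default) are flagged as standard hydrogen
#' bonds.
#'
#' @param cp a `ct_cp_table`.
#' @param popelier_range density window (a.u.) for the standard H-bond flag.
#' @return `cp` with added columns `strength` (weak/moderate/strong),
#'   `regime` (closed_shell/intermediate/shared), `popelier`, `boundary`.
#' @export
classify_hbond <- function(cp, popelier_range = c(0.002, 0.040)) {
  stopifnot(is.data.frame(cp))
  need <- c("rho", "laplacian", "h", "ratio_vg")
  if (!all(need %in% names(cp)))
    stop_input("cp table needs columns %s", paste(need, collapse = ","))
  h <- cp$h; lap <- cp$laplacian; ratio <- cp$ratio_vg
  strength <- ifelse(h >= 0, "weak",
                     ifelse(lap > 0, "moderate", "strong"))
  regime <- ifelse(is.na(ratio), NA_character_,
                   ifelse(ratio < 1, "closed_shell",
                          ifelse(ratio < 2, "intermediate", "shared")))
  cp$strength <- strength
  cp$regime <- regime
  cp$popelier <- cp$rho >= popelier_range[1] & cp$rho <= popelier_range[2]
  cp$boundary <- h == 0 | lap == 0
  cp
}

#' Count hydrogen bonds in a critical-point table
#'
#' A hydrogen bond is a bond critical point with positive Laplacian
#' classified weak or moderate (closed-shell side of the Rozas scheme).
#'
#' @param cp a `ct_cp_table`; classified columns are added if absent.
#' @param complex_id optional value of the `complex` column to restrict to.
#' @return Integer count.
#' @export
count_hbonds <- function(cp, complex_id = NULL) {
  stopifnot(is.data.frame(cp), nrow(cp) >= 1L)
  if (!"strength" %in% names(cp)) cp <- classify_hbond(cp)
  if (!is.null(complex_id)) {
    if (!"complex" %in% names(cp)) stop_input("no `complex` column to filter")
    cp <- cp[cp$complex == complex_id, , drop = FALSE]
  }
  kind <- if ("kind" %in% names(cp)) cp$kind else "BCP"
  sum(kind == "BCP" & cp$laplacian > 0 &
        cp$strength %in% c("weak", "moderate"))
}

#' Counterpoise (BSSE) correction of an interaction energy
#'
#' The corrected supermolecular interaction energy is the raw energy plus
#' the basis-set superposition error. BSSE magnitudes are conventionally
#' tabulated in hartree while the energies are in kcal/mol; the default
#' therefore converts at 627.5095 kcal/mol per hartree. Pass
#' `bsse_units = "kcal"` if the correction is already in kcal/mol. The
#' correction is additive: two successive corrections equal their sum.
#'
#' @param raw_kcal raw interaction energy (kcal/mol).
#' @param bsse nonnegative BSSE correction.
#' @param bsse_units `"hartree"` (default) or `"kcal"`.
#' @return An object of class `ct_interaction_energy`: list with
#'   `raw_kcal`, `bsse_hartree`, `corrected_kcal`.
#' @examples
#' bsse_correct(-75.32, 0.00338)  # -73.20 kcal/mol
#' @export
bsse_correct <- function(raw_kcal, bsse, bsse_units = c("hartree", "kcal")) {
  check_number(raw_kcal, "raw_kcal")
  check_number(bsse, "bsse", nonneg = TRUE)
  bsse_units <- match.arg(bsse_units)
  bsse_hartree <- if (bsse_units == "hartree") bsse
                  else bsse / ct_constants$hartree_kcal
  structure(list(raw_kcal = raw_kcal, bsse_hartree = bsse_hartree,
                 corrected_kcal = raw_kcal +
                   bsse_hartree * ct_constants$hartree_kcal),
            class = "ct_interaction_energy")
}

#' @export
print.ct_interaction_energy <- function(x, ...) {
  cat(sprintf("<interaction energy> raw %.2f + BSSE %.5f Eh -> %.2f kcal/mol\n",
              x$raw_kcal, x$bsse_hartree, x$corrected_kcal))
  invisible(x)
}

#' Read a critical-point descriptor CSV
#'
#' Expected columns (a subset may be missing):
#' `cp_id,kind,bond_label,distance_A,rho,k,v,h,laplacian,ratio_vg`, plus an
#' optional leading `complex` column. `G` is recovered as `h - v`, derived
#' columns (`h`, `k`, `ratio_vg`, `e_int_kcal`) are recomputed from the
#' definitions, and any printed value deviating from its recomputed
#' counterpart by more than `print_tol` (2 units in the last printed digit
#' of 3-significant-figure tables, i.e. 0.002 on the ratio, 2 relative
#' ulps elsewhere) is flagged in `print_mismatch` — never overwritten.
#'
#' @param path CSV path.
#' @param print_tol tolerance on the ratio comparison.
#' @return A classified `ct_cp_table` including `complex` (if present) and
#'   `print_mismatch`.
#' @export
read_cp_csv <- function(path, print_tol = 0.002) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("rho", "v", "laplacian") %in% names(df)))
    stop_input("cp CSV needs at least rho, v, laplacian columns")
  if (is.null(df$h)) {
    if (is.null(df$k)) stop_input("cp CSV needs an h or k column")
    df$h <- -df$k
  }
  g <- df$h - df$v
  if (any(g < 0)) warning("negative recovered G(r): check input signs")
  out <- derive_cp_fields(df$rho, df$laplacian, g = pmax(g, 0), v = df$v,
                          cp_id = if (is.null(df$cp_id)) seq_len(nrow(df))
                                  else df$cp_id,
                          kind = if (is.null(df$kind)) "BCP" else df$kind,
                          bond_label = if (is.null(df$bond_label)) ""
                                       else df$bond_label,
                          distance_A = if (is.null(df$distance_A)) NA_real_
                                       else df$distance_A)
  if (!is.null(df$complex)) out <- cbind(complex = df$complex, out)
  mismatch <- rep(FALSE, nrow(out))
  if (!is.null(df$ratio_vg))
    mismatch <- mismatch | abs(df$ratio_vg - out$ratio_vg) > print_tol
  if (!is.null(df$k))
    mismatch <- mismatch | abs(df$k - out$k) > 2 * abs(out$k) * 0.01
  out$print_mismatch <- mismatch
  class(out) <- c("ct_cp_table", "data.frame")
  classify_hbond(out)
}

#' Serialise a classified critical-point table to JSON
#'
#' Per-row class, flags, and the interaction-energy estimate in both a.u.
#' and kcal/mol.
#'
#' @param cp a classified `ct_cp_table`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
cp_report_json <- function(cp, path = NULL) {
  stopifnot(is.data.frame(cp))
  if (!"strength" %in% names(cp)) cp <- classify_hbond(cp)
  cp <- check_virial_consistency(cp)
  cp$e_int_au <- cp$v / 2
  js <- jsonlite::toJSON(cp, dataframe = "rows", digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
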