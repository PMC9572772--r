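#' Molecular geometry for the promolecular density engine
#'
#' Coordinates are held in angstrom; all density math runs in bohr.
#' Supported elements are H, C, N, O and Cl. An optional fragment
#' partition (list of atom-index vectors) enables intermolecular filtering
#' of NCI scatter data.
#'
#' @param elements character vector of element symbols.
#' @param coords_A numeric matrix (n x 3) of coordinates in angstrom.
#' @param fragments optional list of integer vectors partitioning the atoms.
#' @return An object of class `ct_geometry`.
#' @export
molecular_geometry <- function(elements, coords_A, fragments = NULL) {
  elements <- as.character(elements)
  coords_A <- matrix(as.numeric(coords_A), ncol = 3)
  if (nrow(coords_A) != length(elements))
    stop_input("elements and coordinates must have equal length")
  bad <- setdiff(unique(elements), names(slater_shell_table))
  if (length(bad))
    stop_input("unsupported element(s): %s", paste(bad, collapse = ", "))
  if (nrow(coords_A) >= 2L) {
    d <- as.matrix(stats::dist(coords_A))
    diag(d) <- Inf
    if (min(d) < 0.5)
      stop_input("atoms closer than 0.5 angstrom (min %.3f)", min(d))
  }
  if (!is.null(fragments)) {
    idx <- sort(unlist(fragments))
    if (!identical(idx, seq_along(elements)))
      stop_input("fragments must partition the atom indices")
  }
  structure(list(elements = elements, coords_A = coords_A,
                 fragments = fragments),
            class = "ct_geometry")
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("<ct_geometry> %d atoms (%s)%s\n", length(x$elements),
              paste(sort(unique(x$elements)), collapse = ","),
              if (!is.null(x$fragments))
                sprintf(", %d fragments", length(x$fragments)) else ""))
  invisible(x)
}

element_z <- c(H = 1, C = 6, N = 7, O = 8, Cl = 17)

#' Read and write XYZ geometry files
#'
#' Standard XYZ: atom count, comment line, then `element x y z` in angstrom.
#'
#' @param path file path.
#' @param fragments optional fragment partition attached to the geometry.
#' @return `read_xyz` returns a [molecular_geometry()].
#' @export
read_xyz <- function(path, fragments = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2L)
    stop_input("malformed XYZ file: %s", path)
  rows <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  el <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecular_geometry(el, xyz, fragments = fragments)
}

#' @rdname read_xyz
#' @param geom a [molecular_geometry()].
#' @param comment comment line content.
#' @export
write_xyz <- function(geom, path, comment = "") {
  stopifnot(inherits(geom, "ct_geometry"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(length(geom$elements)), comment), con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", geom$elements,
                     geom$coords_A[, 1], geom$coords_A[, 2],
                     geom$coords_A[, 3]), con)
  invisible(path)
}
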