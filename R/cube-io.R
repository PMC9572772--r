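#' Write a scalar grid as a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and grid origin
#' (bohr); three axis records (steps and voxel vector); one record per atom
#' (atomic number, charge, coordinates in bohr); then values in scientific
#' notation, at most six per line, with the last (z) axis varying fastest.
#'
#' @param values 3-D array of grid values matching `field$shape`.
#' @param field a `ct_density_grid` or `ct_rdg_field` carrying grid metadata
#'   and the geometry.
#' @param path output path.
#' @param comment first comment line.
#' @return `path`, invisibly.
#' @export
export_cube <- function(values, field, path, comment = "ctclab grid") {
  shape <- field$shape
  if (!identical(as.integer(dim(values)), as.integer(shape)))
    stop_input("values shape does not match the grid")
  if (any(!is.finite(values))) stop_input("values must be finite")
  geom <- field$geom
  b <- ct_constants$bohr_per_angstrom
  coords <- geom$coords_A * b
  z <- element_z[geom$elements]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(comment, "scalar field on a regular grid (bohr, a.u.)"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", length(geom$elements),
                     field$origin_bohr[1], field$origin_bohr[2],
                     field$origin_bohr[3]), con)
  step <- field$step_bohr
  writeLines(c(sprintf("%5d %11.6f %11.6f %11.6f", shape[1], step[1], 0, 0),
               sprintf("%5d %11.6f %11.6f %11.6f", shape[2], 0, step[2], 0),
               sprintf("%5d %11.6f %11.6f %11.6f", shape[3], 0, 0, step[3])),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, z,
                     coords[, 1], coords[, 2], coords[, 3]), con)
  # x slowest, z fastest: aperm so the flattened order is z-fastest per (x,y)
  v <- aperm(values, c(3, 2, 1))
  for (ix in seq_len(shape[1])) for (iy in seq_len(shape[2])) {
    col <- v[, iy, ix]
    idx <- seq(1, length(col), by = 6)
    writeLines(vapply(idx, function(i)
      paste(sprintf("%15.7E", col[i:min(i + 5, length(col))]),
            collapse = ""), ""), con)
  }
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @return A list with `origin_bohr`, `step_bohr`, `shape`, `values` (3-D
#'   array), `elements`, `coords_bohr`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms <- as.integer(hdr[1])
  origin <- hdr[2:4]
  ax <- t(vapply(lines[4:6], num, numeric(4)))
  shape <- as.integer(ax[, 1])
  step <- c(ax[1, 2], ax[2, 3], ax[3, 4])
  at <- unname(t(vapply(lines[7:(6 + natoms)], num, numeric(5))))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natoms))]), "\\s+")))
  if (length(vals) != prod(shape))
    stop_input("cube value count %d does not match shape", length(vals))
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  zsym <- names(element_z)[match(as.integer(at[, 1]), element_z)]
  list(origin_bohr = origin, step_bohr = step, shape = shape, values = arr,
       elements = zsym, coords_bohr = at[, 3:5, drop = FALSE])
}
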