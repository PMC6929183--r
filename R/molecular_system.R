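#' Molecular system with Cartesian Hessian
#'
#' Container for the raw material of a vibrational analysis: atom labels,
#' Cartesian coordinates (Angstrom), per-atom masses (amu) and the full
#' symmetric Cartesian Hessian in hartree/bohr^2 (the convention of quantum
#' chemistry outputs). Linearity is detected from the geometry unless given,
#' and controls how many rotational modes are projected out.
#'
#' @param labels Character vector of element labels (e.g. "C", "H", "O", "Cl").
#' @param coords Numeric N x 3 matrix of coordinates in Angstrom.
#' @param masses Numeric vector of N atomic masses in amu, all > 0.
#' @param hessian Numeric 3N x 3N symmetric matrix, hartree/bohr^2, ordered
#'   (x1, y1, z1, x2, ...).
#' @param linear Logical or NULL; NULL means detect collinearity from
#'   `coords`.
#' @return Object of class `molecular_system`.
#' @export
molecular_system <- function(labels, coords, masses, hessian, linear = NULL) {
  coords <- as.matrix(coords)
  n <- length(labels)
  if (n < 1L) stop_input("at least one atom required")
  if (!is.numeric(masses) || length(masses) != n || any(masses <= 0)) {
    stop_input("`masses` must be ", n, " positive numbers")
  }
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop_input("`coords` must be an N x 3 matrix matching `labels`")
  }
  hessian <- as.matrix(hessian)
  if (nrow(hessian) != 3L * n || ncol(hessian) != 3L * n) {
    stop_input("`hessian` must be 3N x 3N with N = ", n)
  }
  scale <- max(abs(hessian), 1e-300)
  if (max(abs(hessian - t(hessian))) / scale > 1e-8) {
    stop_input("`hessian` is not symmetric (relative asymmetry > 1e-8)")
  }
  hessian <- (hessian + t(hessian)) / 2
  if (is.null(linear)) linear <- .is_collinear(coords)
  structure(
    list(labels = as.character(labels), coords = unname(coords),
         masses = unname(as.numeric(masses)), hessian = unname(hessian),
         linear = isTRUE(linear)),
    class = "molecular_system")
}

.is_collinear <- function(coords) {
  if (nrow(coords) <= 2L) return(TRUE)
  cen <- sweep(coords, 2L, colMeans(coords))
  d <- svd(cen, nu = 0L, nv = 0L)$d
  d[2] < 1e-8 * max(d[1], 1e-12)
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %d atoms (%s)%s\n",
              length(x$labels), paste(x$labels, collapse = "-"),
              if (x$linear) ", linear" else ""))
  invisible(x)
}

#' Write a molecular system as extended XYZ plus Hessian block
#'
#' Plain-text dialect: an XYZ header (atom count, comment line carrying the
#' linearity flag and units), one `label x y z mass` row per atom, then a
#' line `HESSIAN` followed by the row-major lower triangle of the Cartesian
#' Hessian, one Hessian row per line.
#'
#' @param sys A `molecular_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_hessian <- function(sys, path) {
  stopifnot(inherits(sys, "molecular_system"))
  n <- length(sys$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf(
    "units=angstrom,amu,hartree_bohr2 linear=%s",
    if (sys$linear) "true" else "false"), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("%-3s %18.12f %18.12f %18.12f %14.9f",
                       sys$labels[i], sys$coords[i, 1], sys$coords[i, 2],
                       sys$coords[i, 3], sys$masses[i]), con)
  }
  writeLines("HESSIAN", con)
  for (i in seq_len(3L * n)) {
    writeLines(paste(sprintf("%.15e", sys$hessian[i, seq_len(i)]),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a molecular system from the extended XYZ + Hessian dialect
#'
#' @param path File written by [write_xyz_hessian()].
#' @return A `molecular_system`.
#' @export
read_xyz_hessian <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1L) stop_input("malformed XYZ header in ", path)
  linear <- grepl("linear=true", lines[2], fixed = TRUE)
  atoms <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  labels <- vapply(atoms, `[[`, character(1), 1L)
  num <- t(vapply(atoms, function(a) as.numeric(a[2:5]), numeric(4)))
  if (trimws(lines[3 + n]) != "HESSIAN") {
    stop_input("missing HESSIAN block in ", path)
  }
  m <- 3L * n
  hess <- matrix(0, m, m)
  for (i in seq_len(m)) {
    row <- as.numeric(strsplit(trimws(lines[3 + n + i]), "\\s+")[[1]])
    if (length(row) != i) stop_input("Hessian row ", i, " has wrong length")
    hess[i, seq_len(i)] <- row
    hess[seq_len(i), i] <- row
  }
  molecular_system(labels, num[, 1:3, drop = FALSE], num[, 4], hess,
                   linear = linear)
}
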