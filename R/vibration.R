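# Normal-mode analysis from Cartesian Hessians: mass weighting, Eckart-frame
# rigid-body projection, eigendecomposition, wavenumber conversion.

#' Frequency set of one isotopolog
#'
#' @param real Ascending real-mode wavenumbers (cm^-1), all > 0.
#' @param imaginary Magnitude of the single imaginary wavenumber (cm^-1) for
#'   a first-order saddle, or NULL for a minimum.
#' @param n_dropped Number of projected/near-zero modes excluded.
#' @return Object of class `frequency_set`.
#' @export
frequency_set <- function(real, imaginary = NULL, n_dropped = 0L) {
  real <- sort(as.numeric(real))
  if (any(real <= 0)) stop_input("real wavenumbers must be positive")
  if (!is.null(imaginary)) {
    if (length(imaginary) != 1L || imaginary <= 0) {
      stop_input("`imaginary` must be a single positive magnitude or NULL")
    }
  }
  structure(list(real = real, imaginary = imaginary,
                 n_dropped = as.integer(n_dropped)),
            class = "frequency_set")
}

#' @export
print.frequency_set <- function(x, ...) {
  cat(sprintf("<frequency_set> %d real mode(s)%s; %d projected/dropped\n",
              length(x$real),
              if (is.null(x$imaginary)) ""
              else sprintf(", 1 imaginary (%.1fi cm^-1)", x$imaginary),
              x$n_dropped))
  if (length(x$real)) cat("  real:", paste(sprintf("%.1f", x$real),
                                           collapse = ", "), "cm^-1\n")
  invisible(x)
}

# Orthonormal basis of rigid-body (translation + rotation) directions in
# mass-weighted coordinates; rank-deficient for linear molecules.
.rigid_body_basis <- function(coords, masses) {
  n <- nrow(coords)
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2L, com)
  sm <- sqrt(masses)
  v <- matrix(0, 3L * n, 6L)
  for (a in 1:3) v[seq(a, 3L * n, by = 3L), a] <- sm
  # rotation generators: sqrt(m_i) * (e_a x r_i)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    ri <- r[i, ]
    v[rows, 4] <- sm[i] * c(0, -ri[3], ri[2])
    v[rows, 5] <- sm[i] * c(ri[3], 0, -ri[1])
    v[rows, 6] <- sm[i] * c(-ri[2], ri[1], 0)
  }
  s <- svd(v)
  keep <- s$d > 1e-8 * max(s$d)
  s$u[, keep, drop = FALSE]
}

#' Harmonic frequencies from a Cartesian Hessian
#'
#' Mass-weights the Hessian, projects out rigid-body translations and
#' rotations in the Eckart frame (three translations plus two or three
#' rotations according to linearity), diagonalizes, and converts eigenvalues
#' in hartree/(bohr^2 amu) to wavenumbers. Modes with |wavenumber| below
#' 1 cm^-1 after projection are dropped and counted. A single negative
#' eigenvalue becomes the imaginary mode of a first-order saddle; two or
#' more raise an error.
#'
#' @param sys A [molecular_system()].
#' @param masses Optional mass vector overriding `sys$masses` (used for
#'   isotopolog analyses on the same Hessian).
#' @return A [frequency_set()].
#' @export
frequencies_from_hessian <- function(sys, masses = NULL) {
  stopifnot(inherits(sys, "molecular_system"))
  m <- masses %||% sys$masses
  if (length(m) != length(sys$masses) || any(m <= 0)) {
    stop_input("`masses` must be positive and match the atom count")
  }
  m3 <- rep(m, each = 3L)
  hmw <- sys$hessian / sqrt(outer(m3, m3))
  u <- .rigid_body_basis(sys$coords, m)
  p <- diag(length(m3)) - tcrossprod(u)
  hp <- p %*% hmw %*% p
  hp <- (hp + t(hp)) / 2
  lam <- eigen(hp, symmetric = TRUE, only.values = TRUE)$values
  conv <- phys_constants()$hessian_to_wavenumber
  nu <- sign(lam) * conv * sqrt(abs(lam))
  keep <- abs(nu) >= 1
  n_dropped <- sum(!keep)
  neg <- sort(nu[keep & nu < 0])
  pos <- sort(nu[keep & nu > 0])
  if (length(neg) >= 2L) {
    stop_input("higher-order saddle: ", length(neg),
               " imaginary modes after projection")
  }
  frequency_set(pos,
                imaginary = if (length(neg)) abs(neg[1]) else NULL,
                n_dropped = n_dropped)
}

#' Isotopic substitution at one atomic position
#'
#' @param index Atom index (1-based) of the substituted position.
#' @param element One of "C", "Cl", "H"; must match the atom's label.
#' @param light,heavy Masses in amu; defaults are 12C/13C, 35Cl/37Cl, 1H/2H.
#' @return Object of class `isotope_substitution`.
#' @export
isotope_substitution <- function(index, element = c("C", "Cl", "H"),
                                 light = NULL, heavy = NULL) {
  element <- match.arg(element)
  def <- switch(element,
                C  = c(12.0000000, 13.0033548),
                Cl = c(34.9688527, 36.9659026),
                H  = c(1.00782503, 2.01410178))
  light <- light %||% def[1]
  heavy <- heavy %||% def[2]
  if (!(heavy > light && light > 0)) {
    stop_input("need heavy mass > light mass > 0")
  }
  if (!is_count(index)) stop_input("`index` must be a positive integer")
  structure(list(index = as.integer(index), element = element,
                 light = light, heavy = heavy),
            class = "isotope_substitution")
}

#' Light and heavy frequency sets for one substitution
#'
#' Runs the identical projection and diagonalization on the same Hessian
#' with the light and heavy mass vectors; modes are matched downstream by
#' ascending order, which is safe for the symmetry-free toy systems shipped
#' here (a warning is attached when adjacent modes lie within 1 cm^-1, where
#' order-matching can cross).
#'
#' @param sys A [molecular_system()].
#' @param sub An [isotope_substitution()]; the atom label at `sub$index`
#'   must equal `sub$element`.
#' @return List with `frequency_set` components `light` and `heavy`.
#' @export
isotopolog_frequency_sets <- function(sys, sub) {
  stopifnot(inherits(sys, "molecular_system"),
            inherits(sub, "isotope_substitution"))
  if (sub$index > length(sys$labels)) stop_input("atom index out of range")
  if (sys$labels[sub$index] != sub$element) {
    stop_input("substitution element '", sub$element,
               "' does not match atom label '", sys$labels[sub$index], "'")
  }
  ml <- sys$masses; ml[sub$index] <- sub$light
  mh <- sys$masses; mh[sub$index] <- sub$heavy
  list(light = frequencies_from_hessian(sys, masses = ml),
       heavy = frequencies_from_hessian(sys, masses = mh))
}
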