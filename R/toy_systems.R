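# Toy molecular species with exact analytic Cartesian Hessians.
#
# Potentials are quadratic forms in rotation/translation-invariant internal
# coordinates (bond stretches and degenerate linear bends), so the Cartesian
# Hessian H = B' F B has exactly zero rigid-body eigenvalues and the internal
# spectrum follows in closed form -- the property the frequency-analysis
# oracles rely on.

#' Specification of a toy molecular system
#'
#' Three kinds are supported. `diatomic`: two atoms, one harmonic stretch.
#' `collinear-transfer`: a collinear A-B-C system (e.g. C-H...O) with two
#' stretches, an optional stretch-stretch coupling and degenerate linear
#' bends; the transition-state force field must carry exactly one negative
#' curvature along the light-atom transfer coordinate. `block-composite`:
#' two uncoupled diatomics, whose Hessian is block-diagonal and whose
#' spectrum is the union of the fragments'.
#'
#' @param kind One of "diatomic", "collinear-transfer", "block-composite".
#' @param masses Atomic masses in amu (2, 3 or 4 values by kind).
#' @param distances Internuclear distances in Angstrom (1 or 2 values).
#' @param k_bonds Harmonic stretch constants, hartree/bohr^2 (reactant/minimum
#'   force field).
#' @param k_couple Stretch-stretch coupling constant for the minimum force
#'   field (hartree/bohr^2, collinear-transfer only).
#' @param k_bend Linear-bend force constant in hartree/rad^2
#'   (collinear-transfer only).
#' @param ts_k_bonds,ts_k_couple Transition-state stretch constants and
#'   coupling (collinear-transfer only); the 2 x 2 stretch block must have
#'   exactly one negative eigenvalue.
#' @param ts_k_bend Transition-state linear-bend constant (defaults to
#'   `k_bend`; transfer transition states typically stiffen the bend).
#' @return Object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(kind = c("diatomic", "collinear-transfer",
                                     "block-composite"),
                            masses, distances, k_bonds, k_couple = 0,
                            k_bend = 0.02, ts_k_bonds = NULL,
                            ts_k_couple = NULL, ts_k_bend = NULL) {
  kind <- match.arg(kind)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop_input("all masses must be positive")
  }
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    stop_input("all distances must be positive")
  }
  need <- switch(kind,
                 "diatomic" = c(2L, 1L, 1L),
                 "collinear-transfer" = c(3L, 2L, 2L),
                 "block-composite" = c(4L, 2L, 2L))
  if (length(masses) != need[1] || length(distances) != need[2] ||
      length(k_bonds) != need[3]) {
    stop_input(sprintf(
      "kind '%s' needs %d masses, %d distances, %d bond constants",
      kind, need[1], need[2], need[3]))
  }
  if (kind != "collinear-transfer") {
    if (!is.null(ts_k_bonds) || !is.null(ts_k_couple) ||
        !is.null(ts_k_bend)) {
      stop_input("transition-state force constants are only meaningful for ",
                 "kind = 'collinear-transfer'")
    }
    if (any(k_bonds < 0)) {
      stop_input("negative curvature requested for a minimum kind; ",
                 "only 'collinear-transfer' admits one negative curvature")
    }
  }
  structure(
    list(kind = kind, masses = as.numeric(masses),
         distances = as.numeric(distances), k_bonds = as.numeric(k_bonds),
         k_couple = k_couple, k_bend = k_bend,
         ts_k_bonds = ts_k_bonds, ts_k_couple = ts_k_couple,
         ts_k_bend = ts_k_bend),
    class = "toy_system_spec")
}

# B-matrix row of a bond stretch (coordinates in bohr).
.stretch_row <- function(coords_bohr, i, j) {
  n <- nrow(coords_bohr)
  u <- coords_bohr[j, ] - coords_bohr[i, ]
  u <- u / sqrt(sum(u^2))
  row <- numeric(3L * n)
  row[(3 * i - 2):(3 * i)] <- -u
  row[(3 * j - 2):(3 * j)] <- u
  row
}

# Two degenerate linear-bend rows for collinear a-b-c (angle deviation from
# pi in each plane containing the axis); exactly invariant under rigid
# translations and rotations of the reference geometry.
.linear_bend_rows <- function(coords_bohr, a, b, c) {
  n <- nrow(coords_bohr)
  axis <- coords_bohr[c, ] - coords_bohr[a, ]
  axis <- axis / sqrt(sum(axis^2))
  perp <- diag(3) - tcrossprod(axis)
  e1 <- perp %*% c(1, 0, 0)
  if (sum(e1^2) < 1e-8) e1 <- perp %*% c(0, 1, 0)
  e1 <- as.numeric(e1 / sqrt(sum(e1^2)))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  r1 <- sqrt(sum((coords_bohr[b, ] - coords_bohr[a, ])^2))
  r2 <- sqrt(sum((coords_bohr[c, ] - coords_bohr[b, ])^2))
  mk <- function(e) {
    row <- numeric(3L * n)
    row[(3 * a - 2):(3 * a)] <- e / r1
    row[(3 * b - 2):(3 * b)] <- -e * (1 / r1 + 1 / r2)
    row[(3 * c - 2):(3 * c)] <- e / r2
    row
  }
  rbind(mk(e1), mk(e2))
}

# Assemble H = B' F B (hartree/bohr^2) from stretch/bend internals.
.assemble_hessian <- function(coords_ang, stretches, k_stretch, f_couple,
                              bends = NULL, k_bend = 0) {
  bohr <- phys_constants()$base$bohr
  xb <- coords_ang / bohr
  brows <- lapply(stretches, function(ij) .stretch_row(xb, ij[1], ij[2]))
  B <- do.call(rbind, brows)
  ns <- length(stretches)
  f <- matrix(0, ns, ns)
  diag(f) <- k_stretch
  if (!is.null(f_couple)) f <- f + f_couple
  if (!is.null(bends)) {
    for (bd in bends) {
      B <- rbind(B, .linear_bend_rows(xb, bd[1], bd[2], bd[3]))
    }
    nb <- 2L * length(bends)
    f <- rbind(cbind(f, matrix(0, ns, nb)),
               cbind(matrix(0, nb, ns), diag(k_bend, nb)))
  }
  t(B) %*% f %*% B
}

.collinear_geometry <- function(distances) {
  rbind(c(0, 0, 0), c(0, 0, distances[1]),
        c(0, 0, distances[1] + distances[2]))
}

#' Build a toy species (a minimum) from a specification
#'
#' For `diatomic` and `block-composite` kinds returns the species directly;
#' for `collinear-transfer` returns the reactant minimum (use
#' [make_toy_reaction()] for the reactant/transition-state pair).
#'
#' @param spec A [toy_system_spec()].
#' @param labels Optional element labels overriding the defaults.
#' @return A [molecular_system()] whose Hessian is exact and positive
#'   semidefinite apart from rigid-body (and, for the composite,
#'   inter-fragment) zero modes.
#' @export
make_toy_species <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "toy_system_spec"))
  if (spec$kind == "diatomic") {
    co <- rbind(c(0, 0, 0), c(0, 0, spec$distances[1]))
    h <- .assemble_hessian(co, list(c(1L, 2L)), spec$k_bonds, NULL)
    lab <- labels %||% c("H", "Cl")
    return(molecular_system(lab, co, spec$masses, h, linear = TRUE))
  }
  if (spec$kind == "block-composite") {
    co <- rbind(c(0, 0, 0), c(0, 0, spec$distances[1]),
                c(3, 0, 5), c(3, 0, 5 + spec$distances[2]))
    h <- .assemble_hessian(co, list(c(1L, 2L), c(3L, 4L)), spec$k_bonds, NULL)
    lab <- labels %||% c("H", "Cl", "H", "Cl")
    return(molecular_system(lab, co, spec$masses, h, linear = FALSE))
  }
  # collinear-transfer: the reactant minimum
  res <- .collinear_reactant(spec, labels)
  res
}

.collinear_reactant <- function(spec, labels = NULL) {
  stretch_block <- matrix(c(spec$k_bonds[1], spec$k_couple,
                            spec$k_couple, spec$k_bonds[2]), 2, 2)
  ev <- eigen(stretch_block, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop_input("negative curvature requested for a minimum: the reactant ",
               "stretch block must be positive definite")
  }
  co <- .collinear_geometry(spec$distances)
  fc <- matrix(c(0, spec$k_couple, spec$k_couple, 0), 2, 2)
  h <- .assemble_hessian(co, list(c(1L, 2L), c(2L, 3L)), spec$k_bonds, fc,
                         bends = list(c(1L, 2L, 3L)), k_bend = spec$k_bend)
  molecular_system(labels %||% c("C", "H", "O"), co, spec$masses, h,
                   linear = TRUE)
}

#' Build a reactant / transition-state pair for a collinear transfer toy
#'
#' The reactant force field must be positive definite in the stretch block;
#' the transition-state block (with its stretch-stretch coupling) must have
#' exactly one negative eigenvalue, giving a single imaginary mode dominated
#' by the transferring (middle) atom.
#'
#' @param spec A [toy_system_spec()] of kind "collinear-transfer" whose
#'   `ts_k_bonds`/`ts_k_couple` are set.
#' @param labels Optional element labels (default C, H, O).
#' @return List with components `reactant` and `ts`, both
#'   [molecular_system()] objects.
#' @export
make_toy_reaction <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "toy_system_spec"))
  if (spec$kind != "collinear-transfer") {
    stop_input("make_toy_reaction() needs kind = 'collinear-transfer'")
  }
  if (is.null(spec$ts_k_bonds)) {
    stop_input("spec carries no transition-state force constants")
  }
  reactant <- .collinear_reactant(spec, labels)
  tsk <- spec$ts_k_bonds
  tsc <- spec$ts_k_couple %||% 0
  stretch_block <- matrix(c(tsk[1], tsc, tsc, tsk[2]), 2, 2)
  ev <- eigen(stretch_block, symmetric = TRUE, only.values = TRUE)$values
  if (any(abs(ev) < 1e-10)) {
    stop_input("zero curvature along the transfer coordinate at the ",
               "transition state")
  }
  if (sum(ev < 0) != 1L) {
    stop_input("transition-state stretch block must have exactly one ",
               "negative eigenvalue (found ", sum(ev < 0), ")")
  }
  co <- .collinear_geometry(spec$distances)
  fc <- matrix(c(0, tsc, tsc, 0), 2, 2)
  h <- .assemble_hessian(co, list(c(1L, 2L), c(2L, 3L)), tsk, fc,
                         bends = list(c(1L, 2L, 3L)),
                         k_bend = spec$ts_k_bend %||% spec$k_bend)
  ts <- molecular_system(labels %||% c("C", "H", "O"), co, spec$masses, h,
                         linear = TRUE)
  list(reactant = reactant, ts = ts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
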