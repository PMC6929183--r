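# Path-integral free-energy machinery at toy scale: primitive (Trotter)
# P-bead discretization, exact closed forms for the harmonic oscillator,
# bisection-sampled free-particle paths centred on classical configurations
# (the quantized-classical-path construction), mass-perturbation free
# energy perturbation between isotopologs, and bead-convergence tables.

#' One-dimensional model potential for path-integral toys
#'
#' Stand-in for the quantized region of a condensed-phase simulation:
#' `harmonic` V = k x^2 / 2 (k derived from `wavenumber` and the light mass
#' when not given), `double_well` V = height ((x/width)^2 - 1)^2,
#' `eckart` V = height / cosh^2(x/width) (a barrier; sampling is then
#' confined to `range`).
#'
#' @param form One of "harmonic", "double_well", "eckart".
#' @param mass_light,mass_heavy Particle masses in amu.
#' @param wavenumber Harmonic wavenumber (cm^-1) of the light isotopolog,
#'   used to derive k when `k` is missing.
#' @param k Harmonic force constant, kcal mol^-1 A^-2.
#' @param height,width Double-well / Eckart parameters (kcal/mol, A).
#' @param range Optional sampling interval (required for `eckart`).
#' @return Object of class `model_potential` with a vectorized `$V`.
#' @export
model_potential <- function(form = c("harmonic", "double_well", "eckart"),
                            mass_light, mass_heavy = NULL,
                            wavenumber = NULL, k = NULL,
                            height = 6, width = 1, range = NULL) {
  form <- match.arg(form)
  if (mass_light <= 0 || (!is.null(mass_heavy) && mass_heavy <= 0)) {
    stop_input("masses must be positive")
  }
  if (form == "harmonic") {
    if (is.null(k)) {
      if (is.null(wavenumber)) {
        stop_input("harmonic form needs `k` or `wavenumber`")
      }
      k <- ho_force_constant(wavenumber, mass_light)
    }
    if (k <= 0) stop_input("harmonic force constant must be positive")
    V <- function(x) 0.5 * k * x^2
  } else if (form == "double_well") {
    V <- function(x) height * ((x / width)^2 - 1)^2
  } else {
    if (is.null(range)) stop_input("eckart form needs a sampling `range`")
    V <- function(x) height / cosh(x / width)^2
  }
  structure(list(form = form, V = V, k = k, height = height, width = width,
                 mass_light = mass_light, mass_heavy = mass_heavy,
                 range = range),
            class = "model_potential")
}

#' Harmonic force constant from a wavenumber and mass
#'
#' @param wavenumber Wavenumber in cm^-1.
#' @param mass Mass in amu.
#' @return k in kcal mol^-1 A^-2 with k = m (hbar omega)^2 / hbar^2.
#' @export
ho_force_constant <- function(wavenumber, mass) {
  hw <- phys_constants()$wavenumber_to_kcal * wavenumber
  mass * hw^2 / .hbar2()
}

#' Harmonic wavenumber of a model potential for one isotopolog
#'
#' @param pot A harmonic [model_potential()].
#' @param isotopolog "light" or "heavy".
#' @return Wavenumber in cm^-1.
#' @export
potential_wavenumber <- function(pot, isotopolog = c("light", "heavy")) {
  stopifnot(inherits(pot, "model_potential"))
  isotopolog <- match.arg(isotopolog)
  if (pot$form != "harmonic") stop_input("defined for harmonic form only")
  m <- if (isotopolog == "light") pot$mass_light else pot$mass_heavy
  if (is.null(m)) stop_input("heavy mass not set on this potential")
  hw <- sqrt(.hbar2() * pot$k / m)
  hw / phys_constants()$wavenumber_to_kcal
}

#' Path-integral sampling settings
#'
#' @param P Bead count; a power of two (bisection requirement).
#' @param temperature Temperature in K.
#' @param n_config Number of classical configurations.
#' @param n_pi Free-particle path draws per classical configuration
#'   (the "path integral steps per classical step"; default 10).
#' @param seed Integer seed or NULL.
#' @return Object of class `pi_settings`.
#' @export
pi_settings <- function(P = 64L, temperature = 298, n_config = 8000L,
                        n_pi = 10L, seed = NULL) {
  if (!is_power_of_two(P) || P < 2) {
    stop_input("`P` must be a power of two >= 2 (bisection requirement)")
  }
  if (temperature <= 0) stop_input("temperature must be positive")
  if (!is_count(n_config) || !is_count(n_pi)) {
    stop_input("`n_config` and `n_pi` must be positive integers")
  }
  structure(list(P = as.integer(P), temperature = temperature,
                 n_config = as.integer(n_config), n_pi = as.integer(n_pi),
                 levels = as.integer(round(log2(P))), seed = seed),
            class = "pi_settings")
}

#' Exact P-bead free energy of a 1D harmonic oscillator
#'
#' Closed form for the primitive discretization,
#' \deqn{F_P = k_B T \ln(2\sinh(P\theta/2)), \quad
#'       \cosh\theta = 1 + (\beta\hbar\omega)^2/(2P^2),}
#' which interpolates between the classical value \eqn{k_BT\ln(\beta\hbar\omega)}
#' at P = 1 and the exact quantum free energy
#' \eqn{k_BT\ln(2\sinh(\beta\hbar\omega/2))} as P grows.
#'
#' @param wavenumber Oscillator wavenumber, cm^-1, > 0.
#' @param th A [thermo_settings()].
#' @param P Bead count, integer >= 1 (any integer; powers of two are only
#'   required for the sampling routines).
#' @return Free energy in kcal/mol.
#' @export
pi_free_energy_ho_exact <- function(wavenumber, th, P) {
  stopifnot(inherits(th, "thermo_settings"))
  if (wavenumber <= 0) stop_input("wavenumber must be positive")
  if (any(!is_count(P))) stop_input("P must be a positive integer")
  u <- .mode_u(wavenumber, th)
  kt <- 1 / th$beta
  theta <- acosh(1 + u^2 / (2 * P^2))
  x <- P * theta / 2
  kt * (x + log1p(-exp(-2 * x)))   # log(2 sinh x), overflow-safe
}

#' Exact quantum and classical harmonic free energies
#'
#' @inheritParams pi_free_energy_ho_exact
#' @return kcal/mol.
#' @export
ho_quantum_free_energy <- function(wavenumber, th) {
  u <- .mode_u(wavenumber, th)
  (u / 2 + log1p(-exp(-u))) / th$beta
}

#' @rdname ho_quantum_free_energy
#' @export
ho_classical_free_energy <- function(wavenumber, th) {
  log(.mode_u(wavenumber, th)) / th$beta
}

#' Sample centroid-constrained free-particle ring paths by bisection
#'
#' Draws displacement paths of a free ring polymer of P beads at inverse
#' temperature beta for a particle of mass m, conditioned on zero centroid:
#' a pinned Brownian bridge in imaginary time is constructed level by level
#' (midpoint displacements with variance s*sigma^2/4 for a segment of s
#' links, sigma^2 = beta hbar^2/(m P) per link), then recentred. The
#' recentred pinned bridge is distributed exactly as the centroid-zero free
#' ring because the ring action depends only on bead differences.
#'
#' @param n Number of independent paths.
#' @param P Beads, power of two >= 2.
#' @param beta Inverse temperature, mol/kcal.
#' @param mass Particle mass, amu.
#' @return n x P matrix of bead displacements (Angstrom) with zero row
#'   means.
#' @export
sample_free_paths <- function(n, P, beta, mass) {
  if (!is_power_of_two(P) || P < 2) {
    stop_input("`P` must be a power of two >= 2")
  }
  sigma2 <- .hbar2() * beta / (mass * P)
  x <- matrix(0, n, P + 1L)
  s <- as.integer(P)
  while (s > 1L) {
    half <- s %/% 2L
    mids <- seq.int(half, P - half, by = s)
    v <- half * sigma2 / 2
    x[, mids + 1L] <-
      (x[, mids - half + 1L, drop = FALSE] +
         x[, mids + half + 1L, drop = FALSE]) / 2 +
      matrix(stats::rnorm(n * length(mids), 0, sqrt(v)), n)
    s <- half
  }
  d <- x[, seq_len(P), drop = FALSE]
  d - rowMeans(d)
}

# Classical Boltzmann configurations of a model potential (Metropolis).
.classical_configs <- function(pot, beta, n) {
  if (!is.null(pot$range)) {
    lo <- min(pot$range); hi <- max(pot$range)
    U <- function(x) if (x < lo || x > hi) Inf else pot$V(x)
    init <- (lo + hi) / 2
  } else {
    U <- pot$V
    init <- if (pot$form == "double_well") pot$width else 0
  }
  .metropolis_1d(U, beta, n, init = init)$samples
}

#' Path ensemble for quantized-classical-path estimation
#'
#' Samples `n_config` classical configurations from the classical Boltzmann
#' density of the potential (built-in Metropolis sampler) and, for each,
#' `n_pi` centroid-constrained free-particle bead paths by bisection.
#'
#' @param pot A [model_potential()].
#' @param settings A [pi_settings()].
#' @param isotopolog "light" or "heavy" (selects the path-sampling mass).
#' @return Object of class `bqcp_paths`: centroids, displacement matrix,
#'   masses, beta, P and bookkeeping fields.
#' @export
sample_bqcp_paths <- function(pot, settings, isotopolog = c("light", "heavy")) {
  stopifnot(inherits(pot, "model_potential"), inherits(settings, "pi_settings"))
  isotopolog <- match.arg(isotopolog)
  mass <- if (isotopolog == "light") pot$mass_light else pot$mass_heavy
  if (is.null(mass)) stop_input("heavy mass not set on this potential")
  beta <- 1 / (.kB_kcal() * settings$temperature)
  with_seed(settings$seed, {
    cfg <- .classical_configs(pot, beta, settings$n_config)
    xc <- rep(cfg, each = settings$n_pi)
    disp <- sample_free_paths(length(xc), settings$P, beta, mass)
    structure(list(centroids = xc, disp = disp, pot = pot, beta = beta,
                   mass = mass, isotopolog = isotopolog, P = settings$P,
                   temperature = settings$temperature,
                   n_config = settings$n_config, n_pi = settings$n_pi,
                   seed = settings$seed),
              class = "bqcp_paths")
  })
}

# Jackknife (10 blocks over classical configurations) of -kT log(mean w).
.jackknife_logmean <- function(w, block_id, kt) {
  blocks <- sort(unique(block_id))
  nb <- length(blocks)
  tot <- sum(w); n <- length(w)
  est <- vapply(blocks, function(b) {
    sel <- block_id == b
    -kt * log((tot - sum(w[sel])) / (n - sum(sel)))
  }, numeric(1))
  full <- -kt * log(tot / n)
  se <- sqrt((nb - 1) / nb * sum((est - mean(est))^2))
  list(value = full, se = se)
}

.block_ids <- function(n_config, n_pi, n_blocks = 10L) {
  if (n_config < n_blocks) {
    stop_input("too few classical configurations for a ", n_blocks,
               "-block jackknife")
  }
  rep(ceiling(seq_len(n_config) / (n_config / n_blocks)), each = n_pi)
}

#' Bead-quantized free-energy correction (quantized classical path)
#'
#' Estimates \eqn{\Delta F_{qm} = F_{quantum}(P) - F_{classical}} by the
#' quantized-classical-path estimator
#' \deqn{e^{-\beta \Delta F_{qm}} =
#'   \langle\langle e^{-\beta(\bar V_{path} - V(x_c))}
#'   \rangle_{free\ paths}\rangle_{classical}}
#' with \eqn{\bar V} the bead-averaged potential of a centroid-constrained
#' free-particle path around the classical configuration \eqn{x_c}.
#' Standard error by 10-block jackknife over classical configurations.
#'
#' @param pot A [model_potential()].
#' @param settings A [pi_settings()].
#' @param isotopolog "light" or "heavy".
#' @param species Tag carried into the result ("reactant" or "ts").
#' @param paths Optional pre-sampled [sample_bqcp_paths()] ensemble.
#' @param keep_paths Keep the path ensemble in the result (needed for
#'   [mass_perturbed_difference()]).
#' @return Object of class `quantum_correction`.
#' @export
bqcp_quantum_correction <- function(pot, settings,
                                    isotopolog = c("light", "heavy"),
                                    species = c("reactant", "ts"),
                                    paths = NULL, keep_paths = FALSE) {
  isotopolog <- match.arg(isotopolog)
  species <- match.arg(species)
  if (is.null(paths)) paths <- sample_bqcp_paths(pot, settings, isotopolog)
  stopifnot(inherits(paths, "bqcp_paths"))
  beta <- paths$beta
  kt <- 1 / beta
  v0 <- pot$V(paths$centroids)
  vbar <- rowMeans(pot$V(paths$disp + paths$centroids))
  w <- exp(-beta * (vbar - v0))
  jk <- .jackknife_logmean(w, .block_ids(paths$n_config, paths$n_pi), kt)
  structure(list(species = species, isotopolog = isotopolog,
                 dF_qm = jk$value, se = jk$se, P = paths$P,
                 temperature = paths$temperature,
                 n_config = paths$n_config, n_pi = paths$n_pi,
                 seed = paths$seed,
                 paths = if (keep_paths) paths else NULL),
            class = "quantum_correction")
}

#' Construct a quantum-correction record from known values
#'
#' @param species "reactant" or "ts".
#' @param isotopolog "light" or "heavy".
#' @param dF_qm Correction in kcal/mol.
#' @param se Monte Carlo standard error (>= 0).
#' @param P Bead count.
#' @param temperature Temperature in K.
#' @return Object of class `quantum_correction`.
#' @export
quantum_correction <- function(species = c("reactant", "ts"),
                               isotopolog = c("light", "heavy"),
                               dF_qm, se = 0, P = 64L, temperature = 298) {
  species <- match.arg(species)
  isotopolog <- match.arg(isotopolog)
  if (se < 0) stop_input("standard error must be >= 0")
  structure(list(species = species, isotopolog = isotopolog, dF_qm = dF_qm,
                 se = se, P = as.integer(P), temperature = temperature,
                 paths = NULL),
            class = "quantum_correction")
}

#' @export
print.quantum_correction <- function(x, ...) {
  cat(sprintf(
    "<quantum_correction> %s/%s: dF_qm = %.4f +/- %.4f kcal/mol (P = %d, T = %g K)\n",
    x$species, x$isotopolog, x$dF_qm, x$se, x$P, x$temperature))
  invisible(x)
}

#' Isotope free-energy difference by mass-perturbation FEP
#'
#' Re-uses the light-isotopolog path ensemble: heavy-isotopolog bead paths
#' are obtained exactly by scaling the free-particle displacements about
#' their centroid by \eqn{\sqrt{m_L/m_H}} (a change of variables of the
#' Gaussian path measure, so this is direct sampling for the heavy mass,
#' not importance reweighting). Returns
#' \eqn{\Delta F_{qm}(heavy) - \Delta F_{qm}(light)} with jackknife SE and
#' an effective-sample-size diagnostic on the heavy-path integrand.
#'
#' @param light_paths A [sample_bqcp_paths()] ensemble sampled for the
#'   light isotopolog (or a [bqcp_quantum_correction()] result built with
#'   `keep_paths = TRUE`).
#' @param mass_ratio m_H / m_L, >= 1.
#' @return List with `difference` (kcal/mol), `se`, `ess`, `n`.
#' @export
mass_perturbed_difference <- function(light_paths, mass_ratio) {
  if (inherits(light_paths, "quantum_correction")) {
    light_paths <- light_paths$paths
    if (is.null(light_paths)) {
      stop_input("quantum correction was computed without keep_paths = TRUE")
    }
  }
  stopifnot(inherits(light_paths, "bqcp_paths"))
  if (mass_ratio < 1) stop_input("mass_ratio = m_H/m_L must be >= 1")
  p <- light_paths
  beta <- p$beta; kt <- 1 / beta
  V <- p$pot$V
  v0 <- V(p$centroids)
  s <- 1 / sqrt(mass_ratio)
  wl <- exp(-beta * (rowMeans(V(p$disp + p$centroids)) - v0))
  wh <- exp(-beta * (rowMeans(V(s * p$disp + p$centroids)) - v0))
  ess <- sum(wh)^2 / sum(wh^2)
  if (ess < 0.1 * length(wh)) {
    stop_input(sprintf(
      "unreliable overlap: effective sample size %.0f is below 10%% of %d",
      ess, length(wh)))
  }
  block_id <- .block_ids(p$n_config, p$n_pi)
  blocks <- sort(unique(block_id))
  est <- vapply(blocks, function(b) {
    sel <- block_id != b
    -kt * (log(mean(wh[sel])) - log(mean(wl[sel])))
  }, numeric(1))
  full <- -kt * (log(mean(wh)) - log(mean(wl)))
  nb <- length(blocks)
  se <- sqrt((nb - 1) / nb * sum((est - mean(est))^2))
  list(difference = full, se = se, ess = ess, n = length(wh))
}

#' Path-integral kinetic isotope effect from quantum corrections
#'
#' Combines per-species, per-isotopolog bead-quantized corrections into
#' \deqn{\ln KIE = -\beta\,[\Delta\Delta G^\ddag_{qm}(light) -
#'   \Delta\Delta G^\ddag_{qm}(heavy)]}
#' with \eqn{\Delta\Delta G^\ddag_{qm} = \Delta F_{qm}(TS) -
#' \Delta F_{qm}(reactant)}; the classical PMF transition-state factor is
#' isotope-independent and drops out. Standard errors propagate in
#' quadrature.
#'
#' @param reactant,ts Lists with `light` and `heavy`
#'   [bqcp_quantum_correction()] / [quantum_correction()] entries.
#' @param th A [thermo_settings()] matching the corrections' temperature.
#' @param position,element Optional labels.
#' @return A [position_kie()] with provenance "pi"; `$components` retains
#'   the two \eqn{\Delta\Delta G^\ddag_{qm}} values and settings.
#' @export
pi_kie <- function(reactant, ts, th, position = NA_character_,
                   element = NA_character_) {
  qcs <- list(reactant$light, reactant$heavy, ts$light, ts$heavy)
  for (q in qcs) stopifnot(inherits(q, "quantum_correction"))
  ps <- vapply(qcs, `[[`, integer(1), "P")
  ts_temp <- vapply(qcs, `[[`, numeric(1), "temperature")
  if (length(unique(ps)) != 1L) {
    stop_input("mismatched bead counts across corrections: ",
               paste(unique(ps), collapse = ", "))
  }
  if (any(abs(ts_temp - th$temperature) > 1e-9)) {
    stop_input("corrections were computed at a different temperature ",
               "than `th`")
  }
  ddg_l <- ts$light$dF_qm - reactant$light$dF_qm
  ddg_h <- ts$heavy$dF_qm - reactant$heavy$dF_qm
  ln_kie <- -th$beta * (ddg_l - ddg_h)
  se_ln <- th$beta * sqrt(sum(vapply(qcs, `[[`, numeric(1), "se")^2))
  kie <- exp(ln_kie)
  position_kie(position = position, element = element, kie = kie,
               provenance = "pi", se = kie * se_ln,
               components = list(ddG_light = ddg_l, ddG_heavy = ddg_h,
                                 P = ps[1], temperature = th$temperature))
}

#' Smallest bead count converging the harmonic free energy
#'
#' Evaluates the closed-form P-bead free energy against the exact quantum
#' value for each candidate bead count and returns the smallest one whose
#' absolute deviation is below `tolerance`, with the full deviation table.
#'
#' @param wavenumber Oscillator wavenumber, cm^-1.
#' @param th A [thermo_settings()].
#' @param P_list Ascending candidate bead counts.
#' @param tolerance Convergence criterion, kcal/mol, > 0.
#' @return List with `P` (smallest converged count), `table` (data.frame
#'   P, F_P, deviation), `F_exact`.
#' @export
bead_convergence <- function(wavenumber, th, P_list = c(8L, 16L, 32L, 64L),
                             tolerance = 0.02) {
  if (is.unsorted(P_list, strictly = TRUE)) {
    stop_input("`P_list` must be ascending")
  }
  if (tolerance <= 0) stop_input("`tolerance` must be positive")
  f_exact <- ho_quantum_free_energy(wavenumber, th)
  f_p <- vapply(P_list, function(p) pi_free_energy_ho_exact(wavenumber, th, p),
                numeric(1))
  dev <- abs(f_p - f_exact)
  tab <- data.frame(P = as.integer(P_list), F_P = f_p, deviation = dev)
  ok <- which(dev < tolerance)
  if (!length(ok)) {
    stop_input("no bead count converged; deviations (kcal/mol): ",
               paste(sprintf("P=%d: %.4g", tab$P, tab$deviation),
                     collapse = ", "))
  }
  list(P = tab$P[ok[1]], table = tab, F_exact = f_exact)
}
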