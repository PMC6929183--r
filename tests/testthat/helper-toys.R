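# Shared fixtures: toy reactions built in code, plus the brute-force
# partition-function oracle used to cross-check the Bigeleisen engine.

th_298 <- thermo_settings(298)
th_29815 <- thermo_settings(298.15)

# proton-abstraction toy (C-H...O), the demo's transfer-H system
cho_spec <- function() {
  toy_system_spec("collinear-transfer",
                  masses = c(12.0, 1.00782503, 15.9949146),
                  distances = c(1.1, 1.3),
                  k_bonds = c(0.31, 0.03), k_bend = 0.02,
                  ts_k_bonds = c(0.21, 0.21), ts_k_couple = 0.26,
                  ts_k_bend = 0.055)
}

# chlorine-departure toy (X-C-Cl with a heavy skeleton pseudo-atom)
xccl_spec <- function() {
  toy_system_spec("collinear-transfer",
                  masses = c(83.0, 12.0, 34.9688527),
                  distances = c(1.54, 1.8),
                  k_bonds = c(0.30, 0.18), k_bend = 0.02,
                  ts_k_bonds = c(0.03, 0.17), ts_k_couple = 0.09,
                  ts_k_bend = 0.02)
}

hcl_diatomic <- function(k_npm = 516, m = c(1.00782503, 34.9688527)) {
  make_toy_species(toy_system_spec(
    "diatomic", masses = m, distances = 1.27,
    k_bonds = newton_per_metre_to_hartree_bohr2(k_npm)))
}

# --- independent oracle: full harmonic TST partition-function ratio ------
# Classical rotation / translation factors with quantum harmonic vibrations;
# the Teller-Redlich product rule is exercised numerically because no
# explicit imaginary-frequency factor appears here.

oracle_rot_factor <- function(coords, masses, linear) {
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  imat <- matrix(0, 3, 3)
  for (i in seq_len(nrow(r))) {
    ri <- r[i, ]
    imat <- imat + masses[i] * (sum(ri^2) * diag(3) - tcrossprod(ri))
  }
  ev <- sort(eigen(imat, symmetric = TRUE, only.values = TRUE)$values)
  if (linear) ev[3] else sqrt(prod(ev))
}

oracle_qvib <- function(u) exp(-u / 2) / (1 - exp(-u))

oracle_partition_ratio <- function(sys, m_light, m_heavy, th) {
  fl <- frequencies_from_hessian(sys, masses = m_light)
  fh <- frequencies_from_hessian(sys, masses = m_heavy)
  ul <- th$c2 * fl$real / th$temperature
  uh <- th$c2 * fh$real / th$temperature
  trans <- (sum(m_light) / sum(m_heavy))^1.5
  rot <- oracle_rot_factor(sys$coords, m_light, sys$linear) /
    oracle_rot_factor(sys$coords, m_heavy, sys$linear)
  trans * rot * prod(oracle_qvib(ul)) / prod(oracle_qvib(uh))
}

oracle_kie <- function(reactant, ts, sub, th) {
  ml <- reactant$masses; ml[sub$index] <- sub$light
  mh <- reactant$masses; mh[sub$index] <- sub$heavy
  oracle_partition_ratio(ts, ml, mh, th) /
    oracle_partition_ratio(reactant, ml, mh, th)
}

engine_kie <- function(rx, index, element, th) {
  sub <- isotope_substitution(index, element)
  fr <- isotopolog_frequency_sets(rx$reactant, sub)
  ft <- isotopolog_frequency_sets(rx$ts, sub)
  semiclassical_kie(fr$light, fr$heavy, ft$light, ft$heavy, th,
                    position = paste0(element, index), element = element)
}
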