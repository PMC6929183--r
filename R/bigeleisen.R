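# Semiclassical (harmonic, no tunneling correction) kinetic isotope effects
# assembled from isotopic frequency shifts: per-mode Bigeleisen factors and
# the imaginary-frequency ratio.

#' Thermodynamic settings
#'
#' Temperature plus the physical-constants bundle. Default 298.15 K; the
#' batch hydrolysis experiments run at 303.15 K (30 C), available by
#' argument.
#'
#' @param temperature Absolute temperature in K, > 0.
#' @return Object of class `thermo_settings` with fields `temperature`,
#'   `kB_kcal` (kcal mol^-1 K^-1), `c2` (hc/kB, cm K), `beta`
#'   (mol kcal^-1).
#' @export
thermo_settings <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature <= 0) {
    stop_input("`temperature` must be a single positive value in K")
  }
  structure(list(temperature = temperature,
                 kB_kcal = .kB_kcal(), c2 = .c2(),
                 beta = 1 / (.kB_kcal() * temperature)),
            class = "thermo_settings")
}

# u = h c nu / (kB T), dimensionless mode temperature
.mode_u <- function(nu, th) th$c2 * nu / th$temperature

# Per-mode Bigeleisen factor g_i; the product over modes is the species
# factor g entering KIE = (nu_L/nu_H)^ts * g(TS)/g(R). Computed in log space
# for numerical robustness at low temperature.
.mode_factor <- function(u_l, u_h) {
  exp(log(u_l / u_h) + (u_h - u_l) / 2 +
        log1p(-exp(-u_h)) - log1p(-exp(-u_l)))
}

#' Per-mode Bigeleisen factor table
#'
#' Matches the real modes of a light and a heavy frequency set by ascending
#' order and tabulates u = hc*nu/kBT for both along with the per-mode factor
#' g_i = (u_L/u_H) exp((u_H-u_L)/2) (1-exp(-u_H))/(1-exp(-u_L)). The product
#' of the factors is the species factor g.
#'
#' @param light,heavy [frequency_set()] objects with equal real-mode counts.
#' @param th A [thermo_settings()].
#' @return Object of class `mode_factor_table`: a data.frame with columns
#'   `nu_light`, `nu_heavy`, `u_light`, `u_heavy`, `factor`, plus attributes
#'   `g` (the product) and `mode_crossing_risk` (TRUE when adjacent modes of
#'   either set lie within 1 cm^-1).
#' @export
mode_factor_table <- function(light, heavy, th) {
  stopifnot(inherits(light, "frequency_set"), inherits(heavy, "frequency_set"),
            inherits(th, "thermo_settings"))
  if (length(light$real) != length(heavy$real)) {
    stop_input("mismatched real-mode counts (", length(light$real), " vs ",
               length(heavy$real), ")")
  }
  ul <- .mode_u(light$real, th)
  uh <- .mode_u(heavy$real, th)
  fac <- if (length(ul)) .mode_factor(ul, uh) else numeric(0)
  tab <- data.frame(nu_light = light$real, nu_heavy = heavy$real,
                    u_light = ul, u_heavy = uh, factor = fac)
  crossing <- any(diff(light$real) < 1) || any(diff(heavy$real) < 1)
  structure(tab, class = c("mode_factor_table", "data.frame"),
            g = prod(fac), mode_crossing_risk = crossing)
}

#' Species Bigeleisen factor
#'
#' @param x A [mode_factor_table()].
#' @return The product of the per-mode factors (1 for an empty mode set).
#' @export
species_factor <- function(x) {
  stopifnot(inherits(x, "mode_factor_table"))
  attr(x, "g")
}

#' Semiclassical position-specific kinetic isotope effect
#'
#' The harmonic Bigeleisen KIE
#' \deqn{KIE = (\nu^\ddag_L/\nu^\ddag_H) \; g(TS)/g(R)}
#' with g the product of per-mode factors over real modes. No anharmonicity,
#' no tunneling (Wigner) correction, frequency scaling factor 1.0.
#'
#' @param reactant_l,reactant_h Reactant [frequency_set()]s (no imaginary
#'   entry).
#' @param ts_l,ts_h Transition-state [frequency_set()]s (each carrying one
#'   imaginary entry).
#' @param th A [thermo_settings()].
#' @param position,element Optional labels carried into the result.
#' @return A [position_kie()] with provenance "semiclassical" and the
#'   components (`nu_ratio`, `g_ts`, `g_r`, `temperature`) retained in
#'   `$components`.
#' @export
semiclassical_kie <- function(reactant_l, reactant_h, ts_l, ts_h, th,
                              position = NA_character_,
                              element = NA_character_) {
  for (fs in list(reactant_l, reactant_h)) {
    if (!is.null(fs$imaginary)) {
      stop_input("reactant frequency set carries an imaginary mode")
    }
  }
  for (fs in list(ts_l, ts_h)) {
    if (is.null(fs$imaginary)) {
      stop_input("transition-state frequency set lacks an imaginary mode")
    }
  }
  g_r <- species_factor(mode_factor_table(reactant_l, reactant_h, th))
  g_ts <- species_factor(mode_factor_table(ts_l, ts_h, th))
  nu_ratio <- ts_l$imaginary / ts_h$imaginary
  kie <- nu_ratio * g_ts / g_r
  position_kie(position = position, element = element, kie = kie,
               provenance = "semiclassical",
               components = list(nu_ratio = nu_ratio, g_ts = g_ts, g_r = g_r,
                                 temperature = th$temperature))
}
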