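# In-silico analogue of the alkaline batch hydrolysis experiments: parallel
# first-order decay of light and heavy isotopolog pools per element, with
# the heavy/light rate ratio set by the element's bulk KIE, plus a simple
# measurement-noise model (lognormal multiplicative on concentration,
# additive Gaussian on delta values).

.elements <- c("C", "Cl", "H")
.delta_cols <- c(C = "d13C_permil", Cl = "d37Cl_permil", H = "d2H_permil")

# international reference ratios (placeholder standards; delta arithmetic
# cancels them): VPDB 13C/12C, SMOC 37Cl/35Cl, VSMOW 2H/1H
.default_r_std <- c(C = 0.0111802, Cl = 0.3197655, H = 1.5576e-4)

#' Parameters of a simulated batch-degradation experiment
#'
#' Defaults emulate the alkaline hydrolysis batch design: a pseudo
#' first-order rate constant giving a convenient half-life of about two
#' hours, six positions per element, primary KIEs at the reactive positions
#' and secondary KIEs at the rest (defaults anchored to the reactive-position
#' and secondary-average values predicted for the hydroxide elimination:
#' C 1.03/1.0029, Cl 1.0027/1.0008, H 4.5/1.0156), ten sampling times
#' spanning roughly one decade of degradation, 2 % relative concentration
#' noise, and per-element delta noise of 0.5 permil for C and Cl and 5
#' permil for H.
#'
#' @param k_light First-order rate constant of the light isotopolog, s^-1.
#' @param n Named integer vector of positions per element (default 6,6,6).
#' @param primary,secondary Named numeric vectors of primary and secondary
#'   KIEs per element.
#' @param times_h Strictly increasing sampling times in hours, starting at 0.
#' @param c0 Initial concentration (arbitrary units, > 0).
#' @param delta0 Named initial delta values (permil vs. standard).
#' @param r_std Named reference isotope ratios.
#' @param conc_noise_rel Relative (lognormal) concentration noise sd.
#' @param delta_noise_permil Named additive Gaussian delta noise sd (permil);
#'   a single value is recycled.
#' @param seed Integer seed, or NULL for the current RNG stream.
#' @return Object of class `batch_experiment_params`.
#' @export
batch_experiment_params <- function(
    k_light = 1e-4,
    n = c(C = 6L, Cl = 6L, H = 6L),
    primary = c(C = 1.03, Cl = 1.0027, H = 4.5),
    secondary = c(C = 1.0029, Cl = 1.0008, H = 1.0156),
    times_h = seq(0, 6.75, by = 0.75),
    c0 = 10,
    delta0 = c(C = 0, Cl = 0, H = 0),
    r_std = .default_r_std,
    conc_noise_rel = 0.02,
    delta_noise_permil = c(C = 0.5, Cl = 0.5, H = 5),
    seed = NULL) {
  if (!is.numeric(k_light) || k_light <= 0) stop_input("k_light must be > 0")
  if (c0 <= 0) stop_input("initial concentration must be positive")
  fix <- function(x, what, default = 0) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, 3L), .elements)
    }
    if (!all(.elements %in% names(x))) {
      stop_input("`", what, "` must be named with elements C, Cl, H")
    }
    x[.elements]
  }
  n <- fix(n, "n"); primary <- fix(primary, "primary")
  secondary <- fix(secondary, "secondary"); delta0 <- fix(delta0, "delta0")
  r_std <- fix(r_std, "r_std")
  delta_noise_permil <- fix(delta_noise_permil, "delta_noise_permil")
  if (any(n < 1)) stop_input("position counts must be >= 1")
  if (any(primary <= 0) || any(secondary <= 0)) {
    stop_input("KIE values must be positive")
  }
  if (length(times_h) < 2L || times_h[1] != 0 || any(diff(times_h) <= 0)) {
    stop_input("`times_h` must be strictly increasing and start at 0")
  }
  if (conc_noise_rel < 0 || any(delta_noise_permil < 0)) {
    stop_input("noise magnitudes must be non-negative")
  }
  structure(list(k_light = k_light, n = n, primary = primary,
                 secondary = secondary, times_h = as.numeric(times_h),
                 c0 = c0, delta0 = delta0, r_std = r_std,
                 conc_noise_rel = conc_noise_rel,
                 delta_noise_permil = delta_noise_permil, seed = seed),
            class = "batch_experiment_params")
}

#' Bulk KIE and enrichment factor implied by batch parameters
#'
#' @param p A [batch_experiment_params()].
#' @return Data frame with element, kie_av, epsilon_permil.
#' @export
batch_implied_epsilon <- function(p) {
  stopifnot(inherits(p, "batch_experiment_params"))
  kie_av <- (p$primary + (p$n - 1) * p$secondary) / p$n
  data.frame(element = .elements, kie_av = unname(kie_av),
             epsilon_permil = unname((1 - kie_av) * 1000))
}

#' Simulate a batch degradation experiment
#'
#' For each element the light and heavy isotopolog pools decay first-order;
#' the heavy rate is \eqn{k_H = k_L (1 + \varepsilon/1000)} with
#' \eqn{\varepsilon = (1 - KIE_{av})\cdot 1000} from the element's bulk KIE,
#' so the noise-free data satisfy the Rayleigh relation
#' \eqn{\ln(R/R_0) = (\varepsilon/1000)\ln(C/C_0)} exactly. Heavy
#' isotopologs are treated as trace species: the reported concentration
#' tracks the light pool. Concentration noise is lognormal multiplicative,
#' delta noise additive Gaussian; identical seeds give byte-identical
#' tables.
#'
#' @param p A [batch_experiment_params()].
#' @return A `rayleigh_dataset`: data.frame with columns `time_h`, `conc`,
#'   `d13C_permil`, `d37Cl_permil`, `d2H_permil` and attributes `r_std`,
#'   `c0`, `delta0` (nominal references), `epsilon_true`, `params`, `seed`.
#' @export
simulate_batch_experiment <- function(p) {
  stopifnot(inherits(p, "batch_experiment_params"))
  kie_av <- (p$primary + (p$n - 1) * p$secondary) / p$n
  eps <- (1 - kie_av) * 1000
  if (any(1 + eps / 1000 <= 0)) {
    stop_input("bulk KIE_av >= 2 gives a non-positive heavy-pool rate ",
               "under the linearized enrichment convention")
  }
  t_s <- p$times_h * 3600
  f <- exp(-p$k_light * t_s)                    # light pool fraction
  conc <- p$c0 * f
  r0 <- p$r_std * (1 + p$delta0 / 1000)
  delta <- sapply(.elements, function(el) {
    k_h <- p$k_light * (1 + eps[[el]] / 1000)
    ratio <- r0[[el]] * exp(-(k_h - p$k_light) * t_s)
    (ratio / p$r_std[[el]] - 1) * 1000
  })
  out <- with_seed(p$seed, {
    conc_obs <- conc * exp(stats::rnorm(length(conc), 0, p$conc_noise_rel))
    delta_obs <- delta
    for (el in .elements) {
      delta_obs[, el] <- delta[, el] +
        stats::rnorm(nrow(delta), 0, p$delta_noise_permil[[el]])
    }
    list(conc = conc_obs, delta = delta_obs)
  })
  df <- data.frame(time_h = p$times_h, conc = out$conc,
                   d13C_permil = out$delta[, "C"],
                   d37Cl_permil = out$delta[, "Cl"],
                   d2H_permil = out$delta[, "H"])
  structure(df,
            class = c("rayleigh_dataset", "data.frame"),
            r_std = p$r_std, c0 = p$c0, delta0 = p$delta0,
            epsilon_true = eps, params = p, seed = p$seed)
}

#' Write / read a batch dataset as CSV
#'
#' The CSV holds the observation table; the nominal references travel in a
#' commented header line so that a round trip preserves the fit inputs.
#'
#' @param ds A `rayleigh_dataset`.
#' @param path CSV path.
#' @return `path` (write) or a `rayleigh_dataset` (read).
#' @export
write_rayleigh_csv <- function(ds, path) {
  stopifnot(inherits(ds, "rayleigh_dataset"))
  hdr <- sprintf(
    "# c0=%.10g dC0=%.10g dCl0=%.10g dH0=%.10g RC=%.10g RCl=%.10g RH=%.10g",
    attr(ds, "c0"), attr(ds, "delta0")[["C"]], attr(ds, "delta0")[["Cl"]],
    attr(ds, "delta0")[["H"]], attr(ds, "r_std")[["C"]],
    attr(ds, "r_std")[["Cl"]], attr(ds, "r_std")[["H"]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(ds), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rayleigh_csv
#' @export
read_rayleigh_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_hdr <- startsWith(first, "#")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_h", "conc", unname(.delta_cols))
  if (!all(need %in% names(df))) {
    stop_input("CSV lacks required columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  }
  c0 <- df$conc[1]; delta0 <- c(C = 0, Cl = 0, H = 0)
  r_std <- .default_r_std
  if (has_hdr) {
    kv <- regmatches(first, gregexpr("[A-Za-z0-9]+=[-0-9.eE+]+", first))[[1]]
    vals <- stats::setNames(
      as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
    c0 <- vals[["c0"]]
    delta0 <- c(C = vals[["dC0"]], Cl = vals[["dCl0"]], H = vals[["dH0"]])
    r_std <- c(C = vals[["RC"]], Cl = vals[["RCl"]], H = vals[["RH"]])
  }
  structure(df, class = c("rayleigh_dataset", "data.frame"),
            r_std = r_std, c0 = c0, delta0 = delta0)
}
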