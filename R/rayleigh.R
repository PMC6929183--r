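# Rayleigh regression of batch-degradation data and delta/ratio/epsilon
# conversions of compound-specific isotope analysis.

#' Convert delta notation to an isotope ratio and back
#'
#' \eqn{R = R_{std}(1 + \delta/1000)}.
#'
#' @param delta Delta value(s) in permil, each > -1000.
#' @param ratio Isotope ratio(s), > 0.
#' @param r_std Reference standard ratio.
#' @return Ratio(s) or delta value(s).
#' @export
delta_to_ratio <- function(delta, r_std) {
  if (any(delta <= -1000)) stop_input("delta values must exceed -1000 permil")
  r_std * (1 + delta / 1000)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(ratio, r_std) {
  if (any(ratio <= 0)) stop_input("ratios must be positive")
  (ratio / r_std - 1) * 1000
}

#' Rayleigh regression for one element's enrichment factor
#'
#' Fits \eqn{\ln(R_t/R_0) = (\varepsilon/1000)\,\ln(C_t/C_0)} by least
#' squares. Both axes are referenced to the nominal initial composition and
#' concentration of the prepared batch (stored in the dataset), which makes
#' the observation errors independent across time points; the default fit
#' is through the origin, exactly matching the Rayleigh model, and a
#' free-intercept variant is available as a robustness check.
#'
#' @param ds A `rayleigh_dataset` (see [simulate_batch_experiment()] /
#'   [read_rayleigh_csv()]).
#' @param element "C", "Cl", or "H".
#' @param intercept FALSE (default) for regression through the origin.
#' @return Object of class `epsilon_fit`: list with `element`,
#'   `epsilon_permil`, `se_permil`, `ci95_permil`, `r_squared`, `n`,
#'   `intercept`, `fit` (the underlying `lm`).
#' @export
rayleigh_fit <- function(ds, element = c("C", "Cl", "H"), intercept = FALSE) {
  stopifnot(inherits(ds, "rayleigh_dataset"))
  element <- match.arg(element)
  col <- .delta_cols[[element]]
  c0 <- attr(ds, "c0")
  d0 <- attr(ds, "delta0")[[element]]
  keep <- is.finite(ds$conc) & ds$conc > 0 & is.finite(ds[[col]])
  d <- ds[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop_input("need at least 3 usable time points")
  x <- log(d$conc / c0)
  y <- log((1 + d[[col]] / 1000) / (1 + d0 / 1000))
  if (sum(d$conc < c0) < 2L || max(abs(x)) < 1e-6) {
    stop_input("no dynamic range: concentrations show no degradation")
  }
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  # noise-free generator data fit exactly; the perfect-fit warning from
  # summary.lm is expected there and carries no information
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  structure(list(element = element,
                 epsilon_permil = 1000 * slope,
                 se_permil = 1000 * se,
                 ci95_permil = 1000 * as.numeric(ci),
                 r_squared = sm$r.squared,
                 n = nrow(d), intercept = intercept, fit = fit),
            class = "epsilon_fit")
}

#' @export
print.epsilon_fit <- function(x, ...) {
  cat(sprintf(
    "<epsilon_fit> %s: epsilon = %.3f +/- %.3f permil (95%% CI %.3f..%.3f, R2 = %.4f, n = %d)\n",
    x$element, x$epsilon_permil, x$se_permil, x$ci95_permil[1],
    x$ci95_permil[2], x$r_squared, x$n))
  invisible(x)
}

#' Apparent position-specific KIE from a bulk enrichment factor
#'
#' Undoes the dilution of a single reactive position among n positions of
#' the same element: \eqn{AKIE = 1/(1 + n\,\varepsilon/1000)}. The
#' linearization underlying this correction breaks down for strongly
#' fractionating elements; results with \eqn{1 + n\varepsilon/1000 < 0.5}
#' carry a caution note recommending [infer_secondary_average()] instead.
#'
#' @param eps Bulk enrichment factor in permil (or an `enrichment` object).
#' @param n Position count, >= 1.
#' @return List with `akie`, `n`, and optionally `note`.
#' @export
epsilon_to_akie <- function(eps, n) {
  if (inherits(eps, "enrichment")) eps <- eps$epsilon_permil
  if (!is_count(n, 1L)) stop_input("`n` must be a positive integer")
  denom <- 1 + n * eps / 1000
  if (denom <= 0) {
    stop_input("dilution correction undefined: 1 + n*eps/1000 = ",
               sprintf("%.4g", denom), " <= 0")
  }
  out <- list(akie = 1 / denom, n = n)
  if (denom < 0.5) {
    out$note <- paste0("beyond the applicability of the dilution ",
                       "correction; use infer_secondary_average() instead")
  }
  out
}

#' Write an epsilon fit report as CSV
#'
#' @param fits List of [rayleigh_fit()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epsilon_fits <- function(fits, path) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(element = f$element, epsilon_permil = f$epsilon_permil,
               se_permil = f$se_permil, ci_lo = f$ci95_permil[1],
               ci_hi = f$ci95_permil[2], r_squared = f$r_squared, n = f$n,
               through_origin = !f$intercept)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
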