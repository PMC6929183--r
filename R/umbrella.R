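# Model free-energy profiles A(z) and Metropolis sampling of biased
# umbrella windows along the proton-transfer reaction coordinate.

#' Model free-energy profile specification
#'
#' Functional forms of the underlying profile A(z) used to generate biased
#' window samples: `harmonic` A(z) = kappa z^2 / 2; `double_well`
#' A(z) = height ((z/width)^2 - 1)^2 with minima at +/- width and barrier
#' `height` at z = 0; `table` linear interpolation of supplied (z, A)
#' points.
#'
#' @param form One of "harmonic", "double_well", "table".
#' @param kappa Harmonic curvature, kcal mol^-1 A^-2.
#' @param height Double-well barrier height, kcal/mol.
#' @param width Double-well minimum position, Angstrom.
#' @param z,A Table form: coordinate and free-energy vectors.
#' @param temperature Temperature in K.
#' @return Object of class `profile_spec`.
#' @export
profile_spec <- function(form = c("harmonic", "double_well", "table"),
                         kappa = 20, height = 6, width = 1,
                         z = NULL, A = NULL, temperature = 298) {
  form <- match.arg(form)
  if (temperature <= 0) stop_input("temperature must be positive")
  if (form == "table") {
    if (is.null(z) || is.null(A) || length(z) != length(A) ||
        length(z) < 2L || any(!is.finite(A))) {
      stop_input("table form needs finite aligned `z` and `A` vectors")
    }
    o <- order(z); z <- z[o]; A <- A[o]
  }
  structure(list(form = form, kappa = kappa, height = height, width = width,
                 z = z, A = A, temperature = temperature),
            class = "profile_spec")
}

#' Evaluate a model profile
#'
#' @param spec A [profile_spec()].
#' @param z Coordinate value(s), Angstrom.
#' @return A(z) in kcal/mol (table form: linear interpolation, flat
#'   extension beyond the tabulated range).
#' @export
eval_profile <- function(spec, z) {
  stopifnot(inherits(spec, "profile_spec"))
  switch(spec$form,
         harmonic = 0.5 * spec$kappa * z^2,
         double_well = spec$height * ((z / spec$width)^2 - 1)^2,
         table = stats::approx(spec$z, spec$A, xout = z, rule = 2)$y)
}

#' One umbrella window of biased samples
#'
#' @param id Window identifier.
#' @param center Bias center z0, Angstrom.
#' @param bias_k Harmonic bias force constant, kcal mol^-1 A^-2, > 0.
#' @param samples Numeric vector of sampled z values.
#' @param acceptance Metropolis acceptance rate of the production phase.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(id, center, bias_k, samples, acceptance = NA) {
  if (bias_k <= 0) stop_input("bias_k must be positive")
  if (!length(samples)) stop_input("a window needs at least one sample")
  structure(list(id = id, center = center, bias_k = bias_k,
                 samples = as.numeric(samples), n = length(samples),
                 acceptance = acceptance),
            class = "umbrella_window")
}

# One-dimensional Metropolis chain on energy U(z) (kcal/mol) at inverse
# temperature beta; step size tuned to 30-50 % acceptance during a
# discarded burn-in of 10 % of the requested samples.
.metropolis_1d <- function(U, beta, n, init, step = NULL,
                           burn = max(100L, ceiling(0.1 * n))) {
  step <- step %||% max(0.05, sqrt(1 / beta))
  z <- init
  uz <- U(z)
  # burn-in with adaptation every 50 steps
  acc_block <- 0L
  for (i in seq_len(burn)) {
    zp <- z + stats::runif(1, -step, step)
    up <- U(zp)
    if (log(stats::runif(1)) < -beta * (up - uz)) {
      z <- zp; uz <- up; acc_block <- acc_block + 1L
    }
    if (i %% 50L == 0L) {
      rate <- acc_block / 50
      if (rate < 0.3) step <- step * 0.8
      if (rate > 0.5) step <- step * 1.25
      acc_block <- 0L
    }
  }
  out <- numeric(n)
  acc <- 0L
  for (i in seq_len(n)) {
    zp <- z + stats::runif(1, -step, step)
    up <- U(zp)
    if (log(stats::runif(1)) < -beta * (up - uz)) {
      z <- zp; uz <- up; acc <- acc + 1L
    }
    out[i] <- z
  }
  list(samples = out, acceptance = acc / n, step = step)
}

#' Sample umbrella windows from a model profile
#'
#' Metropolis samples from densities proportional to
#' \eqn{\exp(-\beta[A(z) + k_b (z - z_0)^2/2])} for each window center. A
#' warning is recorded (attribute `overlap_warning`) when adjacent windows'
#' sample ranges do not overlap, in which case the downstream WHAM problem
#' is ill-conditioned.
#'
#' @param profile A [profile_spec()] (its temperature sets beta).
#' @param centers Ordered window centers, Angstrom.
#' @param bias_k Bias force constant, kcal mol^-1 A^-2 (recycled).
#' @param n_per_window Samples per window, >= 100.
#' @param seed Integer seed (one RNG stream for the whole call), or NULL.
#' @return List of [umbrella_window()] objects; attributes `seed`,
#'   `temperature`, `overlap_warning`.
#' @export
sample_umbrella_windows <- function(profile, centers, bias_k, n_per_window,
                                    seed = NULL) {
  stopifnot(inherits(profile, "profile_spec"))
  if (is.unsorted(centers, strictly = TRUE)) {
    stop_input("`centers` must be strictly increasing")
  }
  if (any(bias_k <= 0)) stop_input("bias_k must be positive")
  if (!is_count(n_per_window, 100L)) {
    stop_input("`n_per_window` must be an integer >= 100")
  }
  bias_k <- rep_len(bias_k, length(centers))
  beta <- 1 / (.kB_kcal() * profile$temperature)
  windows <- with_seed(seed, {
    lapply(seq_along(centers), function(k) {
      c0 <- centers[k]; kb <- bias_k[k]
      U <- function(z) eval_profile(profile, z) + 0.5 * kb * (z - c0)^2
      res <- .metropolis_1d(U, beta, n_per_window, init = c0,
                            step = 2 * sqrt(1 / (beta * kb)))
      umbrella_window(k, c0, kb, res$samples, res$acceptance)
    })
  })
  overlap_warn <- FALSE
  if (length(windows) > 1L) {
    for (k in seq_len(length(windows) - 1L)) {
      a <- range(windows[[k]]$samples)
      b <- range(windows[[k + 1L]]$samples)
      if (a[2] < b[1] || b[2] < a[1]) {
        overlap_warn <- TRUE
        warning(sprintf(
          "windows %d and %d have non-overlapping samples; WHAM will be ill-conditioned",
          k, k + 1L), call. = FALSE)
      }
    }
  }
  structure(windows, seed = seed, temperature = profile$temperature,
            overlap_warning = overlap_warn)
}

#' Write / read umbrella windows as long-format TSV
#'
#' Columns: window_id, center, bias_k, sample.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param path TSV path.
#' @return `path` (write) or the window list (read).
#' @export
write_umbrella_tsv <- function(windows, path) {
  tab <- do.call(rbind, lapply(windows, function(w) {
    data.frame(window_id = w$id, center = w$center, bias_k = w$bias_k,
               sample = w$samples)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_umbrella_tsv
#' @export
read_umbrella_tsv <- function(path) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$window_id), function(d) {
    umbrella_window(d$window_id[1], d$center[1], d$bias_k[1], d$sample)
  })
}
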