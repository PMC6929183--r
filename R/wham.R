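# Reaction-coordinate geometry and the weighted histogram analysis method
# (WHAM) for merging biased umbrella windows into one potential of mean
# force.

#' Proton-transfer reaction coordinate specification
#'
#' The antisymmetric combination z = r(donor) - r(acceptor) of the breaking
#' C1-H1 bond and the forming H1-O bond: negative on the reactant side
#' (C-H shorter than H...O), positive on the product side.
#'
#' @param donor Atom-index pair (C1, H1) of the breaking bond.
#' @param acceptor Atom-index pair (H1, O) of the forming bond; the shared
#'   (transferring) atom must be `donor[2] == acceptor[1]`.
#' @return Object of class `reaction_coordinate_spec`.
#' @export
reaction_coordinate_spec <- function(donor, acceptor) {
  idx <- c(donor, acceptor)
  if (length(donor) != 2L || length(acceptor) != 2L) {
    stop_input("donor and acceptor must each be an index pair")
  }
  if (donor[2] != acceptor[1]) {
    stop_input("the transferring atom must close the donor and acceptor ",
               "pairs (donor[2] == acceptor[1])")
  }
  if (length(unique(idx)) != 3L) {
    stop_input("donor, transferring and acceptor atoms must be distinct")
  }
  structure(list(donor = as.integer(donor), acceptor = as.integer(acceptor)),
            class = "reaction_coordinate_spec")
}

#' Evaluate the reaction coordinate on a geometry
#'
#' @param geometry N x 3 coordinate matrix (Angstrom) or a
#'   [molecular_system()].
#' @param spec A [reaction_coordinate_spec()].
#' @return z in Angstrom.
#' @export
reaction_coordinate <- function(geometry, spec) {
  stopifnot(inherits(spec, "reaction_coordinate_spec"))
  co <- if (inherits(geometry, "molecular_system")) geometry$coords
        else as.matrix(geometry)
  dist <- function(i, j) sqrt(sum((co[i, ] - co[j, ])^2))
  r1 <- dist(spec$donor[1], spec$donor[2])
  r2 <- dist(spec$acceptor[1], spec$acceptor[2])
  if (r1 < 1e-9 || r2 < 1e-9) stop_input("coincident atoms in geometry")
  r1 - r2
}

# Freedman-Diaconis bin count on pooled samples, clamped to [10, 400].
.fd_bins <- function(x) {
  iqr <- stats::IQR(x)
  w <- 2 * iqr * length(x)^(-1 / 3)
  if (!is.finite(w) || w <= 0) return(50L)
  max(10L, min(400L, ceiling(diff(range(x)) / w)))
}

#' Weighted histogram analysis of umbrella windows
#'
#' Solves the WHAM self-consistent equations on a binned grid:
#' \deqn{P(z_m) \propto \sum_k n_k(z_m) \Big/ \sum_k N_k e^{\beta(F_k - W_k(z_m))}}
#' \deqn{e^{-\beta F_k} = \sum_m P(z_m) e^{-\beta W_k(z_m)}}
#' iterated until the largest change in any window free energy F_k falls
#' below `tol`. The F_k gauge is fixed by F_1 = 0 and the reported profile
#' A(z) = -kBT ln P(z) is shifted so its minimum is zero.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param th A [thermo_settings()].
#' @param bins Bin count or breaks vector; default Freedman-Diaconis on the
#'   pooled samples.
#' @param tol Convergence tolerance on F_k, kcal/mol.
#' @param max_iter Iteration cap; reaching it raises a condition of class
#'   `isokie_wham_nonconverged` carrying the partial profile.
#' @return Object of class `pmf_profile`: list with `z` (bin centers), `A`
#'   (kcal/mol, min-shifted, NA for empty bins), `F_k`, `counts` (window x
#'   bin matrix), `iterations`, `residual`, `converged`, `ill_conditioned`,
#'   `temperature`.
#' @export
wham <- function(windows, th, bins = NULL, tol = 1e-6, max_iter = 1e5) {
  stopifnot(length(windows) >= 1L, inherits(th, "thermo_settings"))
  beta <- th$beta
  pooled <- unlist(lapply(windows, `[[`, "samples"))
  breaks <- if (is.null(bins)) {
    seq(min(pooled), max(pooled), length.out = .fd_bins(pooled) + 1L)
  } else if (length(bins) == 1L) {
    seq(min(pooled), max(pooled), length.out = as.integer(bins) + 1L)
  } else sort(bins)
  z <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nw <- length(windows)
  counts <- t(vapply(windows, function(w) {
    tabulate(findInterval(w$samples, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = length(z))
  }, numeric(length(z))))
  n_k <- vapply(windows, `[[`, numeric(1), "n")
  # overlap diagnostic: windows adjacent along the coordinate (ordered by
  # bias center) must share occupied bins
  ill <- FALSE
  if (nw > 1L) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    for (k in seq_len(nw - 1L)) {
      if (!any(counts[ord[k], ] > 0 & counts[ord[k + 1L], ] > 0)) ill <- TRUE
    }
    if (ill) warning("adjacent windows share no occupied bins; ",
                     "WHAM is ill-conditioned", call. = FALSE)
  }
  # bias energies at bin centers, window x bin
  w_km <- t(vapply(windows, function(w) 0.5 * w$bias_k * (z - w$center)^2,
                   numeric(length(z))))
  tot_m <- colSums(counts)
  log_tot <- ifelse(tot_m > 0, log(tot_m), -Inf)
  log_nk <- log(n_k)
  f_k <- numeric(nw)                      # beta * F_k
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    # log denominator per bin: logsumexp_k [log N_k + f_k - beta W_k(z_m)]
    mat <- sweep(-beta * t(w_km), 2L, log_nk + f_k, `+`)  # bin x window
    log_p <- log_tot - row_logsumexp(mat)
    f_new <- -row_logsumexp(sweep(-beta * w_km, 2L, log_p, `+`))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f_k)) / beta
    f_k <- f_new
    if (resid < tol) break
    if (iter >= max_iter) {
      partial <- .pmf_profile(z, log_p, f_k / beta, counts, iter, resid,
                              FALSE, ill, th$temperature)
      cond <- structure(
        class = c("isokie_wham_nonconverged", "error", "condition"),
        list(message = sprintf(
          "WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
          iter, resid),
          call = NULL, profile = partial))
      stop(cond)
    }
  }
  mat <- sweep(-beta * t(w_km), 2L, log_nk + f_k, `+`)
  log_p <- log_tot - row_logsumexp(mat)
  .pmf_profile(z, log_p, f_k / beta, counts, iter, resid, TRUE, ill,
               th$temperature)
}

.pmf_profile <- function(z, log_p, F_k, counts, iterations, residual,
                         converged, ill, temperature) {
  kt <- .kB_kcal() * temperature
  a <- -kt * log_p
  a[!is.finite(a)] <- NA_real_
  a <- a - min(a, na.rm = TRUE)
  structure(list(z = z, A = a, F_k = F_k, counts = counts,
                 iterations = iterations, residual = residual,
                 converged = converged, ill_conditioned = ill,
                 temperature = temperature),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "<pmf_profile> %d bins on [%.3f, %.3f] A; %d windows; %s after %d iterations (residual %.2g)\n",
    length(x$z), min(x$z), max(x$z), nrow(x$counts),
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$residual))
  invisible(x)
}

#' Free-energy barrier from a PMF profile
#'
#' The barrier is the highest interior point of A(z) beyond the reactant
#' basin minus the minimum of A(z) within the reactant range. A profile
#' whose maximum sits at the edge of the sampled range (monotone ascent,
#' no turning point) raises a "no barrier" error.
#'
#' @param p A `pmf_profile`.
#' @param reactant_range Length-2 z interval containing the reactant basin.
#' @return Barrier height in kcal/mol, with attributes `z_ts` and `z_min`.
#' @export
barrier_height <- function(p, reactant_range) {
  stopifnot(inherits(p, "pmf_profile"), length(reactant_range) == 2L)
  ok <- is.finite(p$A)
  z <- p$z[ok]; a <- p$A[ok]
  in_r <- z >= min(reactant_range) & z <= max(reactant_range)
  if (!any(in_r)) stop_input("reactant range contains no sampled bins")
  a_min <- min(a[in_r])
  z_min <- z[in_r][which.min(a[in_r])]
  beyond <- which(z > max(reactant_range))
  if (length(beyond) < 3L) stop_input("profile does not extend beyond the reactant range")
  i_max <- beyond[which.max(a[beyond])]
  if (i_max >= length(z) - 1L) {
    stop_input("no barrier: profile is monotone up to the sampled edge")
  }
  structure(a[i_max] - a_min, z_ts = z[i_max], z_min = z_min)
}

#' Write / read a PMF profile as TSV
#'
#' Columns: z, A_kcal_mol.
#'
#' @param p A `pmf_profile`.
#' @param path TSV path.
#' @return `path` (write); a data.frame (read).
#' @export
write_pmf_tsv <- function(p, path) {
  utils::write.table(data.frame(z = p$z, A_kcal_mol = p$A), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pmf_tsv
#' @export
read_pmf_tsv <- function(path) utils::read.delim(path)
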