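# From position-specific KIEs to element-wise bulk quantities: unweighted
# averages, enrichment factors, model-ensemble statistics, the hybrid
# primary/secondary assembly, and the inverse back-calculation of the
# secondary average implied by a measured bulk value.

#' Position-specific kinetic isotope effect record
#'
#' @param position Position label, e.g. "H1", "C2", "Cl2".
#' @param element Element symbol ("C", "Cl", "H", or NA).
#' @param kie KIE value (light/heavy rate ratio), > 0.
#' @param provenance One of "semiclassical", "pi", "assumed".
#' @param se Optional standard error of the KIE.
#' @param components Optional list of retained components (see
#'   [semiclassical_kie()], [pi_kie()]).
#' @return Object of class `position_kie`.
#' @export
position_kie <- function(position, element, kie,
                         provenance = c("semiclassical", "pi", "assumed"),
                         se = NA_real_, components = NULL) {
  provenance <- match.arg(provenance)
  if (!is.numeric(kie) || length(kie) != 1L || !is.finite(kie) || kie <= 0) {
    stop_input("`kie` must be a single positive number")
  }
  structure(list(position = as.character(position),
                 element = as.character(element), kie = kie,
                 provenance = provenance, se = se, components = components),
            class = "position_kie")
}

#' @export
print.position_kie <- function(x, ...) {
  cat(sprintf("<position_kie> %s (%s): KIE = %.6g [%s]%s\n", x$position,
              x$element, x$kie, x$provenance,
              if (is.finite(x$se)) sprintf(" +/- %.2g", x$se) else ""))
  invisible(x)
}

.kie_values <- function(records) {
  vapply(records, function(r) {
    stopifnot(inherits(r, "position_kie"))
    r$kie
  }, numeric(1))
}

.kie_elements <- function(records) {
  vapply(records, function(r) r$element, character(1))
}

#' Element-wise bulk (compound-average) KIE
#'
#' Unweighted arithmetic mean of position-specific KIEs of a single element;
#' symmetry-equivalent positions are entered individually (the
#' hexachlorocyclohexane skeleton carries six positions per element).
#'
#' @param records List of [position_kie()] records, all of one element.
#' @return Object of class `bulk_kie` with fields `element`, `kie_av`, `n`,
#'   `records`.
#' @export
average_kie <- function(records) {
  if (!length(records)) stop_input("need at least one position record")
  el <- unique(.kie_elements(records))
  if (length(el) != 1L) {
    stop_input("mixed elements in one bulk average: ",
               paste(el, collapse = ", "))
  }
  vals <- .kie_values(records)
  structure(list(element = el, kie_av = mean(vals), n = length(vals),
                 records = records),
            class = "bulk_kie")
}

#' @export
print.bulk_kie <- function(x, ...) {
  cat(sprintf("<bulk_kie> %s: KIE_av = %.6g over %d position(s)\n",
              x$element, x$kie_av, x$n))
  invisible(x)
}

#' Bulk enrichment factor from a bulk KIE
#'
#' \deqn{\varepsilon = (1 - KIE_{av}) \cdot 1000\ permil}
#' Normal isotope effects (KIE_av > 1) give negative enrichment factors.
#'
#' @param b A [bulk_kie()].
#' @return Object of class `enrichment` with fields `element`,
#'   `epsilon_permil`, `kie_av`, `n`.
#' @export
enrichment_from_kie <- function(b) {
  stopifnot(inherits(b, "bulk_kie"))
  structure(list(element = b$element,
                 epsilon_permil = (1 - b$kie_av) * 1000,
                 kie_av = b$kie_av, n = b$n),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("<enrichment> %s: epsilon = %.4g permil (KIE_av = %.6g)\n",
              x$element, x$epsilon_permil, x$kie_av))
  invisible(x)
}

#' Mean and spread of one position's KIE across model variants
#'
#' Unweighted mean and sample standard deviation of a position-specific KIE
#' predicted by several solvation-model variants.
#'
#' @param per_model List of [position_kie()] records (same position, >= 2
#'   entries) or a numeric vector of KIE values.
#' @return List with `mean`, `sd`, `n`.
#' @export
model_ensemble_stats <- function(per_model) {
  vals <- if (is.numeric(per_model)) per_model else {
    pos <- vapply(per_model, function(r) r$position, character(1))
    if (length(unique(pos)) != 1L) {
      stop_input("ensemble statistics need a single position; got ",
                 paste(unique(pos), collapse = ", "))
    }
    .kie_values(per_model)
  }
  if (length(vals) < 2L) {
    stop_input("sample standard deviation undefined for fewer than 2 models")
  }
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Hybrid primary/secondary bulk assembly
#'
#' Combines one path-integral primary (reactive-position) KIE with assumed
#' or model-derived secondary KIEs for the remaining positions of the same
#' element, averages, and applies the enrichment-factor formula. A note is
#' attached when the resulting |epsilon| exceeds 300 permil, outside the
#' range of typical bulk compound-specific measurements.
#'
#' @param primary A [position_kie()] with provenance "pi".
#' @param secondary List of [position_kie()] records for the n - 1
#'   non-reactive positions (same element).
#' @return List with components `bulk` ([average_kie()] result) and
#'   `enrichment` ([enrichment_from_kie()] result); the latter carries a
#'   `note` field when flagged.
#' @export
hybrid_bulk <- function(primary, secondary) {
  stopifnot(inherits(primary, "position_kie"))
  if (primary$provenance != "pi") {
    stop_input("hybrid assembly expects a path-integral primary record ",
               "(provenance 'pi'), got '", primary$provenance, "'")
  }
  el <- unique(c(primary$element, .kie_elements(secondary)))
  if (length(el) != 1L) {
    stop_input("element mismatch between primary and secondary records")
  }
  bulk <- average_kie(c(list(primary), secondary))
  enr <- enrichment_from_kie(bulk)
  if (abs(enr$epsilon_permil) > 300) {
    enr$note <- paste0("epsilon of ", sprintf("%.0f", enr$epsilon_permil),
                       " permil is overestimated relative to typical bulk ",
                       "measurements; the primary KIE is likely too large")
  }
  list(bulk = bulk, enrichment = enr)
}

#' Secondary-KIE average implied by a bulk enrichment factor
#'
#' Inverts the hybrid assembly: given a measured bulk enrichment factor, an
#' assumed primary KIE and the element's position count n, returns the
#' average secondary KIE \eqn{\bar s = (n\,KIE_{av} - primary)/(n-1)} with
#' \eqn{KIE_{av} = 1 - \varepsilon/1000}, flagging inverse effects
#' (\eqn{\bar s < 1}).
#'
#' @param bulk_eps An [enrichment_from_kie()] result or epsilon in permil.
#' @param primary_kie Assumed primary KIE (> 0).
#' @param n Positions of the element in the molecule (>= 2).
#' @return List with `secondary_mean`, `inverse` (logical), `kie_av`.
#' @export
infer_secondary_average <- function(bulk_eps, primary_kie, n) {
  eps <- if (inherits(bulk_eps, "enrichment")) bulk_eps$epsilon_permil
         else as.numeric(bulk_eps)
  if (!is_count(n, 2L)) stop_input("`n` must be an integer >= 2")
  if (primary_kie <= 0) stop_input("`primary_kie` must be positive")
  kie_av <- 1 - eps / 1000
  s <- (n * kie_av - primary_kie) / (n - 1)
  if (s <= 0) {
    stop_input(sprintf(
      paste0("non-physical secondary average %.4g: primary KIE %.4g cannot ",
             "be reconciled with bulk epsilon %.4g permil at n = %d"),
      s, primary_kie, eps, n))
  }
  list(secondary_mean = s, inverse = s < 1, kie_av = kie_av)
}

#' Write a position-KIE table as CSV
#'
#' Columns: position, element, KIE, nu_ratio, g_TS, g_R, T, provenance.
#' Components absent from a record are written as NA.
#'
#' @param records List of [position_kie()] records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kie_table <- function(records, path) {
  get_comp <- function(r, what) {
    v <- r$components[[what]]
    if (is.null(v)) NA_real_ else v
  }
  tab <- data.frame(
    position = vapply(records, function(r) r$position, character(1)),
    element = .kie_elements(records),
    KIE = .kie_values(records),
    nu_ratio = vapply(records, get_comp, numeric(1), "nu_ratio"),
    g_TS = vapply(records, get_comp, numeric(1), "g_ts"),
    g_R = vapply(records, get_comp, numeric(1), "g_r"),
    T = vapply(records, get_comp, numeric(1), "temperature"),
    provenance = vapply(records, function(r) r$provenance, character(1)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
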