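#' @include AllClasses.R fitting.R
NULL

#' Bragg's law d-spacing
#'
#' First-order (or order `n`) Bragg relation `2 d sin(theta) = n lambda`
#' solved for the interplanar spacing: `d = n * lambda / (2 sin(theta))`.
#'
#' @param twoSinTheta dimensionless diffraction abscissa `2 sin(theta)`, > 0.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param order diffraction order `n`, integer >= 1 (default 1).
#' @return d-spacing in Angstrom, vectorized over `twoSinTheta`.
#' @examples
#' braggDSpacing(0.18561, 1.54029)   # ~8.30 Angstrom
#' @export
braggDSpacing <- function(twoSinTheta, wavelength, order = 1L) {
  if (any(!is.finite(twoSinTheta)) || any(twoSinTheta <= 0))
    stop("twoSinTheta must be finite and > 0", call. = FALSE)
  if (!.scalarOk(wavelength) || wavelength <= 0)
    stop("wavelength must be a positive scalar", call. = FALSE)
  if (order < 1 || order != round(order))
    stop("order must be an integer >= 1", call. = FALSE)
  order * wavelength / twoSinTheta
}

#' Fit the X-ray wavelength from a peak table
#'
#' Least-squares line of reciprocal d-spacing `1/d` against `2 sin(theta)`.
#' By Bragg's law (first order) `1/d = (1/lambda) * 2 sin(theta)`, so the
#' fitted slope is the reciprocal wavelength. The default convention forces
#' the line through the origin, which is what the law itself prescribes;
#' `throughOrigin = FALSE` frees the intercept (useful as a zero-offset
#' diagnostic). The reported `r` is the Pearson correlation of the two
#' columns regardless of convention.
#'
#' @param table a [PeakTable-class] with at least 3 peaks carrying `recipD`.
#' @param throughOrigin logical, force the intercept to zero (default TRUE).
#' @return a [BraggFit-class].
#' @export
fitBraggWavelength <- function(table, throughOrigin = TRUE) {
  stopifnot(is(table, "PeakTable"))
  p <- table@peaks[!is.na(table@peaks$recipD), , drop = FALSE]
  if (nrow(p) < 3)
    stop("need at least 3 peaks with reciprocal d-spacings", call. = FALSE)
  x <- p$twoSinTheta
  y <- p$recipD
  if (stats::var(x) == 0)
    stop("degenerate peak table: zero variance in 2sin(theta)", call. = FALSE)
  if (throughOrigin) {
    slope <- sum(x * y) / sum(x * x)
    intercept <- 0
  } else {
    cf <- stats::coef(stats::lm(y ~ x))
    intercept <- unname(cf[1])
    slope <- unname(cf[2])
  }
  new("BraggFit", wavelength = 1 / slope, slope = slope,
      intercept = intercept, r = stats::cor(x, y), nPeaks = nrow(p),
      throughOrigin = throughOrigin, dose = table@dose)
}

#' Relative intensities of peaks against the strongest peak
#'
#' Across a set of peak tables (one per dose), fits the through-origin
#' proportionality `I_target = a * I_reference` for each target symbol,
#' expressing the conservation of relative peak intensities under
#' irradiation. The reported `r` per target is the Pearson correlation of
#' the unconstrained `(I_reference, I_target)` pairing.
#'
#' @param tables list of [PeakTable-class] objects (>= 3) carrying
#'   intensities for the reference and all targets.
#' @param referenceSymbol symbol of the reference (strongest) peak.
#' @param targetSymbols character vector of target peak symbols.
#' @return named list (per target symbol) of
#'   `list(model = LinearLinkModel, r = numeric)`.
#' @export
relativeIntensities <- function(tables, referenceSymbol, targetSymbols) {
  if (length(tables) < 3)
    stop("need at least 3 peak tables", call. = FALSE)
  getI <- function(tab, sym) {
    p <- tab@peaks
    i <- match(sym, p$symbol)
    if (is.na(i) || is.na(p$intensity[i]))
      stop(sprintf("missing intensity for symbol '%s' at dose %g kGy",
                   sym, tab@dose), call. = FALSE)
    p$intensity[i]
  }
  iref <- vapply(tables, getI, numeric(1), sym = referenceSymbol)
  out <- lapply(targetSymbols, function(sym) {
    itar <- vapply(tables, getI, numeric(1), sym = sym)
    a <- sum(iref * itar) / sum(iref * iref)
    r <- if (stats::var(iref) > 0 && stats::var(itar) > 0)
      stats::cor(iref, itar) else NA_real_
    list(model = linearLinkModel(slope = a), r = r)
  })
  names(out) <- targetSymbols
  out
}

#' Match peaks across diffractograms by position
#'
#' Groups peaks across tables whose `2 sin(theta)` positions agree within an
#' absolute tolerance, keyed by the first (reference) table's symbols. Each
#' group collects at most one peak per table; two peaks of one table falling
#' within tolerance of the same group is an ambiguity and raises an error.
#'
#' @param tables list of [PeakTable-class] objects; the first is the
#'   reference.
#' @param tolerance absolute tolerance on `2 sin(theta)` (default 5e-4,
#'   matching the shared absolute abscissa grid of tabulated
#'   diffractograms).
#' @return `list(groups =, unmatched =)`: `groups` is a named list (by
#'   reference symbol) of data.frames with columns `dose, symbol,
#'   twoSinTheta, recipD, intensity`; `unmatched` is one data.frame of peaks
#'   assigned to no group.
#' @export
matchPeaks <- function(tables, tolerance = 5e-4) {
  if (!length(tables)) stop("no peak tables given", call. = FALSE)
  if (!.scalarOk(tolerance) || tolerance < 0)
    stop("tolerance must be >= 0", call. = FALSE)
  ref <- tables[[1]]
  centers <- ref@peaks$twoSinTheta
  keys <- ref@peaks$symbol
  rowOf <- function(tab, i) {
    p <- tab@peaks[i, , drop = FALSE]
    data.frame(dose = tab@dose, symbol = p$symbol,
               twoSinTheta = p$twoSinTheta, recipD = p$recipD,
               intensity = p$intensity, stringsAsFactors = FALSE)
  }
  groups <- lapply(seq_along(centers), function(i) rowOf(ref, i))
  names(groups) <- keys
  memberOf <- lapply(seq_along(centers), function(i) 1L)  # table indices
  unmatched <- list()
  for (t in seq_along(tables)[-1]) {
    tab <- tables[[t]]
    for (i in seq_len(nrow(tab@peaks))) {
      d <- abs(centers - tab@peaks$twoSinTheta[i])
      hit <- which(d <= tolerance)
      if (length(hit) > 1)
        stop(sprintf(
          "ambiguous match: peak '%s' (dose %g) within tolerance of groups %s",
          tab@peaks$symbol[i], tab@dose,
          paste(keys[hit], collapse = ", ")), call. = FALSE)
      if (length(hit) == 1) {
        if (t %in% memberOf[[hit]])
          stop(sprintf(
            "ambiguous match: two peaks of table %d (dose %g) within tolerance of group '%s'",
            t, tab@dose, keys[hit]), call. = FALSE)
        groups[[hit]] <- rbind(groups[[hit]], rowOf(tab, i))
        memberOf[[hit]] <- c(memberOf[[hit]], t)
      } else {
        unmatched[[length(unmatched) + 1]] <- rowOf(tab, i)
      }
    }
  }
  list(groups = groups,
       unmatched = if (length(unmatched)) do.call(rbind, unmatched)
                   else data.frame(dose = numeric(), symbol = character(),
                                   twoSinTheta = numeric(),
                                   recipD = numeric(),
                                   intensity = numeric()))
}

#' Summarize fitted wavelengths across doses
#'
#' Arithmetic mean of the fitted wavelengths and the maximum absolute
#' relative deviation from that mean, in percent — the spread the X-ray
#' source's emission width imposes on per-dose wavelength estimates.
#'
#' @param fits list of [BraggFit-class] objects (>= 2).
#' @return `list(mean = Angstrom, spreadPct = percent)`.
#' @examples
#' \dontrun{
#' summarizeWavelengths(lapply(table1Fixture(), fitBraggWavelength))
#' }
#' @export
summarizeWavelengths <- function(fits) {
  if (!length(fits)) stop("empty input", call. = FALSE)
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  lam <- vapply(fits, function(f) {
    stopifnot(is(f, "BraggFit")); f@wavelength }, numeric(1))
  m <- mean(lam)
  list(mean = m, spreadPct = 100 * max(abs(lam - m)) / m)
}
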