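#' @include AllClasses.R models.R
NULL

## default study grids: electron-beam and gamma experiments
.EBEAM_GRID <- c(0, 25, 50, 100, 150, 200, 300, 400)
.GAMMA_GRID <- c(0, 5, 15, 20, 40, 50)

#' Default dose grids
#'
#' The electron-beam grid (0-400 kGy) and the gamma-irradiation grid
#' (0-50 kGy) used throughout the simulations, mirroring the two
#' irradiation experiments.
#'
#' @return numeric dose grid in kGy.
#' @export
ebeamDoseGrid <- function() .EBEAM_GRID

#' @rdname ebeamDoseGrid
#' @export
gammaDoseGrid <- function() .GAMMA_GRID

.sortedGrid <- function(cfg) sort(cfg@doseGrid)

#' Simulate property-vs-dose relaxation series
#'
#' Generates `replicates` dose series from an exponential relaxation model
#' plus iid additive Gaussian noise of standard deviation `noiseSd`. The
#' default generating model is the fitted pH curve
#' `pH(D) = 0.23 exp(-D/73.4) + 6.75`; the default grid is the electron-beam
#' grid. Pure function of the configuration: the same seed reproduces the
#' same series.
#'
#' @param cfg a [SimulationConfig-class]; `modelParams` must be a
#'   [RelaxationModel-class] (default pH model when `NULL`).
#' @param label,units series annotation.
#' @return list of [DoseSeries-class], one per replicate.
#' @examples
#' cfg <- simulationConfig(seed = 1, doseGrid = ebeamDoseGrid(),
#'                         noiseSd = 0.01, replicates = 2)
#' simulateRelaxationSeries(cfg)[[1]]
#' @export
simulateRelaxationSeries <- function(cfg, label = "pH", units = "") {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  m <- if (is.null(cfg@modelParams)) relaxationModel(6.98, 6.75, 73.4)
       else cfg@modelParams
  if (!is(m, "RelaxationModel"))
    stop("modelParams must be a RelaxationModel", call. = FALSE)
  d <- .sortedGrid(cfg)
  mu <- evalRelaxation(m, d)
  set.seed(cfg@seed)
  lapply(seq_len(cfg@replicates), function(r)
    doseSeries(label, d, mu + stats::rnorm(length(d), 0, cfg@noiseSd), units))
}

#' Simulate a pair of linearly linked series
#'
#' Generates the predictor series from the relaxation model of the
#' configuration (with its noise), then the response as the affine link of
#' the observed predictor plus independent Gaussian noise `linkNoiseSd`.
#' Models the paired behaviour of pH and melting point (raw link) or of
#' water content and UV content (deviation link).
#'
#' @param cfg a [SimulationConfig-class] for the predictor.
#' @param link a [LinearLinkModel-class].
#' @param linkNoiseSd standard deviation of the response noise (response
#'   units), >= 0.
#' @param labels character(2), predictor and response labels.
#' @return list of `list(predictor = DoseSeries, response = DoseSeries)`,
#'   one per replicate.
#' @export
simulateLinkedSeries <- function(cfg, link, linkNoiseSd = 0,
                                 labels = c("pH", "Tf")) {
  stopifnot(is(cfg, "SimulationConfig"), is(link, "LinearLinkModel"))
  validObject(cfg); validObject(link)
  if (!.scalarOk(linkNoiseSd) || linkNoiseSd < 0)
    stop("linkNoiseSd must be >= 0", call. = FALSE)
  m <- if (is.null(cfg@modelParams)) relaxationModel(6.98, 6.75, 73.4)
       else cfg@modelParams
  if (!is(m, "RelaxationModel"))
    stop("modelParams must be a RelaxationModel", call. = FALSE)
  d <- .sortedGrid(cfg)
  mu <- evalRelaxation(m, d)
  set.seed(cfg@seed)
  lapply(seq_len(cfg@replicates), function(r) {
    x <- mu + stats::rnorm(length(d), 0, cfg@noiseSd)
    y <- evalLinearLink(link, x) + stats::rnorm(length(d), 0, linkNoiseSd)
    list(predictor = doseSeries(labels[1], d, x),
         response = doseSeries(labels[2], d, y))
  })
}

#' Simulate peak-intensity series versus dose
#'
#' Generates diffraction-peak intensities from the sigmoid-modulated
#' intensity-dose model with multiplicative Gaussian noise (`noiseSd` is
#' the relative standard deviation, e.g. 0.01 for 1% noise). When several
#' peaks are requested they share the optimized dose and sigmoid shape and
#' differ only by a proportional scale, so relative intensities are
#' conserved across doses by construction.
#'
#' @param cfg a [SimulationConfig-class]; `modelParams` must be an
#'   [IntensityDoseModel-class] (default: `iInit = 100`, `D0 = 21.7`,
#'   sigmoid `fMax = 0.05`, `fMin = -0.08`, `alpha = 0.15`, `Dc = 35` on
#'   the gamma grid).
#' @param scales numeric vector of per-peak proportionality factors
#'   (default 1, a single peak).
#' @return list over replicates; each element a named list of
#'   [DoseSeries-class], one per peak.
#' @export
simulateIntensitySeries <- function(cfg, scales = 1) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  m <- if (is.null(cfg@modelParams))
    intensityDoseModel(100, 21.7,
                       specificFunctionParams(0.05, -0.08, 0.15, 35))
  else cfg@modelParams
  if (!is(m, "IntensityDoseModel"))
    stop("modelParams must be an IntensityDoseModel", call. = FALSE)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("scales must be positive", call. = FALSE)
  d <- .sortedGrid(cfg)
  base <- evalIntensityModel(m, d)
  set.seed(cfg@seed)
  lapply(seq_len(cfg@replicates), function(r) {
    out <- lapply(seq_along(scales), function(k) {
      mu <- scales[k] * base
      doseSeries(sprintf("peak%d", k), d,
                 mu * (1 + stats::rnorm(length(d), 0, cfg@noiseSd)),
                 "counts")
    })
    names(out) <- sprintf("peak%d", seq_along(scales))
    out
  })
}

#' Simulate a diffractogram peak table
#'
#' Inverts Bragg's law: for each d-spacing, `2 sin(theta) = lambda / d` with
#' an optional per-peak wavelength jitter emulating the finite width of the
#' X-ray source emission line. `cfg@noiseSd` is the jitter scale in
#' Angstrom (Gaussian sd, or Lorentzian/Cauchy scale with
#' `jitter = "lorentzian"`); the study-scale default is 0.0022 Angstrom
#' (0.14% of the Cu K-alpha wavelength). Reciprocal d-spacings are stored
#' exactly.
#'
#' @param cfg a [SimulationConfig-class] (`doseGrid` unused beyond the first
#'   element, which tags the table's dose).
#' @param dSpacings positive d-spacings in Angstrom.
#' @param wavelength generating wavelength in Angstrom (default 1.5392).
#' @param jitter `"gaussian"` (default) or `"lorentzian"`.
#' @return a [PeakTable-class].
#' @export
simulateDiffractogram <- function(cfg, dSpacings, wavelength = 1.5392,
                                  jitter = c("gaussian", "lorentzian")) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  jitter <- match.arg(jitter)
  if (any(!is.finite(dSpacings)) || any(dSpacings <= 0))
    stop("d-spacings must be positive", call. = FALSE)
  if (!.scalarOk(wavelength) || wavelength <= 0)
    stop("wavelength must be positive", call. = FALSE)
  set.seed(cfg@seed)
  eps <- if (cfg@noiseSd == 0) 0
         else if (jitter == "gaussian")
           stats::rnorm(length(dSpacings), 0, cfg@noiseSd)
         else stats::rcauchy(length(dSpacings), 0, cfg@noiseSd)
  tst <- (wavelength + eps) / dSpacings
  n <- length(dSpacings)
  peakTable(dose = cfg@doseGrid[1],
            symbol = make.unique(LETTERS[(seq_len(n) - 1) %% 26 + 1]),
            twoSinTheta = tst, recipD = 1 / dSpacings,
            source = "simulated")
}
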