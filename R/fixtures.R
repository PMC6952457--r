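#' @include io.R
NULL

## integrity checksums for the packaged tables: sums of the numeric columns
## rounded to 5 dp (robust to formatting, catches any corrupted transcription)
.TABLE1_CHECKSUM <- list(nTables = 6L, nPeaks = 23L)
.TABLE2_CHECKSUM <- list(nRows = 6L)

#' Packaged X-ray peak tables (gamma study)
#'
#' The transcribed X-ray diffraction peak table of metoprolol tartrate
#' before and after gamma irradiation: one table per dose
#' (0, 5, 15, 20, 40, 50 kGy), 23 peaks each (symbols B-X) with the shared
#' `2 sin(theta)` abscissa column and per-dose reciprocal d-spacings in
#' 1/Angstrom. Intensities were not tabulated and are `NA`. Tables are
#' verified against embedded checksums on load.
#'
#' @return list of six [PeakTable-class] objects, named by dose.
#' @examples
#' tabs <- table1Fixture()
#' fitBraggWavelength(tabs[["0"]])
#' @export
table1Fixture <- function() {
  dosesKGy <- c(0, 5, 15, 20, 40, 50)
  paths <- system.file("extdata",
                       sprintf("xrd_peaks_dose%03d.csv", dosesKGy),
                       package = "radstab", mustWork = TRUE)
  tabs <- lapply(paths, readPeakTable)
  names(tabs) <- as.character(dosesKGy)
  ## integrity: shared abscissa, per-table checksum
  if (length(tabs) != .TABLE1_CHECKSUM$nTables ||
      any(vapply(tabs, function(t) nrow(peaks(t)), integer(1)) !=
          .TABLE1_CHECKSUM$nPeaks))
    stop("peak-table fixture corrupted: unexpected dimensions",
         call. = FALSE)
  sums <- vapply(tabs, function(t)
    round(sum(peaks(t)$twoSinTheta) + sum(peaks(t)$recipD), 5), numeric(1))
  expected <- c(`0` = 14.84858, `5` = 14.85141, `15` = 14.85187,
                `20` = 14.83719, `40` = 14.86478, `50` = 14.85332)
  if (!isTRUE(all.equal(unname(sums), unname(expected), tolerance = 1e-8)))
    stop("peak-table fixture corrupted: checksum mismatch", call. = FALSE)
  tabs
}

#' Packaged dose series (gamma study)
#'
#' The tabulated variation of X-ray, UV and thermal quantities with gamma
#' dose: fitted wavelength lambda (Angstrom), UV absorbance, strongest-peak
#' intensity ratio `I0(D)/I0(0)`, and the enthalpies of melting (`dH1`) and
#' stepwise oxidative decomposition (`dH2`) in kJ/g, all on the gamma grid
#' 0-50 kGy. Verified against an embedded checksum on load.
#'
#' @return named list of five [DoseSeries-class] objects: `lambda`,
#'   `uv_absorbance`, `intensity_ratio`, `dH1`, `dH2`.
#' @examples
#' table2Fixture()$lambda
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "xrd_uv_thermal_vs_dose.csv",
                      package = "radstab", mustWork = TRUE)
  tb <- .readTable(path)
  df <- tb$data
  need <- c("dose_kGy", "lambda_A", "uv_absorbance", "intensity_ratio",
            "dH1_kJ_g", "dH2_kJ_g")
  if (!identical(names(df), need) || nrow(df) != .TABLE2_CHECKSUM$nRows)
    stop("dose-series fixture corrupted: unexpected layout", call. = FALSE)
  if (round(sum(as.matrix(df[-1])), 5) != 1384.73039)
    stop("dose-series fixture corrupted: checksum mismatch", call. = FALSE)
  list(
    lambda = doseSeries("lambda", df$dose_kGy, df$lambda_A, "Angstrom"),
    uv_absorbance = doseSeries("uv_absorbance", df$dose_kGy,
                               df$uv_absorbance, ""),
    intensity_ratio = doseSeries("intensity_ratio", df$dose_kGy,
                                 df$intensity_ratio, ""),
    dH1 = doseSeries("dH1", df$dose_kGy, df$dH1_kJ_g, "kJ/g"),
    dH2 = doseSeries("dH2", df$dose_kGy, df$dH2_kJ_g, "kJ/g"))
}
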