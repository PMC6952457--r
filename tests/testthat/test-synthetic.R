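test_that("generators are pure functions of their configuration", {
  cfg <- simulationConfig(7, ebeamDoseGrid(), 0.01, replicates = 3)
  a <- simulateRelaxationSeries(cfg)
  b <- simulateRelaxationSeries(cfg)
  expect_identical(lapply(a, measurements), lapply(b, measurements))
  cfgI <- simulationConfig(8, gammaDoseGrid(), 0.01, replicates = 2)
  expect_identical(
    lapply(simulateIntensitySeries(cfgI)[[1]], measurements),
    lapply(simulateIntensitySeries(cfgI)[[1]], measurements))
  d <- seq(2, 9, length.out = 10)
  cfgD <- simulationConfig(9, 0, 0.0022)
  expect_identical(peaks(simulateDiffractogram(cfgD, d)),
                   peaks(simulateDiffractogram(cfgD, d)))
  # different seeds differ
  expect_false(identical(
    measurements(simulateRelaxationSeries(
      simulationConfig(1, ebeamDoseGrid(), 0.01))[[1]]),
    measurements(simulateRelaxationSeries(
      simulationConfig(2, ebeamDoseGrid(), 0.01))[[1]])))
})

test_that("noiseless generators trace their models exactly", {
  cfg <- simulationConfig(5, ebeamDoseGrid(), 0)
  s <- simulateRelaxationSeries(cfg)[[1]]
  expect_equal(measurements(s),
               evalRelaxation(relaxationModel(6.98, 6.75, 73.4), doses(s)))
  link <- linearLinkModel(12.71, 32.83)
  pair <- simulateLinkedSeries(cfg, link)[[1]]
  expect_equal(measurements(pair$response),
               evalLinearLink(link, measurements(pair$predictor)))
  cfgI <- simulationConfig(5, gammaDoseGrid(), 0)
  ints <- simulateIntensitySeries(cfgI)[[1]][[1]]
  m <- intensityDoseModel(100, 21.7,
                          specificFunctionParams(0.05, -0.08, 0.15, 35))
  expect_equal(measurements(ints), evalIntensityModel(m, doses(ints)))
  expect_equal(measurements(ints)[doses(ints) == 0], 100)
})

test_that("zero-dose sample mean of noisy replicates matches the generator", {
  cfg <- simulationConfig(55, c(0, 100), 0.01, replicates = 10000)
  at0 <- vapply(simulateRelaxationSeries(cfg), function(s)
    measurements(s)[1], numeric(1))
  se <- 0.01 / sqrt(length(at0))
  expect_lt(abs(mean(at0) - 6.98), 3 * se)
})

test_that("generated peak families conserve relative intensities", {
  scales <- c(1, 0.8, 0.6, 0.4, 0.2)
  cfg <- simulationConfig(6, gammaDoseGrid(), 0)
  fam <- simulateIntensitySeries(cfg, scales = scales)[[1]]
  tabs <- lapply(seq_along(gammaDoseGrid()), function(k)
    peakTable(gammaDoseGrid()[k], names(fam),
              twoSinTheta = seq(0.2, 0.6, length.out = length(fam)),
              recipD = NA_real_,
              intensity = vapply(fam, function(s) measurements(s)[k],
                                 numeric(1))))
  got <- relativeIntensities(tabs, "peak1", names(fam)[-1])
  for (k in 2:length(scales)) {
    expect_equal(got[[sprintf("peak%d", k)]]$model@slope, scales[k],
                 tolerance = 1e-12)
    expect_equal(got[[sprintf("peak%d", k)]]$r, 1, tolerance = 1e-12)
  }
})

test_that("noiseless generator-to-fitter loop returns the generator, all families", {
  # relaxation
  cfg <- simulationConfig(3, ebeamDoseGrid(), 0)
  s <- simulateRelaxationSeries(cfg)[[1]]
  p <- fitParams(fitRelaxation(doses(s), measurements(s))$fit)
  expect_equal(unname(p[c("y0", "yInf", "DC")]), c(6.98, 6.75, 73.4),
               tolerance = 1e-6)
  # linear link
  link <- linearLinkModel(12.71, 32.83)
  pair <- simulateLinkedSeries(cfg, link)[[1]]
  lf <- fitLinear(measurements(pair$predictor), measurements(pair$response))
  expect_equal(lf$model@slope, 12.71, tolerance = 1e-6)
  expect_equal(lf$model@intercept, 32.83, tolerance = 1e-6)
  # intensity-dose
  cfgI <- simulationConfig(3, gammaDoseGrid(), 0)
  ints <- simulateIntensitySeries(cfgI)[[1]][[1]]
  ip <- fitParams(fitIntensityDose(doses(ints), measurements(ints),
                                   iInitFixed = 100)$fit)
  expect_equal(unname(ip[c("D0", "fMax", "fMin", "alpha", "Dc")]),
               c(21.7, 0.05, -0.08, 0.15, 35), tolerance = 1e-6)
})

test_that("simulated diffractograms round-trip through the Bragg fit", {
  dsp <- seq(1.8, 8.5, length.out = 15)
  exact <- simulateDiffractogram(simulationConfig(4, 0, 0), dsp,
                                 wavelength = 1.5392)
  expect_equal(wavelength(fitBraggWavelength(exact)), 1.5392,
               tolerance = 1e-12)
  # jitter at the source-linewidth scale: fitted lambda within 0.0022 A
  # of truth in at least 95% of seeds
  hits <- vapply(1:100, function(seed) {
    tab <- simulateDiffractogram(simulationConfig(seed, 0, 0.0022), dsp,
                                 wavelength = 1.5392)
    abs(wavelength(fitBraggWavelength(tab)) - 1.5392) <= 0.0022
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("regenerated abscissae agree with the tabulated peak positions", {
  tab0 <- table1Fixture()[["0"]]
  dsp <- 1 / peaks(tab0)$recipD
  regen <- simulateDiffractogram(simulationConfig(1, 0, 0), dsp,
                                 wavelength = 1.54029)
  relErr <- abs(peaks(regen)$twoSinTheta - peaks(tab0)$twoSinTheta) /
    peaks(tab0)$twoSinTheta
  expect_lt(max(relErr), 0.005)
})

test_that("generator configuration is validated", {
  expect_error(simulationConfig(1, c(10, 5), 0.01), "increasing")
  expect_error(simulationConfig(1, numeric(), 0.01), "non-empty")
  expect_error(simulationConfig(1, 0:3, -0.1), "noiseSd")
  expect_error(simulationConfig(1, 0:3, 0.1, replicates = 0), "replicates")
  cfg <- simulationConfig(1, 0:3, 0.1,
                          modelParams = linearLinkModel(1, 0))
  expect_error(simulateRelaxationSeries(cfg), "RelaxationModel")
  expect_error(simulateDiffractogram(simulationConfig(1, 0, 0), c(-1, 2)),
               "positive")
})
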