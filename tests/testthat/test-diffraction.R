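test_that("Bragg d-spacing follows 2 d sin(theta) = n lambda", {
  expect_equal(braggDSpacing(1.54, 1.54), 1)
  # hand division; consistency with the tabulated 1/d for the first peak
  d <- braggDSpacing(0.18561, 1.54029)
  expect_equal(d, 8.298, tolerance = 1e-4)
  expect_equal(1 / d, 0.12054, tolerance = 5e-3)
  expect_equal(braggDSpacing(0.3, 1.5, order = 2),
               2 * braggDSpacing(0.3, 1.5))
  expect_error(braggDSpacing(0, 1.5), "> 0")
  expect_error(braggDSpacing(-0.1, 1.5), "> 0")
})

test_that("wavelength fit recovers a perfect Bragg line exactly", {
  lam <- 1.54
  d <- seq(2, 9, length.out = 12)
  tab <- peakTable(0, LETTERS[1:12], twoSinTheta = lam / d, recipD = 1 / d)
  for (origin in c(TRUE, FALSE)) {
    f <- fitBraggWavelength(tab, throughOrigin = origin)
    expect_equal(wavelength(f), lam, tolerance = 1e-12)
    expect_equal(f@r, 1, tolerance = 1e-12)
  }
})

test_that("wavelength fit is invariant to peak order and labels", {
  tabs <- table1Fixture()
  t0 <- tabs[["0"]]
  p <- peaks(t0)
  perm <- rev(seq_len(nrow(p)))
  shuffled <- peakTable(dose(t0), sprintf("p%02d", seq_len(nrow(p))),
                        p$twoSinTheta[perm], p$recipD[perm])
  expect_equal(wavelength(fitBraggWavelength(shuffled)),
               wavelength(fitBraggWavelength(t0)))
})

test_that("free-intercept fits of the packaged tables have near-zero intercepts", {
  # the empirical justification for the through-origin proportionality
  for (tab in table1Fixture()) {
    f <- fitBraggWavelength(tab, throughOrigin = FALSE)
    expect_lt(abs(f@intercept), 0.01 * max(peaks(tab)$recipD))
  }
})

test_that("wavelength estimate is stable under small position noise", {
  lam <- 1.54
  d <- braggDSpacing(table1Fixture()[["0"]]@peaks$twoSinTheta, lam)
  set.seed(21)
  errs <- replicate(100, {
    tab <- peakTable(0, sprintf("p%02d", seq_along(d)),
                     twoSinTheta = lam / d,
                     recipD = 1 / d + rnorm(length(d), 0, 1e-4))
    wavelength(fitBraggWavelength(tab)) - lam
  })
  expect_lt(max(abs(errs)), 0.002)
})

test_that("wavelength fit rejects degenerate inputs", {
  expect_error(fitBraggWavelength(
    peakTable(0, c("A", "B"), c(0.2, 0.3), c(0.13, 0.19))), "at least 3")
  tab3 <- peakTable(0, c("A", "B", "C"), c(0.2, 0.3, 0.4),
                    c(0.13, NA, 0.26))
  expect_error(fitBraggWavelength(tab3), "at least 3")
})

test_that("relative intensities recover through-origin proportionality", {
  a <- c(J = 0.8, M = 0.6, O = 0.4, N = 0.2)
  iref <- c(1000, 400, 350, 950, 1150, 1010)
  mkTables <- function(noise) {
    set.seed(22)
    lapply(seq_along(iref), function(k) {
      ints <- c(1, a) * iref[k] * (1 + rnorm(5, 0, noise))
      peakTable(c(0, 5, 15, 20, 40, 50)[k], c("I0", names(a)),
                twoSinTheta = seq(0.2, 0.6, length.out = 5),
                recipD = NA_real_, intensity = ints)
    })
  }
  exact <- relativeIntensities(mkTables(0), "I0", names(a))
  for (s in names(a)) {
    expect_equal(exact[[s]]$model@slope, unname(a[s]), tolerance = 1e-12)
    expect_equal(exact[[s]]$r, 1, tolerance = 1e-12)
    expect_lte(exact[[s]]$model@slope, 1)  # reference is the strongest peak
  }
  noisy <- relativeIntensities(mkTables(0.01), "I0", names(a))
  for (s in names(a))
    expect_lt(abs(noisy[[s]]$model@slope - a[s]) / a[s], 0.02)
  expect_gte(mean(vapply(noisy, `[[`, numeric(1), "r")), 0.99)
  # missing intensity names the symbol and dose
  broken <- mkTables(0)
  broken[[2]]@peaks$intensity[3] <- NA
  expect_error(relativeIntensities(broken, "I0", names(a)),
               "symbol 'M' at dose 5")
  expect_error(relativeIntensities(broken[1:2], "I0", names(a)),
               "at least 3")
})

test_that("peak matching groups the packaged tables into 23 groups of 6", {
  tabs <- table1Fixture()
  m <- matchPeaks(tabs, tolerance = 1e-6)
  expect_length(m$groups, 23)
  expect_true(all(vapply(m$groups, nrow, integer(1)) == 6L))
  expect_equal(nrow(m$unmatched), 0)
  expect_named(m$groups, peaks(tabs[[1]])$symbol)
})

test_that("peak matching handles identity, strict tolerance and ambiguity", {
  tab <- table1Fixture()[["0"]]
  solo <- matchPeaks(list(tab))
  expect_length(solo$groups, nrow(peaks(tab)))
  expect_true(all(vapply(solo$groups, nrow, integer(1)) == 1L))
  # zero tolerance on jittered positions: everything unmatched
  p <- peaks(tab)
  jit <- peakTable(5, p$symbol, p$twoSinTheta + 1e-7, p$recipD)
  strict <- matchPeaks(list(tab, jit), tolerance = 0)
  expect_equal(nrow(strict$unmatched), nrow(p))
  # two close peaks of one table within tolerance of one group
  twin <- peakTable(5, c("a", "b"), c(0.20000, 0.20010), c(0.13, 0.131))
  ref <- peakTable(0, "A", 0.2, 0.13)
  expect_error(matchPeaks(list(ref, twin), tolerance = 5e-4), "ambiguous")
})

test_that("wavelength summary reports mean and max relative spread", {
  mk <- function(lam) {
    d <- seq(2, 9, length.out = 5)
    fitBraggWavelength(peakTable(0, LETTERS[1:5], lam / d, 1 / d))
  }
  same <- summarizeWavelengths(list(mk(1.54), mk(1.54)))
  expect_equal(same$spreadPct, 0, tolerance = 1e-9)
  two <- summarizeWavelengths(list(mk(1.0), mk(3.0)))
  expect_equal(two$mean, 2.0, tolerance = 1e-12)
  expect_equal(two$spreadPct, 50, tolerance = 1e-9)
  expect_error(summarizeWavelengths(list()), "empty")
  expect_error(summarizeWavelengths(list(mk(1.5))), "at least 2")
})

test_that("fixture tables carry the tabulated values and pass checksums", {
  tabs <- table1Fixture()
  b <- peaks(tabs[["0"]])[1, ]
  expect_equal(b$symbol, "B")
  expect_equal(b$twoSinTheta, 0.18561)
  expect_equal(b$recipD, 0.12054)
  t2 <- table2Fixture()
  expect_equal(measurements(t2$lambda)[doses(t2$lambda) == 20], 1.54121)
  expect_equal(measurements(t2$dH1)[doses(t2$dH1) == 0], 34.60)
})
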