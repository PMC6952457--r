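test_that("pearsonR matches the covariance definition and validates input", {
  expect_equal(pearsonR(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearsonR(1:10, -(1:10)), -1)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(pearsonR(x, y), corOracle(x, y), tolerance = 1e-12)
  }
  expect_error(pearsonR(1:2, 1:2), "at least 3")
  expect_error(pearsonR(rep(1, 5), 1:5), "zero variance")
})

test_that("linear fit reproduces exact affine data and the normal equations", {
  ph <- seq(6.7, 7.0, length.out = 8)
  res <- fitLinear(ph, 32.83 + 12.71 * ph)
  expect_equal(res$model@slope, 12.71, tolerance = 1e-10)
  expect_equal(res$model@intercept, 32.83, tolerance = 1e-8)
  expect_equal(goodnessR(res$fit), 1, tolerance = 1e-12)
  set.seed(32)
  for (i in 1:100) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x))
    for (origin in c(FALSE, TRUE)) {
      got <- fitLinear(x, y, throughOrigin = origin)
      want <- olsOracle(x, y, origin)
      expect_equal(got$model@slope, unname(want["slope"]),
                   tolerance = 1e-10)
      expect_equal(got$model@intercept, unname(want["intercept"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("linear fit handles degenerate and mismatched input per contract", {
  expect_error(fitLinear(1:5, 1:4), "mismatched")
  expect_error(fitLinear(rep(2, 6), rnorm(6)), "zero x-variance")
  flat <- fitLinear(1:6, rep(3, 6))
  expect_equal(flat$model@slope, 0, tolerance = 1e-12)
  expect_true(is.na(goodnessR(flat$fit)))
})

test_that("linear fit is equivariant under predictor scaling", {
  set.seed(33)
  x <- rnorm(12); y <- 2 * x + rnorm(12, 0, 0.1)
  base <- fitLinear(x, y)
  for (c in c(0.5, 3, 10)) {
    scaled <- fitLinear(c * x, y)
    expect_equal(scaled$model@slope, base$model@slope / c,
                 tolerance = 1e-10)
    expect_equal(goodnessR(scaled$fit), goodnessR(base$fit),
                 tolerance = 1e-12)
  }
})

test_that("free-intercept residuals sum to zero", {
  set.seed(34)
  for (i in 1:10) {
    x <- rnorm(20); y <- 1 + 2 * x + rnorm(20)
    expect_lt(abs(sum(residuals(fitLinear(x, y)$fit))), 1e-10)
  }
})

test_that("relaxation fit recovers noiseless generators to 1e-6", {
  d <- seq(0, 400, 25)
  res <- fitRelaxation(d, evalRelaxation(relaxationModel(6.98, 6.75, 73.4), d))
  p <- fitParams(res$fit)
  expect_true(converged(res$fit))
  expect_equal(unname(p["y0"]), 6.98, tolerance = 1e-6)
  expect_equal(unname(p["yInf"]), 6.75, tolerance = 1e-6)
  expect_equal(unname(p["DC"]), 73.4, tolerance = 1e-6)
  set.seed(35)
  for (i in 1:10) {
    m <- randomRelaxationModel()
    got <- fitRelaxation(d, evalRelaxation(m, d))
    expect_true(converged(got$fit))
    expect_equal(got$model@DC, m@DC, tolerance = 1e-5)
  }
  expect_error(fitRelaxation(c(0, 10, 20), c(1, 2, 3)), "at least 4")
})

test_that("relaxation optimum beats a coarse grid-search oracle", {
  d <- c(0, 25, 50, 100, 150, 200, 300, 400)
  set.seed(36)
  y <- evalRelaxation(relaxationModel(6.98, 6.75, 73.4), d) +
    rnorm(length(d), 0, 0.01)
  res <- fitRelaxation(d, y)
  p <- fitParams(res$fit)
  ssFit <- relaxSS(d, y, p["y0"], p["yInf"], p["DC"])
  grid <- expand.grid(y0 = seq(6.9, 7.05, 0.01),
                      yInf = seq(6.65, 6.85, 0.01),
                      DC = seq(20, 200, 5))
  ssGrid <- mapply(relaxSS, grid$y0, grid$yInf, grid$DC,
                   MoreArgs = list(d = d, y = y))
  expect_lte(ssFit, min(ssGrid))
  # the lattice minimum brackets the same neighbourhood
  best <- grid[which.min(ssGrid), ]
  expect_lt(abs(best$DC - p["DC"]), 10)
})

test_that("intensity-dose fit recovers a noiseless generator to 1e-4 relative", {
  d <- seq(0, 50, 2.5)
  truth <- c(D0 = 21.7, fMax = 0.05, fMin = -0.08, alpha = 0.15, Dc = 35)
  m <- intensityDoseModel(100, 21.7,
                          specificFunctionParams(0.05, -0.08, 0.15, 35))
  I <- evalIntensityModel(m, d)
  for (fixI in list(100, NULL)) {
    res <- fitIntensityDose(d, I, iInitFixed = fixI)
    expect_true(converged(res$fit))
    p <- fitParams(res$fit)
    expect_equal(unname(p[names(truth)]), unname(truth),
                 tolerance = 1e-4)
    expect_equal(unname(p["iInit"]), 100, tolerance = 1e-4)
  }
  expect_error(fitIntensityDose(d[1:5], I[1:5]), "too few points")
})

test_that("intensity-dose residuals are orthogonal to the model Jacobian", {
  d <- seq(0, 50, 2.5)
  m <- intensityDoseModel(100, 21.7,
                          specificFunctionParams(0.05, -0.08, 0.15, 35))
  set.seed(37)
  I <- evalIntensityModel(m, d) * (1 + rnorm(length(d), 0, 0.01))
  res <- fitIntensityDose(d, I, iInitFixed = I[1])
  expect_true(converged(res$fit))
  p <- fitParams(res$fit)
  predict <- function(q)
    evalIntensityModel(intensityDoseModel(unname(p["iInit"]), q[1],
      specificFunctionParams(q[2], q[3], q[4], q[5])), d)
  q <- unname(p[c("D0", "fMax", "fMin", "alpha", "Dc")])
  J <- sapply(seq_along(q), function(k) {
    h <- max(1e-7, 1e-7 * abs(q[k]))
    qp <- q; qp[k] <- qp[k] + h
    (predict(qp) - predict(q)) / h
  })
  r <- residuals(res$fit)
  # first-order optimality: J^T r ~ 0 relative to column scale
  for (k in seq_len(ncol(J)))
    expect_lt(abs(sum(J[, k] * r)) / (sqrt(sum(J[, k]^2) * sum(r^2)) + 1e-30),
              1e-4)
})

test_that("converged nonlinear fits never report non-positive DC or alpha", {
  d <- seq(0, 400, 50)
  set.seed(38)
  for (i in 1:15) {
    m <- randomRelaxationModel()
    got <- fitRelaxation(d, evalRelaxation(m, d) + rnorm(length(d), 0, 0.02))
    if (converged(got$fit)) expect_gt(fitParams(got$fit)["DC"], 0)
  }
  dg <- seq(0, 50, 2.5)
  for (i in 1:5) {
    m <- randomIntensityModel()
    I <- evalIntensityModel(m, dg) * (1 + rnorm(length(dg), 0, 0.01))
    got <- fitIntensityDose(dg, I, iInitFixed = I[1])
    if (converged(got$fit)) {
      expect_gt(fitParams(got$fit)["alpha"], 0)
      expect_gt(fitParams(got$fit)["fMax"], fitParams(got$fit)["fMin"])
    }
  }
})

test_that("fitting is deterministic: identical inputs, identical results", {
  d <- seq(0, 400, 25)
  set.seed(39)
  y <- evalRelaxation(relaxationModel(6.98, 6.75, 73.4), d) +
    rnorm(length(d), 0, 0.01)
  a <- fitRelaxation(d, y)
  b <- fitRelaxation(d, y)
  expect_identical(fitParams(a$fit), fitParams(b$fit))
  expect_identical(residuals(a$fit), residuals(b$fit))
})
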