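# shared oracles and random-model factories

# normal-equation least squares, independent of fitLinear
olsOracle <- function(x, y, throughOrigin = FALSE) {
  X <- if (throughOrigin) cbind(x) else cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  if (throughOrigin) c(intercept = 0, slope = beta[1])
  else c(intercept = beta[1], slope = beta[2])
}

# covariance-definition Pearson correlation
corOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

randomRelaxationModel <- function() {
  relaxationModel(y0 = runif(1, -5, 10),
                  yInf = runif(1, -5, 10) + sample(c(-1, 1), 1) * runif(1, 0.5, 3),
                  DC = runif(1, 5, 300))
}

randomSfp <- function() {
  fmin <- runif(1, -1, 0.5)
  specificFunctionParams(fMax = fmin + runif(1, 0.1, 2), fMin = fmin,
                         alpha = runif(1, 0.02, 0.5),
                         Dc = runif(1, 5, 60))
}

randomIntensityModel <- function() {
  intensityDoseModel(iInit = runif(1, 50, 500), D0 = runif(1, 5, 45),
                     sfp = randomSfp())
}

# sum-of-squares of a relaxation model on data, for grid-search oracles
relaxSS <- function(d, y, y0, yInf, DC) {
  sum((y - ((y0 - yInf) * exp(-d / DC) + yInf))^2)
}
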