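test_that("candidate enumeration crosses seasonality blocks with trend", {
  cand <- enumerateCandidates()
  expect_length(cand, 10)
  np <- vapply(cand, `[[`, 1L, "nparam")
  expect_true(all(diff(np) >= 0))
  expect_identical(vapply(cand, `[[`, 1L, "id"), 1:10)
  ## restricted crossing: intercept-only and intercept+trend
  expect_length(enumerateCandidates("none"), 2)
  ## dof arithmetic: 1 + 6 harmonic dof + 1 trend
  h3t <- Filter(function(s) s$seasonal == "harmonics12_6_3" && s$trend, cand)
  expect_equal(h3t[[1]]$nparam, 8)
  mfe <- Filter(function(s) s$seasonal == "month_fixed_effects" && s$trend,
                cand)
  expect_equal(mfe[[1]]$nparam, 13)
})

test_that("design matrix columns follow the stated conventions", {
  cand <- enumerateCandidates()
  h12 <- Filter(function(s) s$seasonal == "harmonics12" && !s$trend, cand)[[1]]
  months <- ymSeq("2017-01", "2017-07")
  X <- buildDesignMatrix(h12, months)
  expect_equal(unname(X[1, ]), c(1, sin(0), cos(0)))           # t = 0
  expect_equal(unname(X[7, 2:3]), c(sin(pi), cos(pi)))         # t = 6
  ## January is the month-effect reference level
  mfe <- Filter(function(s) s$seasonal == "month_fixed_effects" && !s$trend,
                cand)[[1]]
  Xm <- buildDesignMatrix(mfe, ymSeq("2017-01", "2017-03"))
  expect_equal(unname(Xm[1, -1]), rep(0, 11))
  expect_equal(sum(Xm[2, -1]), 1)
  ## trend is the 0-based calendar-year index from the origin
  tr <- enumerateCandidates("none", TRUE)[[1]]
  Xt <- buildDesignMatrix(tr, c("2017-12", "2018-01"), origin = "2017-01")
  expect_equal(unname(Xt[, "trend"]), c(0, 1))
  expect_error(buildDesignMatrix(h12, character()), "empty")
})

test_that("Poisson GLM matches closed forms and a generic-optimizer oracle", {
  ## intercept-only MLE is the log sample mean
  X1 <- matrix(1, 36, 1)
  expect_equal(unname(fitCountGlm(X1, rep(50L, 36))), log(50),
               tolerance = 1e-8)
  expect_equal(unname(fitCountGlm(matrix(1, 2, 1), c(40L, 60L))), log(50),
               tolerance = 1e-8)
  ## intercept + trend against brute-force likelihood maximization
  months <- ymSeq("2017-01", "2019-12")
  tr <- enumerateCandidates("none", TRUE)[[1]]
  X <- buildDesignMatrix(tr, months)
  set.seed(42)
  y <- rpois(36, exp(4.5 + 0.2 * X[, "trend"]))
  beta <- fitCountGlm(X, y)
  oracle <- poissonMleOracle(X, y)
  expect_equal(unname(beta), oracle, tolerance = 1e-6)
  ## invalid inputs
  expect_error(fitCountGlm(X, y - 0.5), "integers")
  expect_error(fitCountGlm(cbind(X, X[, 1]), y), "rank")
})

test_that("blocked CV picks parsimonious truth and breaks ties as stated", {
  months <- ymSeq("2017-01", "2019-12")
  ## constant series: intercept-only should win after the parsimony tie-break
  set.seed(7)
  yconst <- rpois(36, 200)
  sel <- blockedCvSelect(yconst, months)
  expect_equal(sel$spec$seasonal, "none")
  ## tie-break: identical candidates differing only in id -> lowest id wins
  c1 <- list(id = 3L, seasonal = "harmonics12", trend = FALSE, nparam = 3L)
  c2 <- list(id = 9L, seasonal = "harmonics12", trend = FALSE, nparam = 3L)
  selTie <- blockedCvSelect(yconst, months, list(c2, c1))
  expect_equal(selTie$spec$id, 3L)
  expect_equal(selTie$cvTable$cvMse[1], selTie$cvTable$cvMse[2])
  ## same mse but fewer parameters wins over lower id
  c3 <- list(id = 1L, seasonal = "none", trend = FALSE, nparam = 1L)
  c4 <- list(id = 0L, seasonal = "none", trend = FALSE, nparam = 2L)
  selP <- blockedCvSelect(yconst, months, list(c4, c3))
  expect_equal(selP$spec$id, 1L)
  expect_error(blockedCvSelect(rpois(12, 50), ymSeq("2017-01", "2017-12")),
               "2 calendar years")
})

test_that("strong planted annual seasonality is selected", {
  months <- ymSeq("2017-01", "2019-12")
  hits <- vapply(1:20, function(s) {
    y <- makeSeasonalSeries(months, beta0 = log(200), trend = 0.1,
                            amp = 0.5, seed = s)
    blockedCvSelect(y, months)$spec$seasonal != "none"
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("dispersion assessment routes families from the mean-variance relation", {
  ## zero residuals: phi = 0 -> poisson
  mu <- rep(100, 36)
  d0 <- assessDispersion(mu, mu, p = 1)
  expect_equal(d0$family, "poisson")
  expect_equal(d0$dispersion, 0)
  ## strongly negbin series routes away from poisson with theta near truth
  set.seed(11)
  y <- rnbinom(200, mu = 100, size = 5)
  d1 <- assessDispersion(rep(100, 200), y, p = 1)
  expect_true(d1$family %in% c("negbin", "overdispersed_poisson"))
  if (d1$family == "negbin") expect_gt(d1$familyParam, 1)
  expect_error(assessDispersion(mu[1:2], mu[1:2], p = 2), "observations")
})

test_that("counterfactual draws match the routed family's moments", {
  mos <- ymFormat(ymToSerial("2020-01") + 0:0)
  fitP <- interceptFit(100)
  dP <- simulateCounterfactual(fitP, mos, nSims = 1e5, seed = 1)
  expect_lt(abs(mean(drawMatrix(dP)) - 100), 0.3)   # 3 sigma on the mean
  expect_lt(abs(var(as.numeric(drawMatrix(dP))) - 100), 5)
  ## ODP: moment-matched NB gives variance phi * mu exactly
  fitO <- interceptFit(100, "overdispersed_poisson", familyParam = 4)
  dO <- simulateCounterfactual(fitO, mos, nSims = 1e5, seed = 2)
  expect_lt(abs(var(as.numeric(drawMatrix(dO))) - 400), 20)
  ## negbin: variance mu + mu^2/theta
  fitN <- interceptFit(100, "negbin", familyParam = 5)
  dN <- simulateCounterfactual(fitN, mos, nSims = 1e5, seed = 3)
  expect_lt(abs(var(as.numeric(drawMatrix(dN))) - 2100), 60)
  ## determinism with a single draw
  d1 <- simulateCounterfactual(fitP, mos, nSims = 1, seed = 9)
  d2 <- simulateCounterfactual(fitP, mos, nSims = 1, seed = 9)
  expect_identical(drawMatrix(d1), drawMatrix(d2))
})

test_that("prediction intervals use the inverted-ECDF order statistics", {
  d <- toyDraws(matrix(1:100, nrow = 1), mu = 50.5)
  pi95 <- predictionIntervals(d, 0.95)
  expect_equal(pi95$lower, 3)
  expect_equal(pi95$upper, 98)
  ## degenerate draws give a zero-width interval
  dd <- toyDraws(matrix(100L, 1, 100))
  expect_equal(unlist(predictionIntervals(dd, 0.95)[, c("lower", "upper")]),
               c(lower = 100, upper = 100))
  expect_error(predictionIntervals(d, 0), "level")
  expect_error(predictionIntervals(d, 1.2), "level")
  ## widening the level widens the interval
  pi80 <- predictionIntervals(d, 0.8)
  expect_gte(pi95$upper - pi95$lower, pi80$upper - pi80$lower)
})

test_that("dispersion widens intervals: phi up, theta down widen/narrow PIs", {
  mos <- "2020-01"
  width <- function(fit, seed) {
    p <- predictionIntervals(simulateCounterfactual(fit, mos, 2e4, seed))
    p$upper - p$lower
  }
  wP <- width(interceptFit(100), 1)
  wO2 <- width(interceptFit(100, "overdispersed_poisson", 2), 2)
  wO6 <- width(interceptFit(100, "overdispersed_poisson", 6), 3)
  wN2 <- width(interceptFit(100, "negbin", 2), 4)
  wN20 <- width(interceptFit(100, "negbin", 20), 5)
  expect_lt(wP, wO2); expect_lt(wO2, wO6)
  expect_gt(wN2, wN20); expect_gt(wN20, wP)
})

test_that("rmspe is the root-mean-squared percentage error", {
  expect_equal(rmspe(c(100, 100), c(90, 110)), 0.1)
  expect_equal(rmspe(c(55, 70), c(55, 70)), 0)
  expect_equal(rmspe(100, 87.5), 0.125)
  expect_error(rmspe(c(100, 0), c(90, 10)), "positive")
})
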