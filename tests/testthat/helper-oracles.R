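## Independent brute-force oracles used to check package implementations.

## step-up BH adjustment written directly from the definition:
## sort ascending, adj_(i) = min_{j >= i} m * p_(j) / j, cap at 1,
## return in input order
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## recovery classification by exhaustive run enumeration over a bad-flag
## vector: list every maximal non-bad run, apply the definition literally
recoveryScanOracle <- function(bad, minRun = 3L) {
  n <- length(bad)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!bad[i]) {
      j <- i
      while (j < n && !bad[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = i, len = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs <- Filter(function(r) r["len"] >= minRun, runs)
  if (!length(runs))
    return(list(status = "none", recoveryMonthIndex = NA_integer_))
  start <- runs[[1]]["start"]
  later_bad <- any(bad[start:n])
  list(status = if (later_bad) "partial" else "sustained",
       recoveryMonthIndex = unname(as.integer(start)))
}

## exact two-sided Mann-Whitney p by full enumeration of rank assignments
mwEnumOracle <- function(a, b) {
  m <- length(a); n <- length(b)
  uObs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  allv <- seq_len(m + n)
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(ix) {
    aa <- allv[ix]; bb <- allv[-ix]
    sum(outer(aa, bb, ">"))
  })
  ## two-sided: double the smaller tail of the permutation distribution
  lo <- mean(us <= uObs)
  hi <- mean(us >= uObs)
  min(1, 2 * min(lo, hi))
}

## Kruskal-Wallis H from the textbook formula with tie correction
kwFormulaOracle <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  Rj <- vapply(split(r, rep(seq_along(groups), lengths(groups))), sum, 1.0)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H / C
}

## Poisson log-likelihood maximized by a generic optimizer (model oracle)
poissonMleOracle <- function(X, y, start = NULL) {
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - exp(eta))
  }
  if (is.null(start)) start <- c(log(mean(y)), rep(0, ncol(X) - 1))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$par
}

## adjusted Rand index (closed form on the contingency table)
ariOracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expd <- si * sj / ch2(n)
  (sij - expd) / ((si + sj) / 2 - expd)
}

## one fixed-parameter seasonal-trend Poisson series for model tests
makeSeasonalSeries <- function(months, beta0 = log(150), trend = 0,
                               amp = 0, phase = 0, seed = 1,
                               family = "poisson", theta = 5) {
  s <- CareDelta::ymToSerial(months)
  t <- s - s[1]
  yearIdx <- s %/% 12 - s[1] %/% 12
  mu <- exp(beta0 + trend * yearIdx + amp * sin(2 * pi * t / 12 + phase))
  set.seed(seed)
  if (family == "poisson") rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = theta)
}

## minimal FittedCounterfactual with intercept-only mean, for draw tests
interceptFit <- function(mu, family = "poisson", familyParam = NA_real_,
                         months = ymSeq("2017-01", "2019-12")) {
  spec <- enumerateCandidates("none", FALSE)[[1]]
  new("FittedCounterfactual", entityId = "toy", spec = spec,
      coefficients = c(`(Intercept)` = log(mu)), dispersion = 1,
      family = family, familyParam = familyParam,
      cvTable = data.frame(), rmspe = 0, trainMonths = months,
      holdoutPred = rep(mu, length(months)))
}

## CounterfactualDraws wrapper around an explicit draw matrix
toyDraws <- function(draws, mu = rowMeans(draws),
                     months = ymFormat(ymToSerial("2020-01") +
                                         seq_len(nrow(draws)) - 1L)) {
  new("CounterfactualDraws", entityId = "toy", months = months,
      mu = as.numeric(mu), draws = matrix(as.integer(draws),
                                          nrow = nrow(draws)))
}
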