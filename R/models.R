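## Counterfactual count models: candidate enumeration, blocked leave-one-
## year-out cross-validation, dispersion assessment and Monte-Carlo
## simulation of the counterfactual count distribution.

seasonalDof <- c(none = 0L, harmonics12 = 2L, harmonics12_6 = 4L,
                 harmonics12_6_3 = 6L, month_fixed_effects = 11L)

seasonalPeriods <- list(none = integer(), harmonics12 = 12L,
                        harmonics12_6 = c(12L, 6L),
                        harmonics12_6_3 = c(12L, 6L, 3L),
                        month_fixed_effects = integer())

#' Enumerate candidate seasonal-trend model specifications
#'
#' The candidate set crosses five seasonality blocks (none; harmonic terms
#' with 12-, 12+6-, or 12+6+3-month periodicities; monthly fixed effects)
#' with presence/absence of a linear year trend, giving ten specifications
#' ordered from fewest to most parameters with stable ids.
#'
#' @param seasonalBlocks subset of
#'   `c("none","harmonics12","harmonics12_6","harmonics12_6_3",
#'   "month_fixed_effects")` to retain.
#' @param trend logical vector of trend settings to retain.
#' @return list of candidate specs (lists with `id`, `seasonal`, `trend`,
#'   `nparam`), ordered by parameter count then id.
#' @examples
#' length(enumerateCandidates())            # 10
#' length(enumerateCandidates("none"))      # 2
#' @export
enumerateCandidates <- function(seasonalBlocks = names(seasonalDof),
                                trend = c(FALSE, TRUE)) {
  seasonalBlocks <- match.arg(seasonalBlocks, names(seasonalDof),
                              several.ok = TRUE)
  full <- expand.grid(trend = c(FALSE, TRUE),
                      seasonal = names(seasonalDof),
                      stringsAsFactors = FALSE)
  full$nparam <- 1L + seasonalDof[full$seasonal] + as.integer(full$trend)
  full <- full[order(full$nparam), , drop = FALSE]
  full$id <- seq_len(nrow(full))
  keep <- full$seasonal %in% seasonalBlocks & full$trend %in% trend
  lapply(which(keep), function(i)
    list(id = full$id[i], seasonal = full$seasonal[i], trend = full$trend[i],
         nparam = unname(full$nparam[i])))
}

#' Build the design matrix of a candidate specification
#'
#' Columns: intercept; per harmonic period `P`, `sin(2*pi*t/P)` and
#' `cos(2*pi*t/P)` with `t` the 0-based month index from `origin`; month
#' fixed effects as 11 indicators with January as reference; year trend as
#' the 0-based calendar-year index relative to `origin`'s year.
#'
#' @param spec a candidate from [enumerateCandidates()].
#' @param months contiguous (as observed from `origin`) `YYYY-MM` labels.
#' @param origin `YYYY-MM` month defining `t = 0` (first training month).
#' @return numeric matrix with one row per month.
#' @export
buildDesignMatrix <- function(spec, months, origin = months[1]) {
  if (!length(months)) stop("empty month range", call. = FALSE)
  s <- ymToSerial(months)
  t <- s - ymToSerial(origin)
  X <- cbind(`(Intercept)` = rep(1, length(t)))
  for (P in seasonalPeriods[[spec$seasonal]]) {
    X <- cbind(X, sin(2 * pi * t / P), cos(2 * pi * t / P))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("sin", "cos"), P)
  }
  if (spec$seasonal == "month_fixed_effects") {
    moy <- ymMonthOfYear(s)
    for (m in 2:12) {
      X <- cbind(X, as.numeric(moy == m))
      colnames(X)[ncol(X)] <- paste0("moy", m)
    }
  }
  if (spec$trend) {
    X <- cbind(X, trend = ymYear(s) - ymYear(ymToSerial(origin)))
  }
  X
}

#' Fit a Poisson log-link GLM
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence at relative deviance change `1e-8`, at most 100 iterations).
#' Non-convergence or a rank-deficient design is an error; in
#' cross-validation such candidates are dropped rather than fatal.
#'
#' @param design numeric design matrix (full column rank).
#' @param counts non-negative integer response.
#' @return named coefficient vector on the log-link scale.
#' @examples
#' fitCountGlm(cbind(1, rep(0, 3)), c(40L, 50L, 60L))[1]  # log(50)
#' @export
fitCountGlm <- function(design, counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  fit <- suppressWarnings(glm.fit(
    x = design, y = counts, family = poisson(),
    control = list(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) stop("IRLS did not converge", call. = FALSE)
  if (fit$rank < ncol(design)) stop("design is rank deficient", call. = FALSE)
  fit$coefficients
}

## linear predictor -> mean for a fitted spec
predictMuFromCoef <- function(spec, coefs, months, origin) {
  X <- buildDesignMatrix(spec, months, origin)
  as.numeric(exp(X %*% coefs))
}

#' Select a model by leave-one-year-out blocked cross-validation
#'
#' Folds are the calendar years of the training window.  Each candidate is
#' fit on all other years and scored by the mean squared error between the
#' held-out year's counts and predicted means; the candidate with the lowest
#' average MSE across folds wins, ties broken by fewest parameters then
#' lowest id.  Candidates failing to fit in any fold are excluded; if all
#' fail, intercept+trend is used as fallback.
#'
#' @param counts training-window counts.
#' @param months training-window `YYYY-MM` labels (>= 2 calendar years).
#' @param candidates candidate list from [enumerateCandidates()].
#' @return list with `spec` (winner), `cvTable` (per-candidate mean CV MSE),
#'   and `holdoutPred` (held-out mean predictions of the winner, aligned
#'   with `months`).
#' @export
blockedCvSelect <- function(counts, months, candidates = enumerateCandidates()) {
  s <- ymToSerial(months)
  years <- ymYear(s)
  if (length(unique(years)) < 2)
    stop("training window must span at least 2 calendar years", call. = FALSE)
  origin <- months[1]
  folds <- split(seq_along(months), years)

  scoreOne <- function(spec) {
    mse <- numeric(length(folds))
    pred <- rep(NA_real_, length(months))
    for (f in seq_along(folds)) {
      hold <- folds[[f]]
      co <- tryCatch(
        fitCountGlm(buildDesignMatrix(spec, months[-hold], origin),
                    counts[-hold]),
        error = function(e) NULL)
      if (is.null(co)) return(NULL)
      mu <- predictMuFromCoef(spec, co, months[hold], origin)
      pred[hold] <- mu
      mse[f] <- mean((counts[hold] - mu)^2)
    }
    list(score = mean(mse), pred = pred)
  }

  res <- lapply(candidates, scoreOne)
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) {
    fallback <- enumerateCandidates("none", TRUE)[[1]]
    co <- fitCountGlm(buildDesignMatrix(fallback, months, origin), counts)
    return(list(spec = fallback,
                cvTable = data.frame(id = fallback$id,
                                     seasonal = fallback$seasonal,
                                     trend = fallback$trend,
                                     nparam = fallback$nparam,
                                     cvMse = NA_real_),
                holdoutPred = predictMuFromCoef(fallback, co, months, origin)))
  }
  tab <- data.frame(
    id = vapply(candidates, `[[`, 1L, "id"),
    seasonal = vapply(candidates, `[[`, "", "seasonal"),
    trend = vapply(candidates, `[[`, TRUE, "trend"),
    nparam = vapply(candidates, `[[`, 1L, "nparam"),
    cvMse = vapply(res, function(r) if (is.null(r)) NA_real_ else r$score,
                   1.0))
  cand_ok <- which(ok)
  o <- cand_ok[order(tab$cvMse[cand_ok], tab$nparam[cand_ok], tab$id[cand_ok])]
  best <- o[1]
  list(spec = candidates[[best]], cvTable = tab, holdoutPred = res[[best]]$pred)
}

#' Assess overdispersion and route the simulation family
#'
#' Computes the Pearson dispersion `phi = sum((y-mu)^2/mu) / (n-p)` of the
#' final fit.  At `phi <= 1.2` the Poisson family is kept; otherwise the
#' mean-variance relationship is examined by through-the-origin least
#' squares of the excess squared residual `(y-mu)^2 - mu` against `mu`
#' (overdispersed Poisson, variance `phi*mu`) and against `mu^2` (negative
#' binomial, variance `mu + mu^2/theta`), routing to the form with the
#' smaller residual sum of squares.
#'
#' @param mu fitted means of the final training fit.
#' @param y observed training counts.
#' @param p number of model parameters.
#' @return list with `family` (`"poisson"`, `"overdispersed_poisson"` or
#'   `"negbin"`), `familyParam` (`phi` or `theta`; `NA` for Poisson) and
#'   `dispersion` (Pearson `phi`).
#' @export
assessDispersion <- function(mu, y, p) {
  n <- length(y)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  phiHat <- sum((y - mu)^2 / mu) / (n - p)
  if (phiHat <= 1.2)
    return(list(family = "poisson", familyParam = NA_real_,
                dispersion = phiHat))
  z <- (y - mu)^2 - mu
  aOdp <- sum(z * mu) / sum(mu^2)        # z ~ (phi - 1) * mu
  aNb <- sum(z * mu^2) / sum(mu^4)       # z ~ mu^2 / theta
  rssOdp <- sum((z - aOdp * mu)^2)
  rssNb <- sum((z - aNb * mu^2)^2)
  if (aNb > 0 && rssNb < rssOdp) {
    list(family = "negbin", familyParam = max(1 / aNb, 1e-3),
         dispersion = phiHat)
  } else {
    list(family = "overdispersed_poisson",
         familyParam = max(1 + aOdp, 1 + 1e-6), dispersion = phiHat)
  }
}

#' Fit the counterfactual model for one entity
#'
#' Runs blocked cross-validation selection over the candidate set, refits
#' the winner on the full training window, assesses overdispersion, and
#' computes the out-of-sample RMSPE from the winner's cross-validation
#' holdout predictions.
#'
#' @param counts training-window counts for the entity.
#' @param months training-window `YYYY-MM` labels.
#' @param entityId entity identifier carried through to results.
#' @param candidates candidate list from [enumerateCandidates()].
#' @return a [FittedCounterfactual-class].
#' @export
fitCounterfactual <- function(counts, months, entityId = "entity",
                              candidates = enumerateCandidates()) {
  sel <- blockedCvSelect(counts, months, candidates)
  origin <- months[1]
  X <- buildDesignMatrix(sel$spec, months, origin)
  co <- fitCountGlm(X, counts)
  mu <- predictMuFromCoef(sel$spec, co, months, origin)
  disp <- assessDispersion(mu, counts, sel$spec$nparam)
  rms <- if (all(counts > 0) && !anyNA(sel$holdoutPred))
    rmspe(counts, sel$holdoutPred) else NA_real_
  ## inverse Fisher information (Poisson working weights), for optional
  ## coefficient resampling; scaled by phi when routed to ODP/negbin
  vc <- solve(crossprod(X, X * mu))
  if (disp$family != "poisson") vc <- vc * max(disp$dispersion, 1)
  new("FittedCounterfactual", entityId = entityId, spec = sel$spec,
      coefficients = co, dispersion = disp$dispersion, family = disp$family,
      familyParam = disp$familyParam, cvTable = sel$cvTable, rmspe = rms,
      trainMonths = as.character(months),
      holdoutPred = as.numeric(sel$holdoutPred), vcov = vc)
}

#' Expected counterfactual means over a prediction window
#'
#' @param fit a [FittedCounterfactual-class].
#' @param months `YYYY-MM` labels to predict.
#' @return named numeric vector of expected means.
#' @export
predictExpected <- function(fit, months) {
  setNames(predictMuFromCoef(fit@spec, fit@coefficients, months,
                             fit@trainMonths[1]), months)
}

#' Simulate the Monte-Carlo counterfactual count distribution
#'
#' Draws are conditionally independent given the fitted means: Poisson for
#' the Poisson family; a moment-matched negative binomial with size
#' `mu/(phi-1)` (variance exactly `phi*mu`) for the overdispersed-Poisson
#' family; negative binomial with size `theta` for the negbin family.
#' By default draws are conditional on the fitted mean (outcome noise
#' only); `resampleCoefficients = TRUE` additionally resamples the
#' coefficient vector from its asymptotic normal distribution per draw, so
#' the counterfactual distribution also reflects estimation uncertainty
#' (relevant when predicting beyond the training support).
#'
#' @param fit a [FittedCounterfactual-class].
#' @param months prediction-window `YYYY-MM` labels.
#' @param nSims number of Monte-Carlo draws per month (>= 1).
#' @param seed integer seed; draws depend only on `(fit, months, nSims,
#'   seed, resampleCoefficients)`.
#' @param resampleCoefficients propagate coefficient uncertainty into the
#'   draws (default `FALSE`).
#' @return a [CounterfactualDraws-class].
#' @export
simulateCounterfactual <- function(fit, months, nSims = 10000, seed = 1,
                                   resampleCoefficients = FALSE) {
  if (nSims < 1) stop("nSims must be >= 1", call. = FALSE)
  mu <- predictExpected(fit, months)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("non-positive or non-finite expected mean", call. = FALSE)
  m <- length(months)
  set.seed(as.integer(seed %% 2147483647))
  if (resampleCoefficients) {
    ## beta_s ~ N(beta, vcov); per-draw mean surface mu[m, s]
    L <- chol(fit@vcov)
    Z <- matrix(rnorm(nSims * ncol(L)), nSims)
    B <- sweep(Z %*% L, 2, fit@coefficients, "+")
    X <- buildDesignMatrix(fit@spec, months, fit@trainMonths[1])
    muMat <- exp(X %*% t(B))       # m x nSims
    draws <- switch(fit@family,
      poisson = rpois(m * nSims, muMat),
      overdispersed_poisson = rnbinom(m * nSims, mu = muMat,
                                      size = muMat / (fit@familyParam - 1)),
      negbin = rnbinom(m * nSims, mu = muMat, size = fit@familyParam))
  } else {
    draws <- switch(fit@family,
      poisson = rpois(m * nSims, mu),
      overdispersed_poisson = rnbinom(m * nSims, mu = mu,
                                      size = mu / (fit@familyParam - 1)),
      negbin = rnbinom(m * nSims, mu = mu, size = fit@familyParam))
  }
  draws <- matrix(as.integer(draws), nrow = m, ncol = nSims,
                  dimnames = list(months, NULL))
  new("CounterfactualDraws", entityId = fit@entityId,
      months = as.character(months), mu = unname(mu), draws = draws)
}

## order-statistic quantile (inverted ECDF): k-th smallest with
## k = ceiling(prob * S), clamped to [1, S]
orderStatQuantile <- function(sorted, prob) {
  S <- length(sorted)
  k <- pmin(pmax(ceiling(prob * S), 1L), S)
  sorted[k]
}

#' Prediction intervals from counterfactual draws
#'
#' Per month, the `level` interval is formed from order statistics of the
#' draws: lower = `ceiling(alpha/2 * S)`-th smallest, upper =
#' `ceiling((1 - alpha/2) * S)`-th smallest (inverted-ECDF convention, so
#' bounds are always attainable counts).
#'
#' @param draws a [CounterfactualDraws-class].
#' @param level coverage level in (0, 1); at least `2/(1-level)` draws are
#'   required (40 at the default 0.95).
#' @return data.frame with `month`, `lower`, `upper`, `level`.
#' @export
predictionIntervals <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be a single value in (0, 1)", call. = FALSE)
  S <- nSims(draws)
  if (S < 2 / (1 - level))
    stop("too few draws for the requested level", call. = FALSE)
  alpha <- 1 - level
  lo <- numeric(length(draws@months))
  hi <- numeric(length(draws@months))
  for (i in seq_along(draws@months)) {
    srt <- sort.int(draws@draws[i, ], method = "quick")
    lo[i] <- orderStatQuantile(srt, alpha / 2)
    hi[i] <- orderStatQuantile(srt, 1 - alpha / 2)
  }
  data.frame(month = draws@months, lower = lo, upper = hi, level = level,
             stringsAsFactors = FALSE)
}

#' Root-mean-squared percentage error
#'
#' `sqrt(mean(((observed - predicted)/observed)^2))`, as a fraction.
#' Entities whose selected model reaches 12.5% or more on cross-validation
#' holdout predictions are excluded downstream.
#'
#' @param observed positive observed counts.
#' @param predicted out-of-sample mean predictions.
#' @return non-negative fraction.
#' @examples
#' rmspe(c(100, 100), c(90, 110))  # 0.1
#' @export
rmspe <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch", call. = FALSE)
  if (any(observed <= 0))
    stop("observed counts must be positive for RMSPE", call. = FALSE)
  sqrt(mean(((observed - predicted) / observed)^2))
}
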