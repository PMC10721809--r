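## Deviation statistics: relative observed-vs-expected differences per
## month, calendar quarter and named summary period, with Monte-Carlo
## percentile confidence intervals, add-one empirical p-values and
## Benjamini-Hochberg FDR adjustment.

#' Point deviation from expectation
#'
#' The relative difference between observed and expected patient counts,
#' `delta = (observed - expected) / expected`.
#'
#' @param observed non-negative observed count.
#' @param expected positive expected count.
#' @return numeric deviation (>= -1 for non-negative observed).
#' @examples
#' pointDeviation(33, 100)   # -0.67
#' pointDeviation(150, 100)  # 0.5
#' @export
pointDeviation <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be positive", call. = FALSE)
  if (any(observed < 0)) stop("observed must be non-negative", call. = FALSE)
  (observed - expected) / expected
}

## floor draws at 0.5 before the deviation transform; flag heavy zero mass
floorDraws <- function(y) {
  nzero <- sum(y == 0)
  list(y = pmax(y, 0.5), flagged = nzero > 0.001 * length(y),
       nzero = nzero)
}

## add-one two-sided empirical p from tail counts
addOneTwoSidedP <- function(nLow, nHigh, S) {
  min(1, 2 * min((1 + nLow) / (S + 1), (1 + nHigh) / (S + 1)))
}

#' Monthly deviation inference against the counterfactual distribution
#'
#' Computes the point deviation of the observed count from the model mean,
#' a 95% percentile confidence interval from the per-draw deviations
#' `(observed - y_s) / y_s` (draws floored at 0.5, with a flag when more
#' than 0.1% of draws are zero), and a two-sided add-one empirical p-value
#' from the draw tails around the observation.
#'
#' @param observed observed count for the month.
#' @param draws integer vector of Monte-Carlo counterfactual counts.
#' @param mu model-expected mean for the month.
#' @param level confidence level (default 0.95).
#' @return one-row data.frame: `delta`, `ci_lower`, `ci_upper`, `p_value`,
#'   `n_sims`, `flag_zero_draws`.
#' @export
monthlyInference <- function(observed, draws, mu, level = 0.95) {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  S <- length(draws)
  delta <- pointDeviation(observed, mu)
  fl <- floorDraws(draws)
  d <- (observed - fl$y) / fl$y
  srt <- sort.int(d, method = "quick")
  alpha <- 1 - level
  p <- addOneTwoSidedP(sum(draws <= observed), sum(draws >= observed), S)
  data.frame(delta = delta,
             ci_lower = orderStatQuantile(srt, alpha / 2),
             ci_upper = orderStatQuantile(srt, 1 - alpha / 2),
             p_value = p, n_sims = S, flag_zero_draws = fl$flagged)
}

#' Summary-period deviation inference
#'
#' The period point estimate is the mean over months of the monthly point
#' deviations.  The per-draw joint distribution is formed by averaging the
#' per-month per-draw deviations column-wise (`d_bar_s`), from which a
#' percentile confidence interval is taken; the two-sided add-one empirical
#' p-value references the sign of `d_bar_s` (does the counterfactual
#' deviation distribution straddle zero).
#'
#' @param observed observed counts over the period's months.
#' @param draws integer matrix, months x sims, columns aligned across
#'   months.
#' @param mu model-expected means over the period's months.
#' @param level confidence level (default 0.95).
#' @return one-row data.frame as in [monthlyInference()].
#' @export
periodInference <- function(observed, draws, mu, level = 0.95) {
  if (!is.matrix(draws) || nrow(draws) != length(observed) ||
      length(mu) != length(observed))
    stop("misaligned observed/draws/mu", call. = FALSE)
  S <- ncol(draws)
  delta <- mean(pointDeviation(observed, mu))
  fl <- floorDraws(draws)
  dbar <- colMeans((observed - fl$y) / fl$y)
  srt <- sort.int(dbar, method = "quick")
  alpha <- 1 - level
  p <- addOneTwoSidedP(sum(dbar >= 0), sum(dbar <= 0), S)
  data.frame(delta = delta,
             ci_lower = orderStatQuantile(srt, alpha / 2),
             ci_upper = orderStatQuantile(srt, 1 - alpha / 2),
             p_value = p, n_sims = S, flag_zero_draws = fl$flagged)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values, returned in input order and capped
#' at 1.  Inputs must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.05, 0.01))  # 0.05 0.02
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Default summary periods of the disruption window
#'
#' The acute hiatus (March-May 2020), the post-hiatus recovery window
#' (June 2020-December 2021), and the full pandemic study period
#' (January 2020-December 2021).
#'
#' @return data.frame with `name`, `start`, `end` (`YYYY-MM`).
#' @export
defaultPeriods <- function() {
  data.frame(name = c("hiatus", "post_hiatus", "pandemic"),
             start = c("2020-03", "2020-06", "2020-01"),
             end = c("2020-05", "2021-12", "2021-12"),
             stringsAsFactors = FALSE)
}

#' Default clustered quarters (Q3 2020 - Q4 2021)
#'
#' Calendar quarters of the post-hiatus window used for quarterly deviation
#' summaries and clustering.  June 2020 belongs to the post-hiatus period
#' average but to no clustered quarter.
#'
#' @return named list mapping quarter labels to their months.
#' @export
defaultQuarters <- function() {
  qs <- c("2020-Q3", "2020-Q4", "2021-Q1", "2021-Q2", "2021-Q3", "2021-Q4")
  months <- ymSeq("2020-07", "2021-12")
  split(months, factor(ymQuarter(months), levels = qs))
}

#' All deviation estimates for one entity
#'
#' Computes monthly deviations for every month of the prediction window,
#' quarterly deviations for the supplied quarters, and period deviations
#' for the supplied named periods (periods/quarters outside the window are
#' skipped).
#'
#' @param observed named observed counts over the prediction window
#'   (names are `YYYY-MM`).
#' @param draws a [CounterfactualDraws-class] covering the same window.
#' @param periods period definitions as from [defaultPeriods()].
#' @param quarters quarter->months list as from [defaultQuarters()].
#' @param level confidence level.
#' @return data.frame with `entity_id`, `timeframe_type` (`month`,
#'   `quarter`, `period`), `timeframe`, `delta`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n_sims`, `flag_zero_draws` (`p_adjusted` is added at the
#'   cross-entity family level, see [runPipeline()]).
#' @export
entityDeviations <- function(observed, draws, periods = defaultPeriods(),
                             quarters = defaultQuarters(), level = 0.95) {
  months <- draws@months
  if (!all(names(observed) == months))
    stop("observed months must align with draw months", call. = FALSE)
  mu <- draws@mu
  D <- draws@draws

  rows <- vector("list", 0)
  for (i in seq_along(months)) {
    r <- monthlyInference(observed[i], D[i, ], mu[i], level)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(timeframe_type = "month", timeframe = months[i],
                 stringsAsFactors = FALSE), r)
  }
  for (qn in names(quarters)) {
    idx <- match(quarters[[qn]], months)
    if (anyNA(idx)) next
    r <- periodInference(observed[idx], D[idx, , drop = FALSE], mu[idx], level)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(timeframe_type = "quarter", timeframe = qn,
                 stringsAsFactors = FALSE), r)
  }
  for (j in seq_len(nrow(periods))) {
    pm <- ymSeq(periods$start[j], periods$end[j])
    idx <- match(pm, months)
    if (anyNA(idx)) next
    r <- periodInference(observed[idx], D[idx, , drop = FALSE], mu[idx], level)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(timeframe_type = "period", timeframe = periods$name[j],
                 stringsAsFactors = FALSE), r)
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(entity_id = draws@entityId, stringsAsFactors = FALSE), out)
}
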