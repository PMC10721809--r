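## Synthetic registry-panel generator.  Emulates monthly patient counts per
## diagnosis entity with multiplicative seasonality, a linear-in-year trend,
## Poisson or negative-binomial dispersion, and a configurable disruption
## shock, plus planted trajectory clusters and severity-dependent shock
## depths.  All randomness is routed through per-entity substreams derived
## from (master seed, entity id), so output is independent of entity order.

#' Shock multiplier trajectory
#'
#' Evaluates the piecewise disruption multiplier of a [ShockProfile-class]
#' at calendar months: 1 before onset, linear descent from onset to the
#' nadir (multiplier `1 - A` at the nadir), then exponential approach from
#' `1 - A` toward the plateau `1 - B` at per-month rate `r`.
#'
#' @param profile a [ShockProfile-class].
#' @param months character vector of `YYYY-MM` months.
#' @return numeric vector of multipliers (>= 0), one per month.
#' @examples
#' p <- shockProfile("2020-03", "2020-04", 0.67, 0.13, 4)
#' shockMultiplier(p, c("2019-12", "2020-04", "2021-12"))
#' @export
shockMultiplier <- function(profile, months) {
  stopifnot(is(profile, "ShockProfile"))
  t <- ymToSerial(months)
  onset <- ymToSerial(profile@onset)
  nadir <- ymToSerial(profile@nadir)
  A <- profile@nadirDrop; B <- profile@plateauDrop; r <- profile@recoveryRate
  mult <- rep(1, length(t))
  desc <- t >= onset & t <= nadir
  ## linear descent anchored at multiplier 1 one month before onset
  mult[desc] <- 1 - A * (t[desc] - onset + 1) / (nadir - onset + 1)
  post <- t > nadir
  mult[post] <- (1 - B) + ((1 - A) - (1 - B)) * exp(-r * (t[post] - nadir))
  mult
}

## deterministic per-entity substream seed from (master seed, entity id);
## stable across sessions and independent of entity order in the panel
entitySeed <- function(masterSeed, entityId, salt = 0L) {
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(entityId))) h <- (h * 31 + ch) %% p
  h <- (h + (as.numeric(masterSeed) %% p)) %% p
  h <- (h * 48271) %% p
  h <- (h + as.numeric(salt) * 1000003) %% p
  as.integer(h)
}

#' Simulation configuration for synthetic registry panels
#'
#' Defines the study conditions under which panels are generated.  Entity
#' baseline/trend/seasonality parameters are drawn uniformly from the stated
#' ranges; the shock is either shared, taken from planted `clusters`, or —
#' when `severity = TRUE` — derived from each entity's severity rank via the
#' monotone mapping `A = 0.9 - 0.1 * rank`, `B = 0.25 - 0.04 * rank`, so
#' more severe conditions are planted with shallower drops.
#'
#' @param nEntities number of diagnosis entities (>= 1).
#' @param startMonth,endMonth contiguous month axis (default Jan 2017 -
#'   Dec 2021).
#' @param baselineLogMean range of the baseline log mean `beta0`.
#' @param trendPerYear range of the linear year trend on the log scale.
#' @param seasonalAmplitude range of the 12-month harmonic log-amplitude.
#' @param dispersionFamily `"poisson"` or `"negbin"`.
#' @param negbinSize negative-binomial size `theta` (> 0), used when
#'   `dispersionFamily = "negbin"`.
#' @param shock default [ShockProfile-class] applied to every entity;
#'   `shockProfile(nadirDrop = 0, plateauDrop = 0)` gives a null panel.
#' @param clusters optional list of [ShockProfile-class] objects; entities
#'   are assigned to clusters in round-robin order and take the cluster's
#'   shock (overrides `shock`).
#' @param severity if `TRUE`, severity ranks 1-5 are assigned round-robin
#'   and shocks follow the severity mapping (overrides `shock`/`clusters`).
#' @param recoveryRate per-month recovery rate used by severity-mapped
#'   shocks.
#' @param categories category labels recycled across entities.
#' @param meanFloor smallest admissible planted monthly mean; the default 15
#'   keeps generated counts above single digits so generated panels satisfy
#'   the count-based inclusion rule by construction.
#' @return a classed list of validated settings.
#' @export
simConfig <- function(nEntities = 50,
                      startMonth = "2017-01", endMonth = "2021-12",
                      baselineLogMean = c(5.0, 6.5),
                      trendPerYear = c(-0.04, 0.04),
                      seasonalAmplitude = c(0.1, 0.3),
                      dispersionFamily = c("poisson", "negbin"),
                      negbinSize = 5,
                      shock = shockProfile(),
                      clusters = NULL,
                      severity = FALSE,
                      recoveryRate = 4,
                      categories = c("retina", "cornea", "glaucoma",
                                     "cataract", "neuro"),
                      meanFloor = 15) {
  dispersionFamily <- match.arg(dispersionFamily)
  if (nEntities < 1) stop("nEntities must be >= 1", call. = FALSE)
  if (negbinSize <= 0) stop("negbinSize must be positive", call. = FALSE)
  months <- ymSeq(startMonth, endMonth)
  stopifnot(is(shock, "ShockProfile"))
  if (!is.null(clusters)) {
    if (!length(clusters) || !all(vapply(clusters, is, TRUE, "ShockProfile")))
      stop("clusters must be a non-empty list of ShockProfile objects",
           call. = FALSE)
  }
  structure(list(
    nEntities = as.integer(nEntities), months = months,
    baselineLogMean = baselineLogMean, trendPerYear = trendPerYear,
    seasonalAmplitude = seasonalAmplitude,
    dispersionFamily = dispersionFamily, negbinSize = negbinSize,
    shock = shock, clusters = clusters, severity = isTRUE(severity),
    recoveryRate = recoveryRate, categories = categories,
    meanFloor = meanFloor), class = "SimConfig")
}

## severity rank -> shock depth mapping (monotone: severe = shallower)
severityShock <- function(rank, recoveryRate = 4) {
  shockProfile(nadirDrop = 0.9 - 0.1 * rank, plateauDrop = 0.25 - 0.04 * rank,
               recoveryRate = recoveryRate)
}

## planted mean trajectory for one truth row over given months
plantedMeanRow <- function(tr, months) {
  s <- ymToSerial(months)
  t <- s - s[1] + tr$t0offset
  yearIdx <- ymYear(s) - tr$year0
  lp <- tr$beta0 + tr$trendPerYear * yearIdx +
    tr$amplitude * sin(2 * pi * t / 12 + tr$phase)
  sh <- shockProfile(tr$onset, tr$nadir, tr$nadirDrop, tr$plateauDrop,
                     tr$recoveryRate)
  exp(lp) * shockMultiplier(sh, months)
}

#' Planted mean trajectory of a synthetic entity
#'
#' Returns the exact expected count (seasonal-trend log-linear predictor
#' times shock multiplier) planted for an entity of a generated panel.
#'
#' @param truth the `truth` data.frame returned by [simulatePanel()].
#' @param entityId entity identifier (a row of `truth`).
#' @param months `YYYY-MM` months at which to evaluate the mean.
#' @return numeric vector of planted means.
#' @export
plantedMean <- function(truth, entityId, months) {
  i <- match(entityId, truth$entity_id)
  if (is.na(i)) stop("unknown entity id: ", entityId, call. = FALSE)
  plantedMeanRow(as.list(truth[i, ]), months)
}

#' Generate a synthetic monthly diagnosis-count panel
#'
#' Draws one count per entity-month from the configured dispersion family
#' with mean `exp(beta0 + trend * year + seasonal(month)) * shock(month)`,
#' and returns the panel together with the planted ground truth.  Output is
#' byte-identical for identical `(config, seed)` and independent of entity
#' ordering (each entity has its own seed substream).
#'
#' @param config a [simConfig()] object.
#' @param seed integer master seed.
#' @return a list with elements `panel` ([MonthlyPanel-class]) and `truth`
#'   (data.frame of planted parameters, one row per entity).
#' @examples
#' sim <- simulatePanel(simConfig(nEntities = 3), seed = 1)
#' sim$panel
#' @export
simulatePanel <- function(config, seed) {
  stopifnot(inherits(config, "SimConfig"))
  months <- config$months
  s <- ymToSerial(months)
  n <- config$nEntities
  ids <- sprintf("E%03d", seq_len(n))
  cats <- rep_len(config$categories, n)

  truth <- vector("list", n)
  counts <- matrix(0L, n, length(months), dimnames = list(ids, months))
  for (i in seq_len(n)) {
    ## parameter substream
    set.seed(entitySeed(seed, ids[i], salt = 1L))
    beta0 <- runif(1, config$baselineLogMean[1], config$baselineLogMean[2])
    trend <- runif(1, config$trendPerYear[1], config$trendPerYear[2])
    amp <- runif(1, config$seasonalAmplitude[1], config$seasonalAmplitude[2])
    phase <- runif(1, 0, 2 * pi)
    if (config$severity) {
      rank <- (i - 1L) %% 5L + 1L
      sh <- severityShock(rank, config$recoveryRate)
      cluster <- rank
    } else if (!is.null(config$clusters)) {
      cluster <- (i - 1L) %% length(config$clusters) + 1L
      sh <- config$clusters[[cluster]]
      rank <- NA_integer_
    } else {
      sh <- config$shock
      cluster <- 1L
      rank <- NA_integer_
    }
    tr <- list(entity_id = ids[i], category = cats[i], cluster_id = cluster,
               severity_rank = rank, beta0 = beta0, trendPerYear = trend,
               amplitude = amp, phase = phase,
               family = config$dispersionFamily,
               theta = if (config$dispersionFamily == "negbin")
                 config$negbinSize else NA_real_,
               onset = sh@onset, nadir = sh@nadir, nadirDrop = sh@nadirDrop,
               plateauDrop = sh@plateauDrop, recoveryRate = sh@recoveryRate,
               t0offset = 0L, year0 = ymYear(s[1]))
    mu <- plantedMeanRow(tr, months)
    if (any(mu < config$meanFloor)) {
      stop(sprintf(
        "planted mean for %s falls below the floor (%g < %g at %s)",
        ids[i], min(mu), config$meanFloor, months[which.min(mu)]),
        call. = FALSE)
    }
    ## count substream
    set.seed(entitySeed(seed, ids[i], salt = 2L))
    counts[i, ] <- if (config$dispersionFamily == "poisson") {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = config$negbinSize)
    }
    truth[[i]] <- tr
  }
  truth <- do.call(rbind, lapply(truth, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  list(panel = MonthlyPanel(counts, months, cats), truth = truth)
}

#' Write a panel to long-format CSV
#'
#' One row per entity-month with header `entity_id,category,month,count`.
#'
#' @param panel a [MonthlyPanel-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePanelCsv <- function(panel, path) {
  cts <- panelCounts(panel)
  cat_ <- entityCategories(panel)
  df <- data.frame(
    entity_id = rep(rownames(cts), each = ncol(cts)),
    category = rep(unname(cat_), each = ncol(cts)),
    month = rep(colnames(cts), times = nrow(cts)),
    count = as.integer(t(cts)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write planted ground truth to JSON
#'
#' @param truth truth data.frame from [simulatePanel()].
#' @param path output JSON path; the document is keyed by entity id.
#' @return `path`, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  rows <- split(truth, truth$entity_id)
  obj <- lapply(rows, function(r) as.list(r[1, setdiff(names(r), "entity_id")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
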