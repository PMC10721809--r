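## Panel IO, inclusion filtering and end-to-end orchestration.

#' Read a long-format monthly count panel
#'
#' Expects a CSV with header `entity_id,category,month,count`; months are
#' `YYYY-MM`, counts non-negative integers, the month axis shared and
#' contiguous across entities, and no duplicate entity-month rows.
#'
#' @param path CSV file path.
#' @return a [MonthlyPanel-class].
#' @export
readPanel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "character", "character",
                                "numeric"))
  need <- c("entity_id", "category", "month", "count")
  if (!identical(names(df), need))
    stop("panel CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  badMonth <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", df$month)
  if (any(badMonth))
    stop(sprintf("malformed month %s at row %d", sQuote(df$month[badMonth][1]),
                 which(badMonth)[1]), call. = FALSE)
  badCount <- is.na(df$count) | df$count < 0 | df$count != round(df$count)
  if (any(badCount))
    stop(sprintf("invalid count %s at row %d (field 'count')",
                 sQuote(df$count[badCount][1]), which(badCount)[1]),
         call. = FALSE)
  key <- paste(df$entity_id, df$month)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate row for entity %s, month %s", d$entity_id,
                 d$month), call. = FALSE)
  }
  months <- ymFormat(sort(unique(ymToSerial(df$month))))
  s <- ymToSerial(months)
  if (length(s) > 1 && !all(diff(s) == 1L))
    stop("gap in month axis: missing month(s) between ", months[1], " and ",
         months[length(months)], call. = FALSE)
  ids <- unique(df$entity_id)
  cats <- df$category[match(ids, df$entity_id)]
  M <- matrix(NA_real_, length(ids), length(months),
              dimnames = list(ids, months))
  M[cbind(match(df$entity_id, ids), match(df$month, months))] <- df$count
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing cell: entity %s, month %s", ids[miss[1]],
                 months[miss[2]]), call. = FALSE)
  }
  MonthlyPanel(M, months, cats)
}

#' Inclusion filtering of entities
#'
#' Stage 1 excludes entities whose count falls to single digits (<= 9) in
#' any month; stage 2 excludes entities whose selected counterfactual model
#' has out-of-sample RMSPE at or above `rmspeMax` (default 12.5%).
#'
#' @param panel a [MonthlyPanel-class].
#' @param fits optional named list of [FittedCounterfactual-class] (or a
#'   named numeric vector of RMSPE values); when absent only stage 1 runs.
#' @param rmspeMax RMSPE exclusion threshold (fraction, `>=` rule).
#' @param minCount smallest admissible monthly count (default 10).
#' @return list with `included` (entity ids) and `exclusions` (data.frame
#'   `entity_id`, `reason`).
#' @export
inclusionFilter <- function(panel, fits = NULL, rmspeMax = 0.125,
                            minCount = 10L) {
  cts <- panelCounts(panel)
  lowIds <- rownames(cts)[apply(cts < minCount, 1, any)]
  excl <- data.frame(entity_id = lowIds,
                     reason = rep("below single-digit count threshold",
                                  length(lowIds)),
                     stringsAsFactors = FALSE)
  included <- setdiff(rownames(cts), lowIds)
  if (!is.null(fits)) {
    rms <- if (is.numeric(fits)) fits
    else vapply(fits, cfRmspe, 1.0)
    poor <- included[included %in% names(rms) &
                       !is.na(rms[included]) & rms[included] >= rmspeMax]
    if (length(poor))
      excl <- rbind(excl, data.frame(
        entity_id = poor,
        reason = sprintf("poor model performance (RMSPE %.3f >= %.3f)",
                         rms[poor], rmspeMax),
        stringsAsFactors = FALSE))
    included <- setdiff(included, poor)
  }
  rownames(excl) <- NULL
  list(included = included, exclusions = excl)
}

## mean/sd summary of a deviation column, NA-safe
meanSd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)

#' Run the full counterfactual deviation pipeline
#'
#' Orchestrates, per included entity: blocked-CV model selection on the
#' training window, overdispersion routing, Monte-Carlo counterfactual
#' draws over the prediction window, monthly/quarterly/period deviation
#' inference; then cross-entity BH FDR adjustment (three families: all
#' monthly deviations, all quarterly deviations, and each named period),
#' recovery classification, hierarchical clustering of quarterly deviation
#' trajectories, heatmap intensities, and (optionally) severity tests.
#' Fully reproducible from `(panel, arguments, seed)` and invariant to
#' entity order (per-entity seed substreams).
#'
#' @param panel a [MonthlyPanel-class] covering both windows.
#' @param trainStart,trainEnd pre-disruption training window.
#' @param predictStart,predictEnd prediction (disruption) window.
#' @param nSims Monte-Carlo draws per entity-month (default 10000;
#'   1e5 reproduces registry-scale precision at ~10x the runtime).
#' @param seed master integer seed.
#' @param fdr FDR threshold used for recovery classification.
#' @param rmspeMax RMSPE exclusion threshold.
#' @param minCount stage-1 minimum monthly count.
#' @param periods period definitions ([defaultPeriods()]).
#' @param quarters quarter map ([defaultQuarters()]).
#' @param k optional number of clusters to cut the dendrogram into.
#' @param severity optional data.frame `entity_id`, `severity_rank` (1-5),
#'   optional logical `vt_flag`; severity tests are skipped when absent.
#' @param resampleCoefficients propagate coefficient uncertainty into the
#'   counterfactual draws (see [simulateCounterfactual()]); default
#'   `FALSE` (conditional on the fitted mean).
#' @param nadirMonth month whose deviations are used for severity tests and
#'   nadir summaries (default April 2020).
#' @param level confidence/PI level.
#' @param outDir optional directory; when given, writes `deviations.csv`,
#'   `prediction_intervals.csv`, `recovery.csv`, `clusters.csv`,
#'   `heatmap_matrix.csv`, `severity_tests.json` and `report.json`.
#' @param verbose emit per-stage progress messages.
#' @return list with `deviations`, `predictionIntervals`, `recovery`,
#'   `models`, `exclusions`, `cluster`, `heatmap`, `severityTests`,
#'   `report`.
#' @export
runPipeline <- function(panel,
                        trainStart = "2017-01", trainEnd = "2019-12",
                        predictStart = "2020-01", predictEnd = "2021-12",
                        nSims = 10000, seed = 1, fdr = 0.05,
                        rmspeMax = 0.125, minCount = 10L,
                        periods = defaultPeriods(),
                        quarters = defaultQuarters(),
                        k = NULL, severity = NULL,
                        resampleCoefficients = FALSE, nadirMonth = "2020-04",
                        level = 0.95, outDir = NULL, verbose = FALSE) {
  months <- panelMonths(panel)
  trainMonths <- ymSeq(trainStart, trainEnd)
  predMonths <- ymSeq(predictStart, predictEnd)
  if (!all(c(trainMonths, predMonths) %in% months))
    stop("panel does not cover the requested windows", call. = FALSE)
  note <- function(...) if (verbose) message(sprintf(...))

  stage1 <- inclusionFilter(panel, fits = NULL, rmspeMax, minCount)
  note("stage 1: %d/%d entities pass the count filter",
       length(stage1$included), nrow(panel))
  cts <- panelCounts(panel)

  ids <- sort(stage1$included)
  fits <- list(); devRows <- list(); piRows <- list(); modelRows <- list()
  excl2 <- character()
  for (id in ids) {
    fit <- fitCounterfactual(cts[id, trainMonths], trainMonths, id)
    fits[[id]] <- fit
    modelRows[[id]] <- data.frame(
      entity_id = id, spec_id = fit@spec$id, seasonal = fit@spec$seasonal,
      trend = fit@spec$trend, family = fit@family,
      family_param = fit@familyParam, dispersion = fit@dispersion,
      rmspe = fit@rmspe, stringsAsFactors = FALSE)
    if (!is.na(fit@rmspe) && fit@rmspe >= rmspeMax) {
      excl2 <- c(excl2, id)
      if (fit@rmspe < rmspeMax * 1.2)
        note("entity %s near the RMSPE boundary (%.3f)", id, fit@rmspe)
      next
    }
    draws <- simulateCounterfactual(fit, predMonths, nSims,
                                    entitySeed(seed, id, salt = 3L),
                                    resampleCoefficients)
    devRows[[id]] <- entityDeviations(cts[id, predMonths], draws, periods,
                                      quarters, level)
    pis <- predictionIntervals(draws, level)
    piRows[[id]] <- cbind(data.frame(entity_id = id, stringsAsFactors = FALSE),
                          pis, mu = draws@mu,
                          observed = as.integer(cts[id, predMonths]))
  }
  note("stage 2: %d entities excluded for RMSPE >= %.3f", length(excl2),
       rmspeMax)
  exclusions <- stage1$exclusions
  if (length(excl2)) {
    rms <- vapply(fits[excl2], cfRmspe, 1.0)
    exclusions <- rbind(exclusions, data.frame(
      entity_id = excl2,
      reason = sprintf("poor model performance (RMSPE %.3f >= %.3f)", rms,
                       rmspeMax),
      stringsAsFactors = FALSE))
  }
  included <- setdiff(ids, excl2)
  if (!length(included)) stop("no entities pass the filters", call. = FALSE)

  deviations <- do.call(rbind, devRows)
  rownames(deviations) <- NULL
  ## BH families: all monthly; all quarterly; each named period
  deviations$p_adjusted <- NA_real_
  isM <- deviations$timeframe_type == "month"
  isQ <- deviations$timeframe_type == "quarter"
  deviations$p_adjusted[isM] <- bhAdjust(deviations$p_value[isM])
  if (any(isQ)) deviations$p_adjusted[isQ] <- bhAdjust(deviations$p_value[isQ])
  for (pn in unique(deviations$timeframe[deviations$timeframe_type == "period"])) {
    isP <- deviations$timeframe_type == "period" & deviations$timeframe == pn
    deviations$p_adjusted[isP] <- bhAdjust(deviations$p_value[isP])
  }

  recovery <- recoveryTable(deviations, alpha = fdr)
  note("recovery: %d/%d entities recover",
       sum(recovery$status != "none"), nrow(recovery))

  ## clustering + heatmap intensities over quarterly deviations
  cluster <- NULL; heatmap <- NULL
  if (any(isQ) && length(included) >= 2) {
    QM <- quarterlyMatrix(deviations, names(quarters))
    cluster <- hierarchicalCluster(QM, k = k)
    qd <- deviations[isQ, , drop = FALSE]
    heatmap <- QM
    heatmap[cbind(match(qd$entity_id, rownames(QM)),
                  match(qd$timeframe, colnames(QM)))] <-
      heatmapIntensity(qd$delta, qd$p_adjusted)
  }

  ## severity association tests
  severityTests <- NULL
  nadirDelta <- deviations$delta[isM & deviations$timeframe == nadirMonth]
  names(nadirDelta) <- deviations$entity_id[isM &
                                              deviations$timeframe == nadirMonth]
  phDelta <- deviations$delta[deviations$timeframe_type == "period" &
                                deviations$timeframe == "post_hiatus"]
  names(phDelta) <- deviations$entity_id[deviations$timeframe_type == "period" &
                                           deviations$timeframe == "post_hiatus"]
  if (!is.null(severity)) {
    sv <- severity[severity$entity_id %in% included, , drop = FALSE]
    severityTests <- list()
    if (nrow(sv) >= 3 && var(sv$severity_rank) > 0) {
      severityTests$ols_nadir <- severityRegression(
        nadirDelta[sv$entity_id], sv$severity_rank)
      if (length(phDelta))
        severityTests$ols_post_hiatus <- severityRegression(
          phDelta[sv$entity_id], sv$severity_rank)
      severityTests$kruskal_wallis_nadir <- kruskalWallis(
        split(nadirDelta[sv$entity_id], sv$severity_rank))
    }
    if ("vt_flag" %in% names(sv) && any(sv$vt_flag) && any(!sv$vt_flag)) {
      severityTests$rank_sum_nadir <- rankSumTest(
        nadirDelta[sv$entity_id[sv$vt_flag]],
        nadirDelta[sv$entity_id[!sv$vt_flag]])
      if (length(phDelta))
        severityTests$rank_sum_post_hiatus <- rankSumTest(
          phDelta[sv$entity_id[sv$vt_flag]],
          phDelta[sv$entity_id[!sv$vt_flag]])
    }
  } else note("no severity table supplied; severity tests skipped")

  models <- do.call(rbind, modelRows)
  rownames(models) <- NULL
  cats <- entityCategories(panel)
  report <- list(
    config = list(trainStart = trainStart, trainEnd = trainEnd,
                  predictStart = predictStart, predictEnd = predictEnd,
                  nSims = nSims, seed = seed, fdr = fdr, rmspeMax = rmspeMax,
                  minCount = minCount, level = level,
                  resampleCoefficients = resampleCoefficients,
                  nadirMonth = nadirMonth, k = k),
    software = list(package = "CareDelta",
                    version = as.character(packageVersion("CareDelta"))),
    nInput = nrow(panel), nIncluded = length(included),
    nExcluded = nrow(exclusions),
    summaries = list(
      nadir_month = as.list(meanSd(nadirDelta)),
      periods = lapply(split(
        deviations[deviations$timeframe_type == "period", "delta"],
        deviations[deviations$timeframe_type == "period", "timeframe"]),
        function(x) as.list(meanSd(x))),
      mean_rmspe = mean(models$rmspe[models$entity_id %in% included],
                        na.rm = TRUE),
      recovery = as.list(table(recovery$status)),
      recovery_by_category = lapply(
        split(recovery$status, cats[recovery$entity_id]),
        function(s) as.list(table(s)))))

  out <- list(deviations = deviations,
              predictionIntervals = do.call(rbind, piRows),
              recovery = recovery, models = models, exclusions = exclusions,
              included = included, fits = fits, cluster = cluster,
              heatmap = heatmap, severityTests = severityTests,
              report = report)
  rownames(out$predictionIntervals) <- NULL
  if (!is.null(outDir)) writeRunArtifacts(out, outDir)
  out
}

#' Write pipeline artifacts to a directory
#'
#' @param run result of [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunArtifacts <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  write.csv(run$deviations, fp("deviations.csv"), row.names = FALSE)
  write.csv(run$predictionIntervals, fp("prediction_intervals.csv"),
            row.names = FALSE)
  write.csv(run$recovery, fp("recovery.csv"), row.names = FALSE)
  write.csv(run$exclusions, fp("exclusions.csv"), row.names = FALSE)
  if (!is.null(run$cluster)) {
    cl <- data.frame(entity_id = run$cluster$hclust$labels,
                     leaf_order = order(run$cluster$order),
                     stringsAsFactors = FALSE)
    if (!is.null(run$cluster$labels))
      cl$cluster <- run$cluster$labels[cl$entity_id]
    write.csv(cl, fp("clusters.csv"), row.names = FALSE)
    writeDendrogramNewick(run$cluster, fp("dendrogram.nwk"))
  }
  if (!is.null(run$heatmap))
    write.csv(as.data.frame(run$heatmap), fp("heatmap_matrix.csv"))
  if (!is.null(run$severityTests))
    jsonlite::write_json(run$severityTests, fp("severity_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outDir)
}
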