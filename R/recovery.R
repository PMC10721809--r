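## Recovery classification of monthly deviation trajectories.

#' Classify recovery of a monthly deviation trajectory
#'
#' A month is "bad" iff its deviation is negative and its FDR-adjusted
#' p-value is at most `alpha`.  Recovery is the first run of at least
#' `minRun` consecutive non-bad months; its 1-based start index (January
#' 2020 = 1 in the default study window) is the recovery month.  Recovery
#' is sustained iff no bad month occurs at or after that index, partial
#' otherwise; entities with no qualifying run (including a trailing non-bad
#' run shorter than `minRun`) have status `none`.
#'
#' @param delta ordered monthly deviation point estimates.
#' @param pAdjusted matching FDR-adjusted p-values.
#' @param months optional `YYYY-MM` labels for the months.
#' @param alpha significance threshold (default 0.05).
#' @param minRun required run length (default 3 months).
#' @return list with `status` (`"none"`, `"partial"`, `"sustained"`),
#'   `recoveryMonthIndex` (1-based; `NA` when `status == "none"`) and
#'   `recoveryMonth` (label or `NA`).
#' @examples
#' classifyRecovery(c(-1, -1, -1, rep(0, 9)), c(rep(0.01, 3), rep(1, 9)))
#' @export
classifyRecovery <- function(delta, pAdjusted, months = NULL, alpha = 0.05,
                             minRun = 3L) {
  n <- length(delta)
  if (length(pAdjusted) != n)
    stop("delta and pAdjusted lengths differ", call. = FALSE)
  if (anyNA(delta) || anyNA(pAdjusted))
    stop("missing months in trajectory", call. = FALSE)
  if (!is.null(months)) {
    s <- ymToSerial(months)
    if (length(s) != n || (n > 1 && !all(diff(s) == 1L)))
      stop("months must be ordered and contiguous", call. = FALSE)
  }
  bad <- delta < 0 & pAdjusted <= alpha

  start <- NA_integer_
  runLen <- 0L
  for (i in seq_len(n)) {
    if (!bad[i]) {
      runLen <- runLen + 1L
      if (runLen == minRun) {
        start <- i - minRun + 1L
        break
      }
    } else runLen <- 0L
  }
  if (is.na(start))
    return(list(status = "none", recoveryMonthIndex = NA_integer_,
                recoveryMonth = NA_character_))
  sustained <- !any(bad[start:n])
  list(status = if (sustained) "sustained" else "partial",
       recoveryMonthIndex = start,
       recoveryMonth = if (is.null(months)) NA_character_ else months[start])
}

#' Recovery table across entities
#'
#' Applies [classifyRecovery()] to each entity's monthly deviation rows of
#' a deviations table (which must carry `p_adjusted`).
#'
#' @param deviations deviations table as from [runPipeline()], containing
#'   monthly rows with `entity_id`, `timeframe`, `delta`, `p_adjusted`.
#' @param alpha significance threshold.
#' @param minRun required run length.
#' @return data.frame with `entity_id`, `status`, `recovery_month_index`,
#'   `recovery_month`.
#' @export
recoveryTable <- function(deviations, alpha = 0.05, minRun = 3L) {
  mo <- deviations[deviations$timeframe_type == "month", , drop = FALSE]
  if (!"p_adjusted" %in% names(mo))
    stop("deviations table lacks p_adjusted", call. = FALSE)
  res <- lapply(split(mo, mo$entity_id), function(d) {
    d <- d[order(ymToSerial(d$timeframe)), , drop = FALSE]
    r <- classifyRecovery(d$delta, d$p_adjusted, d$timeframe, alpha, minRun)
    data.frame(entity_id = d$entity_id[1], status = r$status,
               recovery_month_index = r$recoveryMonthIndex,
               recovery_month = r$recoveryMonth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
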