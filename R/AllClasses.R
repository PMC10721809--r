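#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef dnbinom dpois glm.fit lm optim p.adjust pchisq
#'   poisson quantile rnbinom rpois runif sd setNames var wilcox.test
#'   kruskal.test cor.test pt
#' @importFrom utils read.csv write.csv packageVersion
NULL

## ---------------------------------------------------------------------------
## MonthlyPanel: entities x months count matrix on a contiguous month axis
## ---------------------------------------------------------------------------

#' MonthlyPanel: observed monthly diagnosis counts
#'
#' A `MonthlyPanel` holds the observed patient-count series for a set of
#' diagnosis entities on a shared, contiguous month axis.  It extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are diagnosis entities
#' (with a `category` column in `rowData`), columns are calendar months
#' (`colData$month`, `YYYY-MM`), and the single `counts` assay stores
#' non-negative integer patient counts.
#'
#' @export
setClass("MonthlyPanel", contains = "SummarizedExperiment")

setValidity("MonthlyPanel", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts contain NA")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"month" %in% colnames(cd))
    msg <- c(msg, "colData must have a 'month' column (YYYY-MM)")
  else {
    s <- tryCatch(ymToSerial(cd$month), error = function(e) NULL)
    if (is.null(s)) msg <- c(msg, "colData$month labels are malformed")
    else if (length(s) > 1 && !all(diff(s) == 1L))
      msg <- c(msg, "months must be strictly increasing and contiguous")
  }
  if (!"category" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must have a 'category' column")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "entity ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MonthlyPanel
#'
#' @param counts integer matrix, entities x months; rownames are entity ids.
#' @param months character vector of contiguous `YYYY-MM` labels, one per
#'   column of `counts`.
#' @param categories character vector of diagnosis-category labels, one per
#'   entity (recycled if length 1).
#' @return a [MonthlyPanel-class] object.
#' @examples
#' cts <- matrix(50L, 2, 3, dimnames = list(c("a", "b"), NULL))
#' MonthlyPanel(cts, ymSeq("2019-01", "2019-03"), c("retina", "cornea"))
#' @export
MonthlyPanel <- function(counts, months, categories = "unknown") {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(months))
    stop("ncol(counts) must equal length(months)", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("entity_%03d", seq_len(nrow(counts)))
  categories <- rep_len(as.character(categories), nrow(counts))
  storage.mode(counts) <- "integer"
  colnames(counts) <- months
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(category = categories,
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(month = as.character(months),
                                   row.names = months))
  new("MonthlyPanel", se)
}

#' Panel accessors
#'
#' `panelMonths` returns the month axis (`YYYY-MM`), `entityIds` the entity
#' identifiers, `entityCategories` the named per-entity category labels and
#' `panelCounts` the integer entities x months count matrix.
#'
#' @param x a [MonthlyPanel-class].
#' @return see details above.
#' @name panel-accessors
#' @export
panelMonths <- function(x) as.character(SummarizedExperiment::colData(x)$month)

#' @rdname panel-accessors
#' @export
entityIds <- function(x) rownames(x)

#' @rdname panel-accessors
#' @export
entityCategories <- function(x) {
  setNames(as.character(SummarizedExperiment::rowData(x)$category), rownames(x))
}

#' @rdname panel-accessors
#' @export
panelCounts <- function(x) SummarizedExperiment::assay(x, "counts")

setMethod("show", "MonthlyPanel", function(object) {
  m <- panelMonths(object)
  cat("MonthlyPanel:", nrow(object), "entities x", ncol(object), "months [",
      m[1], "..", m[length(m)], "]\n")
  cat("categories:",
      paste(utils::head(unique(entityCategories(object)), 5), collapse = ", "),
      "\n")
})

## ---------------------------------------------------------------------------
## ShockProfile: piecewise disruption multiplier
## ---------------------------------------------------------------------------

#' ShockProfile: multiplicative disruption trajectory
#'
#' Parameterizes the pandemic-style shock applied to an entity's expected
#' monthly mean: identity (multiplier 1) before `onset`, linear descent from
#' `onset` to `nadir` reaching `1 - nadirDrop`, then exponential approach at
#' per-month rate `recoveryRate` toward the long-run plateau
#' `1 - plateauDrop` (a negative `plateauDrop` models exceedance).
#'
#' @slot onset calendar month (`YYYY-MM`), first disrupted month.
#' @slot nadir calendar month of the deepest drop.
#' @slot nadirDrop fraction `A` in `[0, 1]`: multiplier at nadir is `1 - A`.
#' @slot plateauDrop fraction `B` in `(-1, 1]`: long-run multiplier `1 - B`.
#' @slot recoveryRate non-negative per-month exponential rate `r`.
#' @export
setClass("ShockProfile", representation(
  onset = "character", nadir = "character",
  nadirDrop = "numeric", plateauDrop = "numeric", recoveryRate = "numeric"))

setValidity("ShockProfile", function(object) {
  msg <- character()
  on <- tryCatch(ymToSerial(object@onset), error = function(e) NULL)
  na <- tryCatch(ymToSerial(object@nadir), error = function(e) NULL)
  if (is.null(on) || is.null(na)) msg <- c(msg, "onset/nadir must be YYYY-MM")
  else if (na < on) msg <- c(msg, "nadir must not precede onset")
  A <- object@nadirDrop; B <- object@plateauDrop; r <- object@recoveryRate
  if (length(A) != 1 || is.na(A) || A < 0 || A > 1)
    msg <- c(msg, "nadirDrop must be a single value in [0, 1]")
  if (length(B) != 1 || is.na(B) || B <= -1 || B > 1)
    msg <- c(msg, "plateauDrop must be a single value in (-1, 1]")
  if (length(r) != 1 || is.na(r) || r < 0)
    msg <- c(msg, "recoveryRate must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' Construct a ShockProfile
#'
#' @param onset,nadir `YYYY-MM` calendar months, `onset <= nadir`.
#' @param nadirDrop fraction `A` in `[0, 1]` lost at the nadir.
#' @param plateauDrop long-run lost fraction `B` in `(-1, 1]`.
#' @param recoveryRate per-month exponential recovery rate (>= 0).
#' @return a [ShockProfile-class] object.
#' @examples
#' shockProfile("2020-03", "2020-04", 0.67, 0.13, 4)
#' @export
shockProfile <- function(onset = "2020-03", nadir = "2020-04",
                         nadirDrop = 0.67, plateauDrop = 0.13,
                         recoveryRate = 4) {
  new("ShockProfile", onset = onset, nadir = nadir,
      nadirDrop = as.numeric(nadirDrop), plateauDrop = as.numeric(plateauDrop),
      recoveryRate = as.numeric(recoveryRate))
}

setMethod("show", "ShockProfile", function(object) {
  cat(sprintf(
    "ShockProfile: onset %s, nadir %s (x%.3f), plateau x%.3f, rate %.2f/mo\n",
    object@onset, object@nadir, 1 - object@nadirDrop,
    1 - object@plateauDrop, object@recoveryRate))
})

## ---------------------------------------------------------------------------
## FittedCounterfactual
## ---------------------------------------------------------------------------

#' FittedCounterfactual: selected and dispersion-routed entity model
#'
#' The result of blocked cross-validation model selection plus overdispersion
#' assessment for one entity.  Coefficients are on the log-link scale of the
#' selected candidate; `family` records the simulation routing (`poisson`,
#' `overdispersed_poisson` with variance `phi * mu`, or `negbin` with
#' variance `mu + mu^2 / theta`).
#'
#' @slot entityId entity identifier.
#' @slot spec selected candidate (list: `id`, `seasonal`, `trend`, `nparam`).
#' @slot coefficients named numeric vector, log-link scale.
#' @slot dispersion Pearson dispersion statistic of the final fit.
#' @slot family one of `"poisson"`, `"overdispersed_poisson"`, `"negbin"`.
#' @slot familyParam `phi` (ODP) or `theta` (negbin); `NA` for Poisson.
#' @slot cvTable data.frame of per-candidate mean CV MSE.
#' @slot rmspe out-of-sample root-mean-squared percentage error (fraction).
#' @slot trainMonths `YYYY-MM` labels of the training window.
#' @slot holdoutPred cross-validation holdout mean predictions of the
#'   selected candidate, aligned with `trainMonths`.
#' @slot vcov asymptotic covariance of the coefficients (inverse Fisher
#'   information of the final fit), used by optional coefficient
#'   resampling.
#' @export
setClass("FittedCounterfactual", representation(
  entityId = "character", spec = "list", coefficients = "numeric",
  dispersion = "numeric", family = "character", familyParam = "numeric",
  cvTable = "data.frame", rmspe = "numeric", trainMonths = "character",
  holdoutPred = "numeric", vcov = "matrix"))

setValidity("FittedCounterfactual", function(object) {
  msg <- character()
  if (!object@family %in% c("poisson", "overdispersed_poisson", "negbin"))
    msg <- c(msg, "unknown family")
  if (object@family == "poisson" && !is.na(object@familyParam))
    msg <- c(msg, "poisson family carries no familyParam")
  if (object@family == "overdispersed_poisson" &&
      (is.na(object@familyParam) || object@familyParam <= 1))
    msg <- c(msg, "overdispersed_poisson requires phi > 1")
  if (object@family == "negbin" &&
      (is.na(object@familyParam) || object@familyParam <= 0))
    msg <- c(msg, "negbin requires theta > 0")
  if (length(object@rmspe) && !is.na(object@rmspe) && object@rmspe < 0)
    msg <- c(msg, "rmspe must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FittedCounterfactual", function(object) {
  cat(sprintf(
    "FittedCounterfactual <%s>: spec #%d (%s%s), family %s%s, RMSPE %.3f\n",
    object@entityId, object@spec$id, object@spec$seasonal,
    if (object@spec$trend) " + trend" else "", object@family,
    if (is.na(object@familyParam)) ""
    else sprintf(" (param %.3g)", object@familyParam),
    object@rmspe))
})

#' Fit accessors
#'
#' `cfFamily`, `cfSpec` and `cfRmspe` return the simulation family, the
#' selected candidate specification and the out-of-sample RMSPE of a
#' [FittedCounterfactual-class].
#'
#' @param x a [FittedCounterfactual-class].
#' @return family string, spec list, or RMSPE fraction respectively.
#' @name fit-accessors
#' @export
cfFamily <- function(x) x@family

#' @rdname fit-accessors
#' @export
cfSpec <- function(x) x@spec

#' @rdname fit-accessors
#' @export
cfRmspe <- function(x) x@rmspe

## ---------------------------------------------------------------------------
## CounterfactualDraws
## ---------------------------------------------------------------------------

#' CounterfactualDraws: Monte-Carlo counterfactual count distribution
#'
#' Simulated counterfactual counts for one entity over a prediction window.
#' `draws` is a months x nSims integer matrix; `mu` the model-expected mean
#' per month.
#'
#' @slot entityId entity identifier.
#' @slot months `YYYY-MM` labels of the prediction window.
#' @slot mu expected mean per month (log-link inverse of the fit).
#' @slot draws integer matrix, `length(months)` x `nSims`.
#' @export
setClass("CounterfactualDraws", representation(
  entityId = "character", months = "character", mu = "numeric",
  draws = "matrix"))

setValidity("CounterfactualDraws", function(object) {
  msg <- character()
  if (nrow(object@draws) != length(object@months))
    msg <- c(msg, "draws must have one row per month")
  if (length(object@mu) != length(object@months))
    msg <- c(msg, "mu must have one value per month")
  if (any(object@draws < 0)) msg <- c(msg, "draws must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CounterfactualDraws", function(object) {
  cat(sprintf("CounterfactualDraws <%s>: %d months x %d sims, mu in [%.1f, %.1f]\n",
              object@entityId, nrow(object@draws), ncol(object@draws),
              min(object@mu), max(object@mu)))
})

#' Draw accessors
#'
#' `nSims`, `drawMatrix` and `expectedMean` return the number of draws, the
#' months x sims integer draw matrix, and the named expected monthly means
#' of a [CounterfactualDraws-class].
#'
#' @param x a [CounterfactualDraws-class].
#' @return draw count, matrix, or named numeric vector respectively.
#' @name draw-accessors
#' @export
nSims <- function(x) ncol(x@draws)

#' @rdname draw-accessors
#' @export
drawMatrix <- function(x) x@draws

#' @rdname draw-accessors
#' @export
expectedMean <- function(x) setNames(x@mu, x@months)
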