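#' Dichotomize presence ratings into optimal versus sub-optimal
#'
#' A condition's perceived presence is optimal only under strong agreement
#' (rating 5); every alternative answer (1--4) is sub-optimal.  This cut-off
#' suits the right-skewed distribution of perceived presence: any other
#' division would shrink the sub-optimal fraction and leave bottlenecks
#' undetected.  A missing rating is not sub-optimal and is flagged unrated,
#' so it can never contribute to a bottleneck.
#'
#' @param rating numeric/integer vector of ratings in 1--5, NA = missing.
#' @return A list with logical vectors `suboptimal` and `rated`.
#' @examples
#' dichotomizePresence(c(5, 4, 1, NA))
#' @export
dichotomizePresence <- function(rating) {
  r <- as.numeric(rating)
  bad <- which(!is.na(r) & (r < 1 | r > 5 | r != floor(r)))
  if (length(bad))
    stop(sprintf("invalid rating %s at position %d; expected 1..5 or NA",
                 format(rating[bad[1]]), bad[1]))
  list(suboptimal = !is.na(r) & r < 5, rated = !is.na(r))
}

#' Resolve a top-5 importance selection onto registry conditions
#'
#' Pre-listed condition identifiers pass through; free-text additions are
#' recoded via [recodeAddedCondition()]; unmappable entries are dropped (the
#' count is attached as attribute `"dropped"`).  Duplicates collapse, since
#' importance is an unordered set: a condition is important if it appears in
#' the top 5, irrespective of its position therein.
#'
#' @param selections character vector of condition ids and/or free text.
#' @param registry a [ConditionRegistry-class].
#' @param recodeMap optional recode map (`free_text`, `condition_id`).
#' @return Character vector of distinct condition ids (possibly empty), with
#'   attribute `"dropped"` giving the number of dropped entries.
#' @examples
#' reg <- buildDefaultRegistry()
#' resolveImportance(c("imp_01", "int_03", "a lack of time"), reg)
#' @export
resolveImportance <- function(selections, registry, recodeMap = NULL) {
  selections <- as.character(selections)
  selections <- selections[nzchar(trimws(selections))]
  known <- selections %in% conditionIds(registry)
  resolved <- selections
  if (any(!known))
    resolved[!known] <- recodeAddedCondition(selections[!known], recodeMap, registry)
  dropped <- sum(is.na(resolved))
  out <- unique(resolved[!is.na(resolved)])
  attr(out, "dropped") <- dropped
  out
}

#' Flag sub-optimal, important and bottleneck conditions
#'
#' Builds the per-(intervention, condition) flag table: `suboptimal` from
#' [dichotomizePresence()], `important` from the resolved top-5 selections,
#' and `bottleneck = suboptimal AND important` -- a condition is a bottleneck
#' for an intervention when it is perceived as both important and
#' sub-optimally present.  The four flags are added to the survey as logical
#' assays.
#'
#' @param survey a [BottleneckSurvey-class].
#' @param recodeMap optional free-text recode map.
#' @param imputeMissingAsSuboptimal if TRUE, missing ratings are counted as
#'   sub-optimal (sensitivity analysis); the default treats them as not
#'   sub-optimal and unrated, which can only deflate percentages.
#' @return The survey with assays `suboptimal`, `important`, `bottleneck`,
#'   `rated`; `metadata(x)$flagging` records the number of dropped free-text
#'   selections and the total number of selections.
#' @examples
#' ds <- generateDataset(simulationConfig(nInterventions = 30L, seed = 1))
#' sv <- buildFlagTable(ds$survey, defaultRecodeMap(registry(ds$survey)))
#' summary(as.vector(flags(sv, "bottleneck")))
#' @export
buildFlagTable <- function(survey, recodeMap = NULL,
                           imputeMissingAsSuboptimal = FALSE) {
  r <- ratings(survey)
  d <- dichotomizePresence(r)
  subopt <- matrix(d$suboptimal, nrow(r), ncol(r), dimnames = dimnames(r))
  rated <- matrix(d$rated, nrow(r), ncol(r), dimnames = dimnames(r))
  if (imputeMissingAsSuboptimal) subopt[!rated] <- TRUE

  reg <- registry(survey)
  imp <- matrix(FALSE, nrow(r), ncol(r), dimnames = dimnames(r))
  sel <- importanceSelections(survey)
  dropped <- 0L
  totalSel <- 0L
  for (j in seq_along(sel)) {
    totalSel <- totalSel + length(sel[[j]])
    ids <- resolveImportance(sel[[j]], reg, recodeMap)
    dropped <- dropped + attr(ids, "dropped")
    if (length(ids)) imp[ids, j] <- TRUE
  }

  assays(survey, withDimnames = FALSE)$suboptimal <- subopt
  assays(survey, withDimnames = FALSE)$important <- imp
  assays(survey, withDimnames = FALSE)$bottleneck <- subopt & imp
  assays(survey, withDimnames = FALSE)$rated <- rated
  metadata(survey)$flagging <- list(
    droppedFreeText = dropped,
    totalSelections = totalSel,
    droppedFraction = if (totalSel) dropped / totalSel else 0,
    imputeMissingAsSuboptimal = imputeMissingAsSuboptimal
  )
  validObject(survey)
  survey
}

#' @describeIn buildFlagTable extract a flag assay (`"suboptimal"`,
#'   `"important"`, `"bottleneck"` or `"rated"`) as a logical matrix.
#' @param x a flagged [BottleneckSurvey-class].
#' @param which flag assay name.
#' @export
setMethod("flags", "BottleneckSurvey", function(x, which = "bottleneck") {
  which <- match.arg(which, c("bottleneck", "suboptimal", "important", "rated"))
  if (!hasFlags(x))
    stop("survey has no flag assays; run buildFlagTable() first")
  assay(x, which)
})

#' @describeIn buildFlagTable TRUE once the flag assays are present.
#' @export
setMethod("hasFlags", "BottleneckSurvey", function(x) {
  all(c("suboptimal", "important", "bottleneck", "rated") %in% names(assays(x)))
})

#' Export the flag table in long format
#'
#' @param survey a flagged [BottleneckSurvey-class].
#' @return data.frame with columns `intervention_id`, `condition_id`,
#'   `suboptimal`, `important`, `bottleneck`, `rated` (one row per cell).
#' @export
flagTable <- function(survey) {
  if (!hasFlags(survey))
    stop("survey has no flag assays; run buildFlagTable() first")
  cells <- expand.grid(condition_id = rownames(survey),
                       intervention_id = colnames(survey),
                       stringsAsFactors = FALSE)
  data.frame(intervention_id = cells$intervention_id,
             condition_id = cells$condition_id,
             suboptimal = as.vector(flags(survey, "suboptimal")),
             important = as.vector(flags(survey, "important")),
             bottleneck = as.vector(flags(survey, "bottleneck")),
             rated = as.vector(flags(survey, "rated")),
             stringsAsFactors = FALSE)
}

#' Per-condition descriptive profile across all systems
#'
#' For every condition, the percentage of intervention systems in which it
#' was marked sub-optimal, important and a bottleneck.  Denominators are all
#' `nSystems` systems (by default every surveyed intervention), so
#' missingness can only deflate the percentages.
#'
#' @param survey a flagged [BottleneckSurvey-class].
#' @param nSystems denominator; defaults to `ncol(survey)`.
#' @return data.frame with columns `condition_id`, `category`,
#'   `pct_suboptimal`, `pct_important`, `pct_bottleneck` (percentages on the
#'   0--100 scale, full precision).
#' @export
conditionProfile <- function(survey, nSystems = ncol(survey)) {
  if (nSystems < 1) stop("nSystems must be >= 1")
  pct <- function(a) 100 * rowSums(flags(survey, a)) / nSystems
  data.frame(condition_id = rownames(survey),
             category = rowData(survey)$category,
             pct_suboptimal = unname(pct("suboptimal")),
             pct_important = unname(pct("important")),
             pct_bottleneck = unname(pct("bottleneck")),
             stringsAsFactors = FALSE)
}

#' Aggregate a condition profile
#'
#' Mean, minimum and maximum of each percentage across conditions -- the
#' summary surface of a profile table (e.g. "on average sub-optimal in x% of
#' systems, range a--b").
#'
#' @param profile a profile data.frame from [conditionProfile()].
#' @return data.frame with rows `suboptimal`, `important`, `bottleneck` and
#'   columns `measure`, `mean`, `min`, `max`.
#' @export
profileAggregates <- function(profile) {
  agg <- function(v) c(mean = mean(v), min = min(v), max = max(v))
  m <- rbind(suboptimal = agg(profile$pct_suboptimal),
             important = agg(profile$pct_important),
             bottleneck = agg(profile$pct_bottleneck))
  data.frame(measure = rownames(m), m, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross-condition suboptimality-importance correlation
#'
#' Pearson product-moment correlation, across conditions, between the
#' percentage of systems in which a condition is sub-optimal and the
#' percentage in which it is placed in the top-5 of importance, with a
#' two-sided p-value.  A negative correlation indicates that widely
#' sub-optimal conditions tend not to be the ones deemed important.
#'
#' @param profile a profile data.frame from [conditionProfile()].
#' @return list with elements `r`, `p` and `n` (number of conditions).
#' @export
suboptimalImportanceCorrelation <- function(profile) {
  x <- profile$pct_suboptimal
  y <- profile$pct_important
  if (length(x) < 3)
    stop("correlation requires at least 3 conditions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant percentage vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
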