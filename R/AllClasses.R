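#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowData colData
#' @importFrom stats setNames rnorm runif sd cor.test
NULL

## Closed enumerations of the intervention-system taxonomy.  A system is the
## triple (behaviour change method, health theme, implementation setting); the
## 5 x 3 x 7 = 105 possible triples are the sample space of system keys.
.methodLevels <- c("education", "regulation", "facilitation",
                   "citizen_participation", "case_finding")
.themeLevels <- c("overweight", "alcohol", "other")
.settingLevels <- c("school", "outdoor_public", "sports_facility", "home",
                    "commercial_building", "health_welfare_building",
                    "public_building")

## The seven condition categories with their fixed questionnaire block sizes
## (5 + 5 + 10 + 10 + 11 + 4 + 2 = 47 conditions).
.categoryInfo <- data.frame(
  id = c("implementer", "co_implementer", "intervention", "implementer_org",
         "co_implementer_org", "broader_context", "implementation_strategy"),
  label = c("Prime implementer", "Co-implementer(s)", "Intervention",
            "Prime implementer's organization",
            "Co-implementer's organization(s)", "Broader context",
            "Implementation strategy"),
  prefix = c("imp", "coimp", "int", "org", "coorg", "ctx", "strategy"),
  expected_count = c(5L, 5L, 10L, 10L, 11L, 4L, 2L),
  stringsAsFactors = FALSE
)

#' Levels of the intervention-system taxonomy
#'
#' The closed enumerations used to classify each implemented intervention:
#' five behaviour change methods, three health themes and seven implementation
#' settings.
#'
#' @return A named list with character vectors `method`, `theme` and `setting`.
#' @examples
#' systemLevels()
#' @export
systemLevels <- function() {
  list(method = .methodLevels, theme = .themeLevels, setting = .settingLevels)
}

#' Condition category table
#'
#' The seven categories into which the 47 surveyed conditions for
#' implementation are organized, with the number of conditions each category
#' holds in the default registry.
#'
#' @return A data.frame with columns `id`, `label`, `prefix` and
#'   `expected_count` (summing to 47).
#' @examples
#' conditionCategories()
#' @export
conditionCategories <- function() {
  .categoryInfo
}

#' ConditionRegistry: the surveyed conditions for implementation
#'
#' An ordered collection of conditions, each with a stable identifier, one of
#' the seven categories, a statement text and a flag saying whether the
#' condition was pre-listed on the questionnaire.
#'
#' @slot conditions data.frame with columns `condition_id`, `category`,
#'   `statement`, `prelisted`.
#' @seealso [buildDefaultRegistry()], [loadRegistry()]
#' @exportClass ConditionRegistry
setClass("ConditionRegistry", representation(conditions = "data.frame"))

setValidity("ConditionRegistry", function(object) {
  df <- object@conditions
  need <- c("condition_id", "category", "statement", "prelisted")
  if (!all(need %in% names(df)))
    return(paste("conditions must have columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(df$category), .categoryInfo$id)
  if (length(bad))
    return(paste0("unknown condition category token(s): ",
                  paste(sQuote(bad), collapse = ", ")))
  if (anyDuplicated(df$condition_id))
    return(paste0("duplicate condition_id: ",
                  paste(sQuote(unique(df$condition_id[duplicated(df$condition_id)])),
                        collapse = ", ")))
  TRUE
})

#' SimulationConfig: parameters of the synthetic survey cohort
#'
#' Full parameterization of the synthetic cohort generator.  The defaults of
#' [simulationConfig()] reproduce the study conditions the analysis assumes:
#' 243 interventions in 30 projects by 120 implementers, the observed marginal
#' frequencies of methods, themes and settings, a right-skewed presence
#' distribution on the five-point scale, and a negative coupling between
#' perceived presence and selection into the top-5 of importance.
#'
#' @slot nProjects,nInterventions,nImplementers integer counts.
#' @slot methodWeights,themeWeights,settingWeights named non-negative sampling
#'   weights over the closed enumerations.
#' @slot presenceBase named numeric, per-condition latent presence mean.
#' @slot presenceSd positive numeric, latent noise standard deviation.
#' @slot cutpoints four strictly increasing thresholds mapping the latent
#'   presence score to the ordinal 1--5 rating.
#' @slot baseImportance named numeric, per-condition baseline importance score.
#' @slot importanceTemperature positive numeric softmax temperature.
#' @slot importanceCoupling numeric; multiplies the sub-optimality score
#'   `(5 - rating)/4` in the importance weight, so negative values make
#'   sub-optimally present conditions less likely to be called important
#'   (a negative cross-condition suboptimality-importance correlation).
#' @slot injectedEffects data.frame of condition-by-characteristic effects
#'   (`condition_id`, `field`, `level`, `presence_shift`, `importance_boost`).
#' @slot missingRate fraction in `[0, 1)` of ratings replaced by missing.
#' @slot freeTextAliasRate,freeTextDropRate fractions of importance selections
#'   rendered as recodable free text, or as unmappable free text that the
#'   pipeline will drop.
#' @slot seed integer random seed.
#' @slot registry the [ConditionRegistry-class] the cohort is generated for.
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nProjects = "integer",
  nInterventions = "integer",
  nImplementers = "integer",
  methodWeights = "numeric",
  themeWeights = "numeric",
  settingWeights = "numeric",
  presenceBase = "numeric",
  presenceSd = "numeric",
  cutpoints = "numeric",
  baseImportance = "numeric",
  importanceTemperature = "numeric",
  importanceCoupling = "numeric",
  injectedEffects = "data.frame",
  missingRate = "numeric",
  freeTextAliasRate = "numeric",
  freeTextDropRate = "numeric",
  seed = "integer",
  registry = "ConditionRegistry"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkW <- function(w, levels, what) {
    if (length(w) != length(levels))
      return(sprintf("%s must have %d entries", what, length(levels)))
    if (any(w < 0) || sum(w) <= 0)
      return(sprintf("%s must be non-negative with positive sum", what))
    NULL
  }
  msg <- c(msg,
           chkW(object@methodWeights, .methodLevels, "methodWeights"),
           chkW(object@themeWeights, .themeLevels, "themeWeights"),
           chkW(object@settingWeights, .settingLevels, "settingWeights"))
  if (length(object@cutpoints) != 4L || any(diff(object@cutpoints) <= 0))
    msg <- c(msg, "cutpoints must be 4 strictly increasing values")
  if (object@presenceSd <= 0)
    msg <- c(msg, "presenceSd must be > 0")
  if (object@importanceTemperature <= 0)
    msg <- c(msg, "importanceTemperature must be > 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  ids <- object@registry@conditions$condition_id
  if (!identical(sort(names(object@presenceBase)), sort(ids)))
    msg <- c(msg, "presenceBase must be named by the registry's condition ids")
  eff <- object@injectedEffects
  if (nrow(eff)) {
    if (!all(eff$condition_id %in% ids))
      msg <- c(msg, "injectedEffects reference conditions absent from the registry")
    lv <- systemLevels()
    ok <- eff$field %in% names(lv) &
      mapply(function(f, l) f %in% names(lv) && l %in% lv[[f]], eff$field, eff$level)
    if (!all(ok))
      msg <- c(msg, "injectedEffects reference unknown characteristic fields or levels")
  }
  if (length(msg)) msg else TRUE
})

#' BottleneckSurvey: a survey of conditions for implementation
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one column per implemented intervention and one row per surveyed
#' condition.  The `"ratings"` assay stores the 1--5 presence ratings (NA =
#' missing); after [buildFlagTable()] the logical assays `"suboptimal"`,
#' `"important"`, `"bottleneck"` and `"rated"` are added.  `colData` carries
#' the intervention metadata (project, implementer, method, theme, setting and
#' the raw top-5 importance selections); `rowData` mirrors the condition
#' registry.
#'
#' @seealso [BottleneckSurvey()], [generateDataset()], [readSurveyCsv()]
#' @exportClass BottleneckSurvey
setClass("BottleneckSurvey", contains = "SummarizedExperiment")

setValidity("BottleneckSurvey", function(object) {
  if (!"ratings" %in% names(assays(object)))
    return("a 'ratings' assay is required")
  r <- assay(object, "ratings")
  v <- r[!is.na(r)]
  if (length(v) && (any(v < 1) || any(v > 5) || any(v != floor(v))))
    return("ratings must be integers in 1..5 or NA")
  cd <- colData(object)
  need <- c("intervention_id", "project_id", "implementer_id",
            "method", "theme", "setting", "importance")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (ncol(object)) {
    if (!all(cd$method %in% .methodLevels))
      return("colData$method contains tokens outside the method enumeration")
    if (!all(cd$theme %in% .themeLevels))
      return("colData$theme contains tokens outside the theme enumeration")
    if (!all(cd$setting %in% .settingLevels))
      return("colData$setting contains tokens outside the setting enumeration")
    if (anyDuplicated(cd$intervention_id))
      return("intervention_id must be unique")
  }
  if (all(c("suboptimal", "important", "bottleneck") %in% names(assays(object)))) {
    b <- assay(object, "bottleneck")
    if (any(b & !(assay(object, "suboptimal") & assay(object, "important"))))
      return("bottleneck flags must imply suboptimal AND important")
  }
  TRUE
})

#' CongruenceMatrix: congruence labels for frequent systems
#'
#' Labels every (frequent intervention system, condition) pair by comparing
#' the bottleneck call in the frequent-system stratum with the calls in the
#' characteristic strata (method, theme, setting) the system belongs to:
#' `EPB` expectedly present, `UPB` unexpectedly present, `UAB` unexpectedly
#' absent, `concordant_absent` otherwise.
#'
#' @slot labels character matrix, rows = conditions, columns = frequent system
#'   keys, cells in `{"EPB","UPB","UAB","concordant_absent"}`.
#' @slot provenance named list; for each labelled pair, the characteristic
#'   fields whose strata carried the bottleneck.
#' @slot requireAll logical; whether a characteristic-linked bottleneck
#'   required all three matching characteristic strata (universal reading)
#'   rather than at least one (existential reading, the default).
#' @seealso [buildCongruenceMatrix()], [congruenceSummary()]
#' @exportClass CongruenceMatrix
setClass("CongruenceMatrix", representation(
  labels = "matrix",
  provenance = "list",
  requireAll = "logical"
))

setValidity("CongruenceMatrix", function(object) {
  ok <- c("EPB", "UPB", "UAB", "concordant_absent")
  if (!all(object@labels %in% ok))
    return(paste("labels must be one of:", paste(ok, collapse = ", ")))
  TRUE
})
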