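#' Construct a BottleneckSurvey
#'
#' Assembles the survey container from a ratings matrix, intervention
#' metadata, the condition registry and the raw top-5 importance selections.
#'
#' @param ratings integer matrix, conditions x interventions, values 1--5 or
#'   NA; rows must follow the registry order.
#' @param colData data.frame with columns `intervention_id`, `project_id`,
#'   `implementer_id`, `method`, `theme`, `setting` (validated enum tokens).
#' @param registry a [ConditionRegistry-class].
#' @param importance list (one element per intervention) of character vectors
#'   with at most five entries: pre-listed condition ids or free text.
#' @return A [BottleneckSurvey-class].
#' @export
BottleneckSurvey <- function(ratings, colData, registry, importance) {
  ratings <- as.matrix(ratings)
  mode(ratings) <- "integer"
  if (nrow(ratings) != nConditions(registry))
    stop("ratings must have one row per registry condition")
  rownames(ratings) <- conditionIds(registry)
  if (length(importance) != nrow(colData))
    stop("importance must have one element per intervention")
  if (any(lengths(importance) > 5L))
    stop("importance selections are limited to five per intervention")
  cd <- S4Vectors::DataFrame(colData)
  cd$importance <- IRanges::CharacterList(lapply(importance, as.character))
  rownames(cd) <- colData$intervention_id
  colnames(ratings) <- colData$intervention_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratings = ratings),
    rowData = S4Vectors::DataFrame(registry@conditions,
                                   row.names = conditionIds(registry)),
    colData = cd,
    metadata = list(registry = registry)
  )
  new("BottleneckSurvey", se)
}

#' @describeIn BottleneckSurvey the [ConditionRegistry-class] of the survey.
#' @export
setMethod("registry", "BottleneckSurvey", function(x) metadata(x)$registry)

#' @describeIn BottleneckSurvey the conditions x interventions rating matrix.
#' @export
setMethod("ratings", "BottleneckSurvey", function(x) assay(x, "ratings"))

#' @describeIn BottleneckSurvey the `"method|theme|setting"` key of each
#'   intervention.
#' @export
setMethod("systemKeys", "BottleneckSurvey", function(x) {
  cd <- colData(x)
  systemKeyString(cd$method, cd$theme, cd$setting)
})

#' @describeIn BottleneckSurvey the raw importance selections, a list of
#'   character vectors (condition ids or free text).
#' @export
setMethod("importanceSelections", "BottleneckSurvey", function(x) {
  as.list(colData(x)$importance)
})

setMethod("show", "BottleneckSurvey", function(object) {
  cat("BottleneckSurvey:", nrow(object), "conditions x", ncol(object),
      "intervention systems\n")
  cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
  if (ncol(object)) {
    cd <- colData(object)
    cat("  projects:", length(unique(cd$project_id)),
        " implementers:", length(unique(cd$implementer_id)), "\n")
    tal <- sort(table(systemKeys(object)), decreasing = TRUE)
    cat("  most frequent system:", names(tal)[1], sprintf("(n = %d)\n", tal[1]))
  }
})
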