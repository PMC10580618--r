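.stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr,
             error = function(e) stop(sprintf("[%s] %s", name,
                                              conditionMessage(e)),
                                      call. = FALSE)),
    warning = function(w) {
      warning(sprintf("[%s] %s", name, conditionMessage(w)), call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

#' Run the full bottleneck analysis pipeline
#'
#' End-to-end analysis of a survey of conditions for implementation:
#' flagging (dichotomization, importance resolution, bottleneck
#' conjunction), selection of frequent intervention systems, stratified
#' bottleneck calling, congruence labelling and summary statistics.
#' Deterministic for fixed inputs.
#'
#' @param survey a [BottleneckSurvey-class], or a path to a survey CSV.
#' @param registry a [ConditionRegistry-class] or registry CSV path;
#'   defaults to [buildDefaultRegistry()].  Required fields are only read
#'   when `survey` is a path.
#' @param recodeMap optional free-text recode map (data.frame or CSV path
#'   with columns `free_text`, `condition_id`).
#' @param minCount frequent-system frequency cut (strict; default 10).
#' @param threshold stratum bottleneck rate cut (strict fraction; default
#'   0.10).
#' @param frequentOnly restrict characteristic strata to interventions in
#'   frequent systems (sensitivity switch).
#' @param requireAllCharacteristics use the universal reading of a
#'   characteristic-linked bottleneck in the congruence labels.
#' @param imputeMissingAsSuboptimal count missing ratings as sub-optimal
#'   (sensitivity switch).
#' @param outDir if non-NULL, artifacts are written there via
#'   [writeOutputs()].
#' @return A run summary list (class `bottleneckRunSummary`) with elements
#'   `nInterventions`, `nConditions`, `profile`, `aggregates`,
#'   `correlation`, `tally`, `frequentSystems`, `coverage`, `profiles`
#'   (long stratified table), `congruence` ([CongruenceMatrix-class]),
#'   `congruenceSummary`, `flagging` (dropped free-text counts),
#'   `settings`, and `manifest` when `outDir` was given.
#' @examples
#' ds <- generateDataset(simulationConfig(nInterventions = 80L, seed = 3))
#' rs <- runPipeline(ds$survey, recodeMap = defaultRecodeMap(registry(ds$survey)))
#' rs$frequentSystems
#' @export
runPipeline <- function(survey,
                        registry = NULL,
                        recodeMap = NULL,
                        minCount = 10L,
                        threshold = 0.10,
                        frequentOnly = FALSE,
                        requireAllCharacteristics = FALSE,
                        imputeMissingAsSuboptimal = FALSE,
                        outDir = NULL) {
  if (is.character(registry)) registry <- .stage("registry", loadRegistry(registry))
  if (is.character(recodeMap))
    recodeMap <- .stage("recode_map",
                        utils::read.csv(recodeMap, stringsAsFactors = FALSE,
                                        colClasses = "character"))
  if (is.character(survey)) {
    if (is.null(registry)) registry <- buildDefaultRegistry()
    survey <- .stage("read_survey", readSurveyCsv(survey, registry))
  }
  stopifnot(is(survey, "BottleneckSurvey"))

  survey <- .stage("flagging",
                   buildFlagTable(survey, recodeMap = recodeMap,
                                  imputeMissingAsSuboptimal = imputeMissingAsSuboptimal))
  tally <- .stage("stratification", countSystems(survey))
  frequent <- selectFrequentSystems(tally, minCount)
  strata <- .stage("stratification",
                   buildStrata(survey, frequent = frequent,
                               frequentOnly = frequentOnly))
  profiles <- .stage("stratification",
                     stratumProfiles(survey, strata, threshold = threshold))
  profile <- .stage("profiling", conditionProfile(survey))
  correlation <- tryCatch(suboptimalImportanceCorrelation(profile),
                          error = function(e) list(r = NA_real_, p = NA_real_,
                                                   n = nrow(profile)))
  congruence <- .stage("congruence",
                       buildCongruenceMatrix(profiles,
                                             requireAll = requireAllCharacteristics))
  cgSummary <- .stage("congruence",
                      congruenceSummary(congruence, registry(survey)))

  out <- list(
    nInterventions = ncol(survey),
    nConditions = nrow(survey),
    profile = profile,
    aggregates = profileAggregates(profile),
    correlation = correlation,
    tally = tally,
    frequentSystems = frequent,
    coverage = list(
      n_frequent_systems = length(frequent),
      n_covered = sum(tally[frequent]),
      pct_covered = if (ncol(survey))
        100 * sum(tally[frequent]) / ncol(survey) else NA_real_),
    profiles = profiles,
    congruence = congruence,
    congruenceSummary = cgSummary,
    flagging = metadata(survey)$flagging,
    settings = list(minCount = minCount, threshold = threshold,
                    frequentOnly = frequentOnly,
                    requireAllCharacteristics = requireAllCharacteristics,
                    imputeMissingAsSuboptimal = imputeMissingAsSuboptimal),
    survey = survey
  )
  class(out) <- c("bottleneckRunSummary", "list")
  if (!is.null(outDir)) {
    out$manifest <- .stage("reporting",
                           writeOutputs(survey, profiles, congruence,
                                        .summaryForJson(out), outDir))
  }
  out
}

## JSON-serializable slice of a run summary: every number is recomputable
## from the exported CSV artifacts.
.summaryForJson <- function(rs) {
  list(
    n_interventions = rs$nInterventions,
    n_conditions = rs$nConditions,
    aggregates = rs$aggregates,
    correlation = rs$correlation,
    n_frequent_systems = rs$coverage$n_frequent_systems,
    frequent_systems = as.list(rs$tally[rs$frequentSystems]),
    coverage_pct = rs$coverage$pct_covered,
    per_system = rs$congruenceSummary$perSystem,
    overall = rs$congruenceSummary$overall,
    dropped_free_text = rs$flagging$droppedFreeText,
    dropped_free_text_fraction = rs$flagging$droppedFraction,
    settings = rs$settings
  )
}

#' @export
print.bottleneckRunSummary <- function(x, ...) {
  cat("Bottleneck analysis of", x$nInterventions, "intervention systems,",
      x$nConditions, "conditions\n")
  ag <- x$aggregates
  for (i in seq_len(nrow(ag)))
    cat(sprintf("  %% %s: mean %.1f (range %.1f-%.1f)\n", ag$measure[i],
                ag$mean[i], ag$min[i], ag$max[i]))
  if (!is.na(x$correlation$r))
    cat(sprintf("  suboptimality-importance correlation: r = %.2f (p = %.3g)\n",
                x$correlation$r, x$correlation$p))
  cat(sprintf("  frequent systems (n > %d): %d, covering %.0f%% of systems\n",
              x$settings$minCount, x$coverage$n_frequent_systems,
              x$coverage$pct_covered))
  ov <- x$congruenceSummary$overall
  cat(sprintf("  bottlenecks in frequent systems: %d (EPB %d, UPB %d; UAB %d)\n",
              ov$total_bottlenecks, ov$total_EPB, ov$total_UPB, ov$total_UAB))
  invisible(x)
}
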