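#' Tally intervention systems
#'
#' Exact multiset count of the `"method|theme|setting"` triples present in a
#' survey.
#'
#' @param survey a [BottleneckSurvey-class].
#' @return Named integer vector (decreasing), names = system keys.
#' @export
countSystems <- function(survey) {
  keys <- systemKeys(survey)
  if (!length(keys)) return(stats::setNames(integer(), character()))
  tab <- sort(table(keys), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}

#' Select frequent intervention systems
#'
#' Systems present strictly more than `minCount` times; the strict cut
#' excludes systems observed exactly `minCount` times.
#'
#' @param tally named counts from [countSystems()].
#' @param minCount frequency cut (default 10).
#' @return Character vector of frequent system keys.
#' @examples
#' selectFrequentSystems(c("a|b|c" = 11, "d|e|f" = 10))
#' @export
selectFrequentSystems <- function(tally, minCount = 10L) {
  names(tally)[tally > minCount]
}

#' Build the analysis strata
#'
#' Emits one stratum per frequent system (members = interventions with that
#' exact method-theme-setting triple), one per method, theme and setting
#' level present in the data (members = all interventions sharing that level,
#' regardless of frequent-system membership, unless `frequentOnly`), and one
#' all-systems stratum.  Empty levels are omitted.
#'
#' @param survey a [BottleneckSurvey-class].
#' @param frequent character vector of frequent system keys; by default
#'   computed via [countSystems()] and [selectFrequentSystems()].
#' @param minCount frequency cut used when `frequent` is not supplied.
#' @param frequentOnly if TRUE, characteristic and all-systems strata are
#'   restricted to interventions belonging to a frequent system (sensitivity
#'   analysis; the default uses all interventions).
#' @return Named list of strata; each stratum is a list with elements
#'   `kind` (`"frequent_system"`, `"method"`, `"theme"`, `"setting"` or
#'   `"all"`), `key` and `members` (intervention ids).
#' @export
buildStrata <- function(survey, frequent = NULL, minCount = 10L,
                        frequentOnly = FALSE) {
  keys <- systemKeys(survey)
  ids <- colnames(survey)
  if (is.null(frequent))
    frequent <- selectFrequentSystems(countSystems(survey), minCount)
  miss <- setdiff(frequent, keys)
  if (length(miss))
    stop("frequent systems not present in the survey: ",
         paste(sQuote(miss), collapse = ", "))
  pool <- if (frequentOnly) ids[keys %in% frequent] else ids
  poolKeys <- keys[match(pool, ids)]
  strata <- list()
  for (k in frequent) {
    strata[[paste0("frequent_system:", k)]] <-
      list(kind = "frequent_system", key = k, members = ids[keys == k])
  }
  parts <- .splitSystemKey(poolKeys)
  for (field in c("method", "theme", "setting")) {
    for (lev in systemLevels()[[field]]) {
      members <- pool[parts[[field]] == lev]
      if (length(members))
        strata[[paste0(field, ":", lev)]] <-
          list(kind = field, key = lev, members = members)
    }
  }
  if (length(pool))
    strata[["all:all"]] <- list(kind = "all", key = "all", members = pool)
  strata
}

#' Per-stratum bottleneck profile
#'
#' For each condition, the fraction of the stratum's intervention systems in
#' which it was flagged a bottleneck, and the stratum-level bottleneck call:
#' a condition is a bottleneck for the stratum when flagged in strictly more
#' than `threshold` of its members.  The comparison is exact-rational
#' (`n_flagged * D > round(threshold * D) * n_members`, `D = 1e4`), so an
#' exact 10% rate is never called.
#'
#' @param stratum one stratum from [buildStrata()].
#' @param survey a flagged [BottleneckSurvey-class].
#' @param threshold rate cut as a fraction (default 0.10, strict).
#' @param flag which flag assay to profile (default `"bottleneck"`).
#' @return data.frame with columns `stratum_kind`, `stratum_key`,
#'   `condition_id`, `n_members`, `n_flagged`, `rate`, `is_bottleneck`.
#' @examples
#' ds <- generateDataset(simulationConfig(nInterventions = 60L, seed = 2))
#' sv <- buildFlagTable(ds$survey)
#' st <- buildStrata(sv)
#' head(stratumProfile(st[["all:all"]], sv))
#' @export
stratumProfile <- function(stratum, survey, threshold = 0.10,
                           flag = "bottleneck") {
  if (!length(stratum$members)) stop("empty stratum: ", stratum$key)
  m <- flags(survey, flag)[, stratum$members, drop = FALSE]
  n <- length(stratum$members)
  nf <- as.integer(rowSums(m))
  D <- 10000L
  data.frame(stratum_kind = stratum$kind,
             stratum_key = stratum$key,
             condition_id = rownames(m),
             n_members = n,
             n_flagged = nf,
             rate = nf / n,
             is_bottleneck = nf * D > as.integer(round(threshold * D)) * n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bottleneck profiles for a collection of strata
#'
#' Applies [stratumProfile()] to every stratum and binds the results into
#' one long table, the export format for the stratified analysis.
#'
#' @param survey a flagged [BottleneckSurvey-class].
#' @param strata list from [buildStrata()]; computed by default.
#' @param threshold rate cut (strict fraction, default 0.10).
#' @param minCount frequent-system cut used when `strata` is not supplied.
#' @param frequentOnly see [buildStrata()].
#' @return Long data.frame (strata x conditions).
#' @export
stratumProfiles <- function(survey, strata = NULL, threshold = 0.10,
                            minCount = 10L, frequentOnly = FALSE) {
  if (is.null(strata))
    strata <- buildStrata(survey, minCount = minCount,
                          frequentOnly = frequentOnly)
  if (!length(strata))
    return(data.frame(stratum_kind = character(), stratum_key = character(),
                      condition_id = character(), n_members = integer(),
                      n_flagged = integer(), rate = numeric(),
                      is_bottleneck = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(strata, stratumProfile, survey = survey,
                               threshold = threshold))
  rownames(out) <- NULL
  out
}
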