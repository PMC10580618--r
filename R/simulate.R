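## Free-text answers that cannot be recoded onto a pre-listed condition;
## generic complaints of the kind respondents add to the importance top-5.
.unmappablePhrases <- c("a lack of time", "insufficient skills",
                        "short of manpower in general")

#' Simulation configuration for the synthetic survey cohort
#'
#' Builds a validated [SimulationConfig-class].  The defaults encode the
#' cohort the analysis pipeline is designed for: 243 implemented
#' interventions in 30 projects reported by 120 implementers; marginal system
#' frequencies of 137/57/25/13/11 over the behaviour change methods
#' (education, facilitation, regulation, case finding, citizen
#' participation), 123/102/16 over the health themes (overweight, alcohol,
#' other) and 75/38/38/24/24/24/15 over the settings (school, outdoor public
#' site, public building, health/welfare building, sports facility,
#' commercial building, home); a right-skewed five-point presence
#' distribution generated by a latent-threshold (cumulative) ordinal model;
#' and a top-5 importance sampler whose negative coupling to sub-optimality
#' reproduces a moderately negative cross-condition correlation between the
#' percentage of systems in which a condition is sub-optimal and the
#' percentage in which it is called important.
#'
#' Presence ratings follow `rating = 1 + #\{cutpoints below latent\}` with
#' `latent = presenceBase + injected shifts + N(0, presenceSd)`.  Importance
#' is a weighted draw of five distinct conditions with weight
#' `exp((baseImportance + injected boost + importanceCoupling * s) /
#' importanceTemperature)` where `s = (5 - rating)/4` is the sub-optimality
#' score (missing ratings use the neutral `s = 0.5`).
#'
#' @param nProjects,nInterventions,nImplementers cohort sizes.
#' @param methodWeights,themeWeights,settingWeights sampling weights over the
#'   enumerations, in the order of [systemLevels()].
#' @param jointSystemWeights optional named weights over full
#'   `"method|theme|setting"` keys; when supplied, system triples are drawn
#'   jointly from these keys instead of independently per characteristic.
#' @param presenceBase per-condition latent mean; the default is
#'   back-transformed from a mildly skewed spread of per-condition
#'   sub-optimal probabilities over 40--83% with mean near 56.5%.
#' @param presenceSd latent noise standard deviation.
#' @param cutpoints four increasing latent thresholds; the default
#'   `(-2, -1.2, -0.4, 0.3)` makes "strongly agree" the modal answer.
#' @param baseImportance per-condition baseline importance score; the default
#'   cycles over `(-0.45, -0.15, 0.15, 0.45)`, adding importance
#'   heterogeneity unrelated to presence; together with the default coupling
#'   it yields a cross-condition suboptimality-importance correlation near
#'   -0.4.
#' @param importanceTemperature softmax temperature.
#' @param importanceCoupling coupling of importance to sub-optimality;
#'   negative values yield the negative suboptimality-importance correlation.
#' @param injectedEffects data.frame (`condition_id`, `field`, `level`,
#'   `presence_shift`, `importance_boost`) of ground-truth
#'   condition-by-characteristic bottleneck effects.
#' @param missingRate fraction of ratings replaced by missing.
#' @param freeTextAliasRate,freeTextDropRate fractions of importance
#'   selections rendered as recodable free text (an alias the default recode
#'   map resolves) or as unmappable free text that the pipeline drops.
#' @param seed integer seed; [generateDataset()] is fully deterministic
#'   given the configuration.
#' @param registry the [ConditionRegistry-class] to simulate for.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' cfg
#' @export
simulationConfig <- function(nProjects = 30L,
                             nInterventions = 243L,
                             nImplementers = 120L,
                             methodWeights = c(education = 137, regulation = 25,
                                               facilitation = 57,
                                               citizen_participation = 11,
                                               case_finding = 13),
                             themeWeights = c(overweight = 123, alcohol = 102,
                                              other = 16),
                             settingWeights = c(school = 75, outdoor_public = 38,
                                                sports_facility = 24, home = 15,
                                                commercial_building = 24,
                                                health_welfare_building = 24,
                                                public_building = 38),
                             jointSystemWeights = NULL,
                             presenceBase = NULL,
                             presenceSd = 1,
                             cutpoints = c(-2, -1.2, -0.4, 0.3),
                             baseImportance = NULL,
                             importanceTemperature = 1,
                             importanceCoupling = -3,
                             injectedEffects = NULL,
                             missingRate = 0.02,
                             freeTextAliasRate = 0.11,
                             freeTextDropRate = 0.11,
                             seed = 1L,
                             registry = buildDefaultRegistry()) {
  ids <- conditionIds(registry)
  n <- length(ids)
  if (is.null(presenceBase)) {
    ## back-transform from target sub-optimal probabilities: a mildly skewed
    ## spread over 40..83% with mean ~56.5% under the default cutpoints
    pSub <- 0.40 + 0.43 * seq(0, 1, length.out = n)^1.6
    presenceBase <- stats::setNames(cutpoints[4] - stats::qnorm(pSub), ids)
  }
  if (is.null(names(presenceBase))) names(presenceBase) <- ids
  if (is.null(baseImportance))
    baseImportance <- stats::setNames(rep(c(-0.45, -0.15, 0.15, 0.45),
                                          length.out = n), ids)
  if (is.null(names(baseImportance))) names(baseImportance) <- ids
  if (is.null(injectedEffects))
    injectedEffects <- data.frame(condition_id = character(),
                                  field = character(), level = character(),
                                  presence_shift = numeric(),
                                  importance_boost = numeric(),
                                  stringsAsFactors = FALSE)
  mw <- .namedWeights(methodWeights, .methodLevels, "methodWeights")
  tw <- .namedWeights(themeWeights, .themeLevels, "themeWeights")
  sw <- .namedWeights(settingWeights, .settingLevels, "settingWeights")
  cfg <- new("SimulationConfig",
             nProjects = as.integer(nProjects),
             nInterventions = as.integer(nInterventions),
             nImplementers = as.integer(nImplementers),
             methodWeights = mw, themeWeights = tw, settingWeights = sw,
             presenceBase = presenceBase[ids],
             presenceSd = presenceSd,
             cutpoints = cutpoints,
             baseImportance = baseImportance[ids],
             importanceTemperature = importanceTemperature,
             importanceCoupling = importanceCoupling,
             injectedEffects = injectedEffects,
             missingRate = missingRate,
             freeTextAliasRate = freeTextAliasRate,
             freeTextDropRate = freeTextDropRate,
             seed = as.integer(seed),
             registry = registry)
  if (!is.null(jointSystemWeights)) {
    keys <- names(jointSystemWeights)
    parts <- .splitSystemKey(keys)
    .matchEnum(parts$method, .methodLevels, "method")
    .matchEnum(parts$theme, .themeLevels, "theme")
    .matchEnum(parts$setting, .settingLevels, "setting")
    attr(cfg, "jointSystemWeights") <- jointSystemWeights
  }
  cfg
}

.namedWeights <- function(w, levels, what) {
  if (is.null(names(w))) names(w) <- levels
  if (!setequal(names(w), levels))
    stop(what, " must be named by: ", paste(levels, collapse = ", "))
  w <- w[levels]
  if (any(w < 0) || sum(w) <= 0)
    stop(what, " must be non-negative with positive sum")
  w
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nInterventions, "interventions,",
      object@nProjects, "projects,", object@nImplementers, "implementers\n")
  cat("  registry:", nConditions(object@registry), "conditions;",
      "seed:", object@seed, "\n")
  cat("  importance coupling:", object@importanceCoupling,
      " missing rate:", object@missingRate, "\n")
  if (nrow(object@injectedEffects))
    cat("  injected effects:", nrow(object@injectedEffects), "pair(s)\n")
})

## Per-condition injected effect totals for one system (named numeric).
.effectVector <- function(config, method, theme, setting, column) {
  ids <- conditionIds(config@registry)
  out <- stats::setNames(numeric(length(ids)), ids)
  eff <- config@injectedEffects
  if (!nrow(eff)) return(out)
  sys <- c(method = method, theme = theme, setting = setting)
  hit <- sys[eff$field] == eff$level
  for (i in which(hit)) out[eff$condition_id[i]] <- out[eff$condition_id[i]] + eff[[column]][i]
  out
}

#' Sample system assignments for a synthetic cohort
#'
#' Draws `nInterventions` intervention systems: method, theme and setting are
#' drawn independently from their normalized weight vectors (or jointly from
#' `jointSystemWeights` when the configuration carries one), the project
#' uniformly over `nProjects`, and the implementer with replacement from a
#' pool of `nImplementers` (one implementer may hold several interventions).
#' Consumes the current RNG stream; [generateDataset()] seeds it.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `intervention_id`, `project_id`,
#'   `implementer_id`, `method`, `theme`, `setting`.
#' @export
sampleSystemAssignments <- function(config) {
  n <- config@nInterventions
  joint <- attr(config, "jointSystemWeights")
  if (!is.null(joint)) {
    keys <- sample(names(joint), n, replace = TRUE, prob = joint / sum(joint))
    sys <- .splitSystemKey(keys)
  } else {
    sys <- data.frame(
      method = sample(.methodLevels, n, replace = TRUE,
                      prob = config@methodWeights / sum(config@methodWeights)),
      theme = sample(.themeLevels, n, replace = TRUE,
                     prob = config@themeWeights / sum(config@themeWeights)),
      setting = sample(.settingLevels, n, replace = TRUE,
                       prob = config@settingWeights / sum(config@settingWeights)),
      stringsAsFactors = FALSE)
  }
  data.frame(
    intervention_id = sprintf("iv_%04d", seq_len(n)),
    project_id = sprintf("proj_%02d", sample.int(config@nProjects, n, replace = TRUE)),
    implementer_id = sprintf("impl_%03d", sample.int(config@nImplementers, n, replace = TRUE)),
    sys, stringsAsFactors = FALSE)
}

#' Sample presence ratings for one intervention system
#'
#' Latent-threshold draw of the 1--5 presence ratings for a single system:
#' `latent = presenceBase + injected presence shifts matching the system +
#' N(0, presenceSd)`, `rating = 1 + #\{cutpoints below latent\}`; each rating
#' is then replaced by missing with probability `missingRate`.
#'
#' @param system named character vector with `method`, `theme`, `setting`
#'   (e.g. from [parseSystem()]).
#' @param config a [SimulationConfig-class].
#' @return Named integer vector over the registry's conditions (NA = missing).
#' @export
samplePresenceRatings <- function(system, config) {
  ids <- conditionIds(config@registry)
  shift <- .effectVector(config, system[["method"]], system[["theme"]],
                         system[["setting"]], "presence_shift")
  latent <- config@presenceBase + shift +
    stats::rnorm(length(ids), 0, config@presenceSd)
  rating <- 1L + findInterval(latent, config@cutpoints)
  if (config@missingRate > 0)
    rating[stats::runif(length(ids)) < config@missingRate] <- NA_integer_
  stats::setNames(as.integer(rating), ids)
}

#' Sample a top-5 importance selection
#'
#' Draws five distinct conditions without replacement with weight
#' `exp((baseImportance + injected boost + importanceCoupling * s) /
#' importanceTemperature)`, `s = (5 - rating)/4` (missing ratings use the
#' neutral 0.5; unrated conditions remain eligible, as respondents may deem a
#' condition important without a usable rating).  If fewer than five
#' conditions exist, all are returned.
#'
#' @param ratings named integer vector of ratings (NA allowed).
#' @param system named character vector with `method`, `theme`, `setting`.
#' @param config a [SimulationConfig-class].
#' @return Character vector of up to five condition ids.
#' @export
sampleImportance <- function(ratings, system, config) {
  ids <- conditionIds(config@registry)
  s <- (5 - as.numeric(ratings[ids])) / 4
  s[is.na(s)] <- 0.5
  boost <- .effectVector(config, system[["method"]], system[["theme"]],
                         system[["setting"]], "importance_boost")
  score <- (config@baseImportance + boost + config@importanceCoupling * s) /
    config@importanceTemperature
  w <- exp(score - max(score))
  k <- min(5L, length(ids))
  sample(ids, k, prob = w)
}

#' Generate a synthetic survey dataset with ground truth
#'
#' Composes the three samplers into a full cohort: system assignments,
#' presence ratings, top-5 importance selections, and free-text noise in the
#' importance answers (a fraction rendered as recodable aliases that
#' [defaultRecodeMap()] resolves, and a fraction as unmappable generic
#' complaints the pipeline drops).  Fully deterministic given the
#' configuration, including its seed.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `survey` (a [BottleneckSurvey-class]) and
#'   `truth` (list: `pairs`, the injected condition-by-characteristic effects
#'   with a nonzero presence shift; `latent`, the latent presence matrix).
#' @examples
#' ds <- generateDataset(simulationConfig(nInterventions = 40L, seed = 7))
#' ds$survey
#' @export
generateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ids <- conditionIds(config@registry)
  p <- length(ids)
  n <- config@nInterventions
  assign <- sampleSystemAssignments(config)

  shift <- matrix(0, p, n, dimnames = list(ids, NULL))
  boost <- matrix(0, p, n, dimnames = list(ids, NULL))
  eff <- config@injectedEffects
  if (nrow(eff) && n) {
    for (i in seq_len(nrow(eff))) {
      cols <- assign[[eff$field[i]]] == eff$level[i]
      shift[eff$condition_id[i], cols] <- shift[eff$condition_id[i], cols] +
        eff$presence_shift[i]
      boost[eff$condition_id[i], cols] <- boost[eff$condition_id[i], cols] +
        eff$importance_boost[i]
    }
  }

  latent <- config@presenceBase + shift +
    matrix(stats::rnorm(p * n, 0, config@presenceSd), p, n)
  ratingsM <- matrix(1L + findInterval(latent, config@cutpoints), p, n,
                     dimnames = list(ids, NULL))
  if (config@missingRate > 0 && n)
    ratingsM[matrix(stats::runif(p * n) < config@missingRate, p, n)] <- NA_integer_

  importance <- vector("list", n)
  s <- (5 - ratingsM) / 4
  s[is.na(s)] <- 0.5
  scoreM <- (config@baseImportance + boost + config@importanceCoupling * s) /
    config@importanceTemperature
  k <- min(5L, p)
  for (j in seq_len(n)) {
    w <- exp(scoreM[, j] - max(scoreM[, j]))
    sel <- sample(ids, k, prob = w)
    u <- stats::runif(k)
    drop <- u < config@freeTextDropRate
    alias <- !drop & u < config@freeTextDropRate + config@freeTextAliasRate
    if (any(drop))
      sel[drop] <- sample(.unmappablePhrases, sum(drop), replace = TRUE)
    sel[alias] <- paste("alias:", sel[alias])
    importance[[j]] <- sel
  }

  survey <- BottleneckSurvey(ratingsM, assign, config@registry, importance)
  truth <- list(
    pairs = eff[eff$presence_shift != 0,
                c("condition_id", "field", "level"), drop = FALSE],
    latent = latent
  )
  list(survey = survey, truth = truth)
}

#' Reference configuration for recovery experiments
#'
#' A cohort configuration with exchangeable conditions: every condition gets
#' the same latent presence mean (sub-optimal with probability ~0.565 under
#' the default cutpoints) and the same baseline importance.  Without
#' injected effects no (condition, characteristic level) pair is
#' systematically bottleneck-prone, so any stratum-level call is a chance
#' event -- the proper null for measuring false-call rates.  With injected
#' effects it isolates the characteristic-linked signal from per-condition
#' heterogeneity.
#'
#' @param seed integer seed.
#' @param injectedEffects optional ground-truth effect table (see
#'   [simulationConfig()]).
#' @param ... further arguments passed to [simulationConfig()].
#' @return A [SimulationConfig-class].
#' @export
homogeneousConfig <- function(seed = 1L, injectedEffects = NULL, ...) {
  reg <- buildDefaultRegistry()
  ids <- conditionIds(reg)
  cut4 <- 0.3
  simulationConfig(
    presenceBase = stats::setNames(rep(cut4 - stats::qnorm(0.565),
                                       length(ids)), ids),
    baseImportance = stats::setNames(numeric(length(ids)), ids),
    injectedEffects = injectedEffects,
    seed = seed,
    registry = reg,
    ...)
}

#' Default recode map for synthetic free-text aliases
#'
#' The map resolving the recodable free-text importance answers that
#' [generateDataset()] produces (`"alias: <condition_id>"`) back onto their
#' pre-listed conditions.
#'
#' @param registry a [ConditionRegistry-class].
#' @return data.frame with columns `free_text`, `condition_id`.
#' @export
defaultRecodeMap <- function(registry) {
  ids <- conditionIds(registry)
  data.frame(free_text = paste("alias:", ids), condition_id = ids,
             stringsAsFactors = FALSE)
}

#' Recovery experiment: can the pipeline recover injected bottlenecks?
#'
#' Repeatedly generates a cohort from `config` (with per-replicate seeds
#' derived from the configuration seed), runs the full pipeline (flagging,
#' characteristic stratification, bottleneck calls) and records, for every
#' (condition, characteristic level) pair, whether the condition was called a
#' bottleneck in that characteristic stratum.  Injected pairs yield the
#' detection sensitivity; all other pairs yield the false-call rate.
#'
#' @param config a [SimulationConfig-class] (its `injectedEffects` define the
#'   ground truth; an empty set gives a pure null experiment).
#' @param reps number of replicates (>= 1).
#' @param threshold stratum bottleneck rate cut (strict; default 0.10).
#' @return data.frame with one row per (condition, field, level) pair:
#'   `condition_id`, `field`, `level`, `injected`, `n_called`, `reps`,
#'   `rate`.
#' @export
recoveryExperiment <- function(config, reps, threshold = 0.10) {
  stopifnot(reps >= 1)
  ids <- conditionIds(config@registry)
  lv <- systemLevels()
  pairs <- do.call(rbind, lapply(names(lv), function(f) {
    expand.grid(condition_id = ids, field = f, level = lv[[f]],
                stringsAsFactors = FALSE)
  }))
  pairKey <- paste(pairs$condition_id, pairs$field, pairs$level, sep = "|")
  eff <- config@injectedEffects
  injectedKey <- if (nrow(eff)) paste(eff$condition_id, eff$field, eff$level,
                                      sep = "|") else character()
  calls <- integer(length(pairKey))
  names(calls) <- pairKey
  recode <- defaultRecodeMap(config@registry)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg@seed <- as.integer((config@seed + r) %% .Machine$integer.max)
    sv <- generateDataset(cfg)$survey
    sv <- buildFlagTable(sv, recodeMap = recode)
    strata <- buildStrata(sv, frequent = character())
    prof <- stratumProfiles(sv, strata, threshold = threshold)
    prof <- prof[prof$stratum_kind %in% c("method", "theme", "setting"), ]
    hit <- prof[prof$is_bottleneck, ]
    if (nrow(hit)) {
      key <- paste(hit$condition_id, hit$stratum_kind, hit$stratum_key, sep = "|")
      calls[key[key %in% pairKey]] <- calls[key[key %in% pairKey]] + 1L
    }
  }
  data.frame(pairs,
             injected = pairKey %in% injectedKey,
             n_called = unname(calls),
             reps = reps,
             rate = unname(calls) / reps,
             stringsAsFactors = FALSE)
}
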