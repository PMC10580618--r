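## Survey CSV schema: one row per implemented intervention.
##   intervention_id, project_id, implementer_id, method, theme, setting,
##   rating_<condition_id> x registry size, importance_1 .. importance_5
## Ratings are 1..5 or empty (missing); importance cells are condition ids,
## free text, or empty.

#' Write a survey to CSV
#'
#' Serializes a [BottleneckSurvey-class] in the flat survey schema (one row
#' per intervention; `rating_<condition_id>` columns; up to five
#' `importance_*` columns).  Missing ratings become empty cells.
#'
#' @param survey a [BottleneckSurvey-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSurveyCsv <- function(survey, path) {
  cd <- as.data.frame(colData(survey)[, c("intervention_id", "project_id",
                                          "implementer_id", "method",
                                          "theme", "setting")])
  r <- t(ratings(survey))
  rdf <- as.data.frame(r)
  names(rdf) <- paste0("rating_", colnames(r))
  rdf[] <- lapply(rdf, function(v) ifelse(is.na(v), "", as.character(v)))
  sel <- importanceSelections(survey)
  imp <- t(vapply(sel, function(s) c(s, rep("", 5L))[1:5], character(5)))
  colnames(imp) <- paste0("importance_", 1:5)
  out <- cbind(cd, rdf, as.data.frame(imp, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a survey from CSV
#'
#' Parses and validates the flat survey schema against a registry: the
#' `rating_*` columns must match the registry's condition ids exactly,
#' rating cells must be 1--5 or empty (missing), and method/theme/setting
#' tokens must belong to their closed enumerations.  Errors cite the
#' offending row and column.
#'
#' @param path survey CSV path.
#' @param registry a [ConditionRegistry-class].
#' @return A [BottleneckSurvey-class].
#' @export
readSurveyCsv <- function(path, registry) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  idCols <- c("intervention_id", "project_id", "implementer_id",
              "method", "theme", "setting")
  miss <- setdiff(idCols, names(df))
  if (length(miss))
    stop("survey file is missing column(s): ", paste(miss, collapse = ", "))
  ids <- conditionIds(registry)
  ratingCols <- paste0("rating_", ids)
  extra <- setdiff(grep("^rating_", names(df), value = TRUE), ratingCols)
  if (length(extra))
    stop("unknown condition column(s): ", paste(sQuote(extra), collapse = ", "))
  miss <- setdiff(ratingCols, names(df))
  if (length(miss))
    stop("survey file is missing rating column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(df)
  ratingsM <- matrix(NA_integer_, length(ids), n, dimnames = list(ids, NULL))
  for (k in seq_along(ids)) {
    cell <- trimws(df[[ratingCols[k]]])
    ok <- cell %in% c("", "1", "2", "3", "4", "5")
    if (any(!ok)) {
      i <- which(!ok)[1]
      stop(sprintf("malformed rating %s at row %d, column %s",
                   sQuote(cell[i]), i, ratingCols[k]))
    }
    ratingsM[k, ] <- ifelse(cell == "", NA_integer_, as.integer(cell))
  }
  impCols <- grep("^importance_", names(df), value = TRUE)
  importance <- lapply(seq_len(n), function(i) {
    v <- trimws(unlist(df[i, impCols], use.names = FALSE))
    v[nzchar(v)]
  })
  for (f in c("method", "theme", "setting")) {
    df[[f]] <- tryCatch(
      .matchEnum(df[[f]], systemLevels()[[f]], f),
      error = function(e) stop(conditionMessage(e), " (column ", f, ")",
                               call. = FALSE))
  }
  BottleneckSurvey(ratingsM, df[idCols], registry, importance)
}

#' Read a simulation configuration file
#'
#' Loads a flat YAML or JSON file of [simulationConfig()] arguments.
#' `injected_effects` may be given as a list of records with fields
#' `condition_id`, `field`, `level`, `presence_shift`, `importance_boost`.
#'
#' @param path configuration file (.yaml/.yml or .json).
#' @param seed optional seed overriding the file's value.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  nm <- list(n_projects = "nProjects", n_interventions = "nInterventions",
             n_implementers = "nImplementers", method_weights = "methodWeights",
             theme_weights = "themeWeights", setting_weights = "settingWeights",
             presence_base = "presenceBase", presence_sd = "presenceSd",
             cutpoints = "cutpoints", base_importance = "baseImportance",
             importance_temperature = "importanceTemperature",
             importance_coupling = "importanceCoupling",
             injected_effects = "injectedEffects", missing_rate = "missingRate",
             free_text_alias_rate = "freeTextAliasRate",
             free_text_drop_rate = "freeTextDropRate", seed = "seed")
  args <- list()
  for (k in names(raw)) {
    kk <- if (k %in% names(nm)) nm[[k]] else k
    args[[kk]] <- raw[[k]]
  }
  if (!is.null(args$injectedEffects) && !is.data.frame(args$injectedEffects))
    args$injectedEffects <- do.call(rbind, lapply(args$injectedEffects,
                                                  as.data.frame))
  if (!is.null(seed)) args$seed <- seed
  do.call(simulationConfig, args)
}

#' Write the full set of analysis artifacts
#'
#' Writes `flag_table.csv`, `stratum_profiles.csv`, `congruence_matrix.csv`,
#' `summary.json` and `run.log` to `outDir`, and returns a manifest with an
#' MD5 content hash per file.  All outputs are deterministic functions of the
#' inputs (the log carries settings and counts, no timestamps), so reruns on
#' identical inputs produce identical hashes.
#'
#' @param survey a flagged [BottleneckSurvey-class].
#' @param profiles long profile table from [stratumProfiles()].
#' @param matrix a [CongruenceMatrix-class].
#' @param summary the run summary list from [runPipeline()] (or any
#'   JSON-serializable list).
#' @param outDir output directory (created if needed).
#' @return data.frame manifest with columns `file`, `path`, `md5`.
#' @export
writeOutputs <- function(survey, profiles, matrix, summary, outDir) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  if (file.access(outDir, 2) != 0)
    stop("output directory is not writable: ", outDir)
  paths <- c(flag_table = file.path(outDir, "flag_table.csv"),
             stratum_profiles = file.path(outDir, "stratum_profiles.csv"),
             congruence_matrix = file.path(outDir, "congruence_matrix.csv"),
             summary = file.path(outDir, "summary.json"),
             log = file.path(outDir, "run.log"))
  utils::write.csv(flagTable(survey), paths["flag_table"], row.names = FALSE)
  utils::write.csv(profiles, paths["stratum_profiles"], row.names = FALSE)
  utils::write.csv(as.data.frame(matrix), paths["congruence_matrix"],
                   row.names = FALSE)
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  fl <- metadata(survey)$flagging
  logLines <- c(
    "BottleneckProfiler run log",
    sprintf("interventions: %d", ncol(survey)),
    sprintf("conditions: %d", nrow(survey)),
    sprintf("dropped free-text selections: %d of %d",
            fl$droppedFreeText, fl$totalSelections),
    sprintf("impute missing as suboptimal: %s",
            fl$imputeMissingAsSuboptimal),
    sprintf("strata profiled: %d",
            length(unique(paste(profiles$stratum_kind, profiles$stratum_key)))),
    sprintf("congruence: universal characteristic reading: %s",
            matrix@requireAll)
  )
  writeLines(logLines, paths["log"])
  data.frame(file = names(paths), path = unname(paths),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE, row.names = NULL)
}
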