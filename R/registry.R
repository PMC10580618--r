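## Exemplar statements shown on the questionnaire, one per category block.
.exemplarStatements <- c(
  implementer = "I have sufficient skills to implement the intervention",
  co_implementer = "Other professionals are capable enough to implement the intervention",
  intervention = "The intervention is easy to carry out",
  implementer_org = "The intervention fits my organization's policy",
  co_implementer_org = "Other organizations sufficiently support the intervention's health theme",
  broader_context = "There is enough administrative and political support for the intervention",
  implementation_strategy = "Good materials required for implementation are available"
)

#' Build the default condition registry
#'
#' Constructs the default registry of 47 conditions for implementation in the
#' fixed category structure: 5 on the prime implementer, 5 on the
#' co-implementer(s), 10 on the intervention, 10 on the prime implementer's
#' organization, 11 on the co-implementer's organization(s), 4 on the broader
#' context and 2 on the implementation strategy.  Identifiers are stable
#' tokens of the form `<category prefix>_<ordinal>` (e.g. `imp_01`,
#' `strategy_02`).  The first statement of each block is the published
#' exemplar; the remaining statements are placeholders, since the full
#' questionnaire texts do not affect any computation.  Supply a complete
#' registry file through [loadRegistry()] to use real statement texts.
#'
#' @return A [ConditionRegistry-class] with 47 conditions.
#' @examples
#' reg <- buildDefaultRegistry()
#' nConditions(reg)
#' categoryCounts(reg)
#' @export
buildDefaultRegistry <- function() {
  info <- .categoryInfo
  rows <- lapply(seq_len(nrow(info)), function(i) {
    n <- info$expected_count[i]
    ids <- sprintf("%s_%02d", info$prefix[i], seq_len(n))
    stmt <- c(.exemplarStatements[[info$id[i]]],
              sprintf("Condition %s (%s)", ids[-1], info$label[i]))
    data.frame(condition_id = ids, category = info$id[i], statement = stmt,
               prelisted = TRUE, stringsAsFactors = FALSE)
  })
  new("ConditionRegistry", conditions = do.call(rbind, rows))
}

#' Load a condition registry from CSV
#'
#' Reads a registry file with columns `condition_id`, `category` and
#' `statement` (UTF-8, header row).  Categories must be among the seven
#' defined tokens and identifiers must be unique.  Arbitrary per-category
#' counts are accepted (useful for toy registries), but a warning is issued
#' when they deviate from the default (5, 5, 10, 10, 11, 4, 2) structure.
#'
#' @param path path to the registry CSV.
#' @return A [ConditionRegistry-class].
#' @export
loadRegistry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("condition_id", "category", "statement")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry file is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$category %in% .categoryInfo$id)
  if (length(bad))
    stop(sprintf("unknown category %s in registry row %d",
                 sQuote(df$category[bad[1]]), bad[1]))
  dup <- unique(df$condition_id[duplicated(df$condition_id)])
  if (length(dup))
    stop("duplicate condition_id in registry: ", paste(sQuote(dup), collapse = ", "))
  df$prelisted <- if (is.null(df$prelisted)) TRUE else as.logical(df$prelisted)
  reg <- new("ConditionRegistry",
             conditions = df[c("condition_id", "category", "statement", "prelisted")])
  if (!identical(unname(categoryCounts(reg)), .categoryInfo$expected_count))
    warning("registry category counts deviate from the default (5,5,10,10,11,4,2) structure")
  reg
}

#' @describeIn ConditionRegistry-class condition identifiers, in registry order.
#' @export
setMethod("conditionIds", "ConditionRegistry", function(x) x@conditions$condition_id)

#' @describeIn ConditionRegistry-class number of conditions.
#' @export
setMethod("nConditions", "ConditionRegistry", function(x) nrow(x@conditions))

#' @describeIn ConditionRegistry-class per-category condition counts (all
#'   seven categories, zeros included).
#' @export
setMethod("categoryCounts", "ConditionRegistry", function(x) {
  tab <- table(factor(x@conditions$category, levels = .categoryInfo$id))
  stats::setNames(as.integer(tab), .categoryInfo$id)
})

setMethod("show", "ConditionRegistry", function(object) {
  cat("ConditionRegistry with", nConditions(object), "conditions\n")
  cc <- categoryCounts(object)
  for (i in seq_along(cc))
    cat(sprintf("  %-24s %d\n", names(cc)[i], cc[i]))
})

#' @describeIn ConditionRegistry-class conditions as a data.frame.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "ConditionRegistry",
          function(x, row.names = NULL, optional = FALSE, ...) x@conditions)

.normalizeText <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

.normalizeToken <- function(x) {
  gsub("[ /-]+", "_", .normalizeText(x))
}

#' Recode free-text importance answers onto pre-listed conditions
#'
#' Respondents could add a condition not included in the pre-listed 47; about
#' half of such additions can be recoded onto a pre-listed condition, while
#' the rest (generic complaints such as "a lack of time") are too unspecific
#' and are dropped.  Matching is exact after case-folding and whitespace
#' normalization; no fuzzy matching is attempted, so the recode map fully
#' determines the outcome.
#'
#' @param freeText character vector of free-text answers.
#' @param mapping data.frame with columns `free_text` and `condition_id`, or
#'   NULL for an empty map.
#' @param registry optional [ConditionRegistry-class]; when supplied, mapped
#'   identifiers are validated against it.
#' @return Character vector: the mapped `condition_id`, or `NA` (the dropped
#'   marker) for unmatched or empty answers.
#' @examples
#' map <- data.frame(free_text = "good materials available",
#'                   condition_id = "strategy_01")
#' recodeAddedCondition("Good  Materials available", map, buildDefaultRegistry())
#' recodeAddedCondition("a lack of time", map)
#' @export
recodeAddedCondition <- function(freeText, mapping = NULL, registry = NULL) {
  if (is.null(mapping))
    mapping <- data.frame(free_text = character(), condition_id = character())
  if (!all(c("free_text", "condition_id") %in% names(mapping)))
    stop("recode map must have columns free_text and condition_id")
  if (!is.null(registry)) {
    bad <- setdiff(mapping$condition_id, conditionIds(registry))
    if (length(bad))
      stop("recode map references condition_id absent from the registry: ",
           paste(sQuote(bad), collapse = ", "))
  }
  key <- .normalizeText(mapping$free_text)
  q <- .normalizeText(freeText)
  out <- mapping$condition_id[match(q, key)]
  out[!nzchar(q)] <- NA_character_
  as.character(out)
}

#' Parse and validate an intervention-system key
#'
#' Maps method, theme and setting tokens (case-insensitive; spaces, hyphens
#' and slashes are treated as underscores) onto the closed enumerations of
#' the system taxonomy.
#'
#' @param method,theme,setting character tokens.
#' @return A named character vector `c(method=, theme=, setting=)`.
#' @examples
#' parseSystem("Education", "Overweight", "School")
#' @export
parseSystem <- function(method, theme, setting) {
  c(method = .matchEnum(method, .methodLevels, "method"),
    theme = .matchEnum(theme, .themeLevels, "theme"),
    setting = .matchEnum(setting, .settingLevels, "setting"))
}

.matchEnum <- function(x, levels, field) {
  norm <- .normalizeToken(x)
  bad <- which(!norm %in% levels)
  if (length(bad))
    stop(sprintf("invalid %s token %s; expected one of: %s",
                 field, sQuote(x[bad[1]]), paste(levels, collapse = ", ")))
  norm
}

#' System key strings
#'
#' Collapses method, theme and setting into the canonical
#' `"method|theme|setting"` key used for tallies and stratum labels.
#'
#' @param method,theme,setting validated enum tokens (vectorized).
#' @return Character vector of keys.
#' @export
systemKeyString <- function(method, theme, setting) {
  paste(method, theme, setting, sep = "|")
}

.splitSystemKey <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(method = vapply(parts, `[`, "", 1L),
             theme = vapply(parts, `[`, "", 2L),
             setting = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
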