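# Fixtures built in code: toy registries and small random surveys.

toyRegistry <- function(p) {
  cats <- rep(conditionCategories()$id, length.out = p)
  df <- data.frame(condition_id = sprintf("c_%02d", seq_len(p)),
                   category = cats,
                   statement = sprintf("toy condition %d", seq_len(p)),
                   prelisted = TRUE, stringsAsFactors = FALSE)
  new("ConditionRegistry", conditions = df)
}

# A survey where every flag is fully controlled: `suboptCols` / `impCols` are
# lists (per condition) of column indices that get a sub-optimal rating (4) /
# an importance selection.  All other cells are optimal (5) and unselected.
controlledSurvey <- function(nConditionsToy, n, suboptCols = list(),
                             impCols = list(),
                             method = rep("education", n),
                             theme = rep("overweight", n),
                             setting = rep("school", n)) {
  reg <- toyRegistry(nConditionsToy)
  ids <- conditionIds(reg)
  ratings <- matrix(5L, nConditionsToy, n, dimnames = list(ids, NULL))
  for (cid in names(suboptCols)) ratings[cid, suboptCols[[cid]]] <- 4L
  importance <- replicate(n, character(0), simplify = FALSE)
  for (cid in names(impCols)) {
    for (j in impCols[[cid]]) importance[[j]] <- unique(c(importance[[j]], cid))
  }
  stopifnot(all(lengths(importance) <= 5))
  records <- data.frame(intervention_id = sprintf("iv_%03d", seq_len(n)),
                        project_id = "p1", implementer_id = "i1",
                        method = method, theme = theme, setting = setting,
                        stringsAsFactors = FALSE)
  BottleneckSurvey(ratings, records, reg, importance)
}

randomSmallInstance <- function(seed) {
  set.seed(seed)
  p <- sample(4:10, 1)
  n <- sample(12:30, 1)
  reg <- toyRegistry(p)
  ids <- conditionIds(reg)
  lv <- systemLevels()
  methods <- sample(lv$method, 2)
  themes <- sample(lv$theme, 2)
  settings <- sample(lv$setting, 2)
  records <- data.frame(
    intervention_id = sprintf("iv_%02d", seq_len(n)),
    project_id = sprintf("p%d", sample(1:3, n, replace = TRUE)),
    implementer_id = sprintf("i%d", sample(1:5, n, replace = TRUE)),
    method = sample(methods, n, replace = TRUE),
    theme = sample(themes, n, replace = TRUE),
    setting = sample(settings, n, replace = TRUE),
    stringsAsFactors = FALSE)
  ratings <- matrix(sample(c(1:5, NA), p * n, replace = TRUE,
                           prob = c(rep(0.12, 4), 0.42, 0.10)),
                    p, n, dimnames = list(ids, NULL))
  importance <- lapply(seq_len(n), function(j) sample(ids, sample(0:min(5, p), 1)))
  BottleneckSurvey(ratings, records, reg, importance)
}
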