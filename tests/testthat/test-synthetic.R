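test_that("dataset generation is fully deterministic given the configuration", {
  cfg <- simulationConfig(nInterventions = 60L, seed = 7)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(ratings(d1$survey), ratings(d2$survey))
  expect_identical(importanceSelections(d1$survey),
                   importanceSelections(d2$survey))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeSurveyCsv(d1$survey, f1)
  writeSurveyCsv(d2$survey, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("system assignments recover the marginal weights", {
  ds <- generateDataset(simulationConfig(seed = 3))
  frac <- mean(SummarizedExperiment::colData(ds$survey)$method == "education")
  expect_lt(abs(frac - 137 / 243), 0.05)

  # degenerate weights collapse the marginal
  cfg1 <- simulationConfig(methodWeights = c(1, 0, 0, 0, 0),
                           nInterventions = 50L, seed = 4)
  ds1 <- generateDataset(cfg1)
  expect_true(all(SummarizedExperiment::colData(ds1$survey)$method == "education"))

  # convergence at n = 10^4: every marginal within 3 s.e. of its weight
  big <- generateDataset(simulationConfig(nInterventions = 10000L, seed = 5,
                                          missingRate = 0))
  cd <- SummarizedExperiment::colData(big$survey)
  cfg <- simulationConfig()
  for (f in c("method", "theme", "setting")) {
    w <- slot(cfg, paste0(f, "Weights"))
    pr <- w / sum(w)
    for (lev in names(pr)) {
      se <- sqrt(pr[lev] * (1 - pr[lev]) / 10000)
      expect_lt(abs(mean(cd[[f]] == lev) - pr[lev]), 3 * se + 1e-9)
    }
  }
})

test_that("presence ratings follow the latent-threshold model", {
  reg <- buildDefaultRegistry()
  eff <- data.frame(condition_id = "int_01", field = "setting",
                    level = "school", presence_shift = -10,
                    importance_boost = 0)
  cfg <- simulationConfig(presenceSd = 0.1, injectedEffects = eff,
                          missingRate = 0, seed = 9)
  set.seed(1)
  r <- samplePresenceRatings(c(method = "education", theme = "overweight",
                               setting = "school"), cfg)
  expect_identical(unname(r["int_01"]), 1L)
  r2 <- samplePresenceRatings(c(method = "education", theme = "overweight",
                                setting = "home"), cfg)
  expect_gt(r2[["int_01"]], 1L)  # shift only applies to the school setting

  # cutpoints all below any achievable latent: every rating is 5
  lowCut <- simulationConfig(cutpoints = c(-50, -49, -48, -47),
                             presenceBase = setNames(numeric(47),
                                                     conditionIds(reg)),
                             presenceSd = 0.1, missingRate = 0, seed = 2)
  set.seed(2)
  r3 <- samplePresenceRatings(c(method = "education", theme = "overweight",
                                setting = "school"), lowCut)
  expect_true(all(r3 == 5L))

  # missingRate 0 leaves no missing cells (47 x 243 = 11421 draws)
  ds <- generateDataset(simulationConfig(missingRate = 0, seed = 6))
  expect_false(anyNA(ratings(ds$survey)))
})

test_that("importance sampling respects boosts, uniformity and set limits", {
  reg <- buildDefaultRegistry()
  eff <- data.frame(condition_id = "coorg_05", field = "method",
                    level = "education", presence_shift = 0,
                    importance_boost = 50)
  cfg <- simulationConfig(injectedEffects = eff, seed = 1)
  allFive <- setNames(rep(5L, 47), conditionIds(reg))
  sys <- c(method = "education", theme = "overweight", setting = "school")
  set.seed(3)
  for (i in 1:50)
    expect_true("coorg_05" %in% sampleImportance(allFive, sys, cfg))

  # uniform weights: selection is exchangeable over the 47 conditions.
  # The first pick of each set is an iid uniform draw -> chi-square goodness
  # of fit; the pooled top-5 frequencies stay near 5/47.
  flat <- simulationConfig(importanceCoupling = 0,
                           baseImportance = setNames(numeric(47),
                                                     conditionIds(reg)),
                           seed = 1)
  set.seed(4)
  sets <- replicate(10000, sampleImportance(allFive, sys, flat),
                    simplify = FALSE)
  first <- table(factor(vapply(sets, `[`, "", 1L),
                        levels = conditionIds(reg)))
  expect_gt(chisq.test(first)$p.value, 1e-3)
  hits <- table(factor(unlist(sets), levels = conditionIds(reg)))
  expect_true(all(abs(hits / 10000 - 5 / 47) < 0.015))

  # every generated record carries at most five selections
  ds <- generateDataset(simulationConfig(nInterventions = 243L, seed = 8))
  expect_true(all(lengths(importanceSelections(ds$survey)) <= 5))
  expect_identical(ncol(ds$survey), 243L)
})

test_that("an empty cohort is a valid degenerate dataset", {
  ds <- generateDataset(simulationConfig(nInterventions = 0L, seed = 1))
  expect_identical(ncol(ds$survey), 0L)
  expect_identical(nrow(ds$survey), 47L)
  expect_identical(nrow(ds$truth$pairs), 0L)
})

test_that("lowering a condition's presence base weakly raises its sub-optimal share", {
  reg <- buildDefaultRegistry()
  base <- setNames(rep(0.2, 47), conditionIds(reg))
  lo <- base; lo["org_05"] <- -1.5
  pctSub <- function(b, s) {
    cfg <- simulationConfig(presenceBase = b, seed = s, missingRate = 0)
    sv <- buildFlagTable(generateDataset(cfg)$survey,
                         defaultRecodeMap(reg))
    conditionProfile(sv)$pct_suboptimal[match("org_05", conditionIds(reg))]
  }
  for (s in 1:3) expect_gte(pctSub(lo, s), pctSub(base, s))
})

test_that("ground truth records exactly the injected pairs with nonzero shifts", {
  eff <- data.frame(condition_id = c("imp_01", "int_02"),
                    field = c("method", "theme"),
                    level = c("education", "alcohol"),
                    presence_shift = c(-2, 0), importance_boost = c(3, 1))
  ds <- generateDataset(simulationConfig(nInterventions = 20L, seed = 2,
                                         injectedEffects = eff))
  expect_identical(ds$truth$pairs$condition_id, "imp_01")
  expect_error(simulationConfig(injectedEffects = data.frame(
    condition_id = "ghost", field = "method", level = "education",
    presence_shift = -1, importance_boost = 0)), "registry|validity|invalid")
})

test_that("a single-replicate recovery table is reproducible", {
  eff <- data.frame(condition_id = "imp_02", field = "method",
                    level = "education", presence_shift = -2,
                    importance_boost = 3)
  cfg <- homogeneousConfig(seed = 5, injectedEffects = eff,
                           nInterventions = 80L)
  t1 <- recoveryExperiment(cfg, reps = 1)
  t2 <- recoveryExperiment(cfg, reps = 1)
  expect_identical(t1, t2)
  expect_identical(sum(t1$injected), 1L)
})
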