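test_that("the survey CSV round-trips records, missing cells and free text", {
  ds <- generateDataset(simulationConfig(nInterventions = 30L, seed = 13))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSurveyCsv(ds$survey, f)
  back <- readSurveyCsv(f, registry(ds$survey))
  expect_identical(ratings(back), ratings(ds$survey))
  expect_identical(importanceSelections(back),
                   importanceSelections(ds$survey))
  expect_identical(as.data.frame(SummarizedExperiment::colData(back)[1:6]),
                   as.data.frame(SummarizedExperiment::colData(ds$survey)[1:6]))

  # header-only file: an empty, valid record list
  empty <- generateDataset(simulationConfig(nInterventions = 0L, seed = 1))$survey
  writeSurveyCsv(empty, f)
  expect_identical(ncol(readSurveyCsv(f, registry(empty))), 0L)
})

test_that("survey validation names the offending row and column", {
  ds <- generateDataset(simulationConfig(nInterventions = 5L, seed = 3,
                                         missingRate = 0))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSurveyCsv(ds$survey, f)
  lines <- readLines(f)
  lines[4] <- sub("^(\"[^\"]*\",\"[^\"]*\",\"[^\"]*\",\"[^\"]*\",\"[^\"]*\",\"[^\"]*\",)\"[1-5]\"",
                  "\\1\"6\"", lines[4])
  writeLines(lines, f)
  expect_error(readSurveyCsv(f, registry(ds$survey)), "row 3.*rating_")

  writeSurveyCsv(ds$survey, f)
  lines <- readLines(f)
  lines[1] <- sub("rating_imp_01", "rating_ghost_01", lines[1])
  writeLines(lines, f)
  expect_error(readSurveyCsv(f, registry(ds$survey)), "ghost_01")
})

test_that("artifact writing is deterministic and complete", {
  ds <- generateDataset(simulationConfig(nInterventions = 60L, seed = 21))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rs1 <- runPipeline(ds$survey, recodeMap = defaultRecodeMap(registry(ds$survey)),
                     outDir = d1)
  rs2 <- runPipeline(ds$survey, recodeMap = defaultRecodeMap(registry(ds$survey)),
                     outDir = d2)
  expect_identical(nrow(rs1$manifest), 5L)
  expect_true(all(file.exists(rs1$manifest$path)))
  expect_identical(rs1$manifest$md5, rs2$manifest$md5)

  # summary.json round-trips through the JSON reader
  js <- jsonlite::fromJSON(file.path(d1, "summary.json"))
  expect_equal(js$n_interventions, 60)
  expect_equal(js$overall$total_bottlenecks,
               rs1$congruenceSummary$overall$total_bottlenecks)
  expect_equal(js$correlation$r, rs1$correlation$r, tolerance = 1e-12)
})

test_that("pipeline degenerate cases: all-optimal and saturated surveys", {
  # every rating 5: no sub-optimal flags, hence no bottlenecks anywhere
  svOpt <- controlledSurvey(4, 30)
  rsOpt <- runPipeline(svOpt, minCount = 5L)
  expect_identical(rsOpt$congruenceSummary$overall$total_bottlenecks, 0L)
  expect_false(any(rsOpt$profiles$is_bottleneck))

  # one condition sub-optimal and important everywhere: bottleneck in every
  # stratum and EPB in every frequent system
  n <- 26
  svSat <- controlledSurvey(4, n,
                            suboptCols = list(c_02 = 1:n),
                            impCols = list(c_02 = 1:n),
                            method = rep(c("education", "regulation"), each = 13),
                            theme = rep("alcohol", n),
                            setting = rep("home", n))
  rsSat <- runPipeline(svSat, minCount = 10L)
  pc2 <- rsSat$profiles[rsSat$profiles$condition_id == "c_02", ]
  expect_true(all(pc2$is_bottleneck))
  lab <- congruenceLabels(rsSat$congruence)
  expect_identical(ncol(lab), 2L)
  expect_true(all(lab["c_02", ] == "EPB"))
})

test_that("pipeline summary agrees with a brute-force frequent-system filter", {
  ds <- generateDataset(simulationConfig(seed = 7))
  rs <- runPipeline(ds$survey, recodeMap = defaultRecodeMap(registry(ds$survey)))
  tal <- countSystems(ds$survey)
  expect_identical(rs$coverage$n_frequent_systems,
                   sum(vapply(tal, function(v) v > 10, NA)))
  # internal consistency: per-system EPB + UPB adds to the bottleneck total
  ps <- rs$congruenceSummary$perSystem
  expect_identical(ps$n_EPB + ps$n_UPB, ps$n_bottlenecks)
  expect_identical(sum(ps$n_bottlenecks),
                   rs$congruenceSummary$overall$total_bottlenecks)
})

test_that("simulation configs load from YAML and JSON with seed override", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_interventions: 25", "seed: 5", "missing_rate: 0",
               "importance_coupling: -2"), fy)
  cfg <- readSimulationConfig(fy)
  expect_identical(cfg@nInterventions, 25L)
  expect_identical(cfg@seed, 5L)
  expect_equal(cfg@importanceCoupling, -2)
  cfg2 <- readSimulationConfig(fy, seed = 99)
  expect_identical(cfg2@seed, 99L)

  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_interventions = 12, seed = 3,
                            injected_effects = list(list(
                              condition_id = "imp_01", field = "method",
                              level = "education", presence_shift = -2,
                              importance_boost = 3))),
                       fj, auto_unbox = TRUE)
  cfg3 <- readSimulationConfig(fj)
  expect_identical(cfg3@nInterventions, 12L)
  expect_identical(cfg3@injectedEffects$condition_id, "imp_01")
  d <- generateDataset(cfg3)
  expect_identical(ncol(d$survey), 12L)
})

test_that("stage names are attached to propagated pipeline errors", {
  expect_error(runPipeline("/nonexistent/survey.csv"), "\\[read_survey\\]")
})
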