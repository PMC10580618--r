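test_that("presence dichotomization: only strong agreement is optimal", {
  d <- dichotomizePresence(c(5, 4, 3, 2, 1, NA))
  expect_identical(d$suboptimal, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(d$rated, c(rep(TRUE, 5), FALSE))
  expect_error(dichotomizePresence(6), "invalid rating")
  expect_error(dichotomizePresence(2.5), "invalid rating")
  # total on {1..5, NA}; re-application to the boolean domain is stable
  for (r in c(1:5, NA)) {
    d1 <- dichotomizePresence(r)
    expect_type(d1$suboptimal, "logical")
  }
})

test_that("importance resolution recodes, drops, and collapses duplicates", {
  reg <- buildDefaultRegistry()
  out <- resolveImportance(c("imp_01", "int_03", "a lack of time"), reg)
  expect_setequal(as.vector(out), c("imp_01", "int_03"))
  expect_identical(attr(out, "dropped"), 1L)

  expect_length(resolveImportance(character(0), reg), 0L)
  expect_identical(as.vector(resolveImportance(c("imp_01", "imp_01"), reg)),
                   "imp_01")
  map <- data.frame(free_text = "alias: strategy_02",
                    condition_id = "strategy_02")
  out2 <- resolveImportance(c("imp_01", "alias: strategy_02"), reg, map)
  expect_setequal(as.vector(out2), c("imp_01", "strategy_02"))
  expect_identical(attr(out2, "dropped"), 0L)
})

test_that("bottleneck is the conjunction of sub-optimal and important", {
  # condition c_01: suboptimal+important; c_02: suboptimal only;
  # c_03: important only; c_04: neither
  sv <- controlledSurvey(4, 2,
                         suboptCols = list(c_01 = 1:2, c_02 = 1:2),
                         impCols = list(c_01 = 1:2, c_03 = 1:2))
  sv <- buildFlagTable(sv)
  b <- flags(sv, "bottleneck")
  expect_true(all(b["c_01", ]))
  expect_false(any(b[c("c_02", "c_03", "c_04"), ]))
  expect_true(all(flags(sv, "suboptimal")["c_02", ]))
  expect_true(all(flags(sv, "important")["c_03", ]))
  # exhaustive conjunction check over every cell
  expect_identical(b, flags(sv, "suboptimal") & flags(sv, "important"))
})

test_that("missing ratings never produce sub-optimal flags unless imputed", {
  reg <- toyRegistry(2)
  ratings <- matrix(c(NA, 5L, NA, 4L), 2, 2,
                    dimnames = list(conditionIds(reg), NULL))
  records <- data.frame(intervention_id = c("a", "b"), project_id = "p",
                        implementer_id = "i", method = "education",
                        theme = "alcohol", setting = "school")
  sv <- BottleneckSurvey(ratings, records, reg, list("c_01", "c_01"))
  f <- buildFlagTable(sv)
  expect_false(any(flags(f, "suboptimal")["c_01", ]))
  expect_false(any(flags(f, "bottleneck")["c_01", ]))
  expect_identical(unname(flags(f, "rated")["c_01", ]), c(FALSE, FALSE))
  fi <- buildFlagTable(sv, imputeMissingAsSuboptimal = TRUE)
  expect_true(all(flags(fi, "suboptimal")["c_01", ]))
  expect_true(all(flags(fi, "bottleneck")["c_01", ]))
})

test_that("condition profiles use the all-systems denominator", {
  sv <- controlledSurvey(3, 20,
                         suboptCols = list(c_01 = 1:2),
                         impCols = list(c_01 = 1:2))
  sv <- buildFlagTable(sv)
  prof <- conditionProfile(sv)
  expect_equal(prof$pct_bottleneck[prof$condition_id == "c_01"], 10.0)
  expect_equal(prof$pct_suboptimal[prof$condition_id == "c_02"], 0)
  expect_error(conditionProfile(sv, nSystems = 0), "nSystems")

  # all flags false: percentages and aggregates collapse to zero
  sv0 <- buildFlagTable(controlledSurvey(3, 10))
  ag <- profileAggregates(conditionProfile(sv0))
  expect_true(all(ag$mean == 0 & ag$min == 0 & ag$max == 0))
})

test_that("profiles are permutation-invariant and monotone in added flags", {
  sv <- buildFlagTable(randomSmallInstance(42))
  prof <- conditionProfile(sv)
  svPerm <- buildFlagTable(randomSmallInstance(42)[, sample(ncol(sv))])
  profPerm <- conditionProfile(svPerm)
  expect_equal(prof[order(prof$condition_id), ],
               profPerm[order(profPerm$condition_id), ],
               ignore_attr = TRUE)
  # bottleneck never exceeds its components
  expect_true(all(prof$pct_bottleneck <= pmin(prof$pct_suboptimal,
                                              prof$pct_important) + 1e-12))

  # adding one record with a true bottleneck flag raises count while the
  # denominator grows by one: percentage of flagged conditions never drops
  # when computed over a fixed denominator
  a <- buildFlagTable(controlledSurvey(2, 10, suboptCols = list(c_01 = 1:3),
                                       impCols = list(c_01 = 1:3)))
  b <- buildFlagTable(controlledSurvey(2, 11, suboptCols = list(c_01 = 1:4),
                                       impCols = list(c_01 = 1:4)))
  n <- 11
  expect_gte(conditionProfile(b, n)$pct_bottleneck[1],
             conditionProfile(a, n)$pct_bottleneck[1])
})

test_that("suboptimality-importance correlation matches closed forms", {
  prof <- data.frame(pct_suboptimal = c(10, 20, 30),
                     pct_important = c(30, 20, 10))
  expect_equal(suboptimalImportanceCorrelation(prof)$r, -1)
  prof$pct_important <- prof$pct_suboptimal
  expect_equal(suboptimalImportanceCorrelation(prof)$r, 1)
  prof$pct_suboptimal <- c(0, 0, 0)
  expect_error(suboptimalImportanceCorrelation(prof), "undefined correlation")
})
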