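test_that("the generator is deterministic and its spec validates", {
  g1 <- smallGen()
  g2 <- generateReferenceDb(smallSpec())
  expect_identical(g1$db@interactions, g2$db@interactions)
  expect_identical(vapply(g1$db@compounds, smiles, character(1)),
                   vapply(g2$db@compounds, smiles, character(1)))
  expect_identical(g1$truth@withheld, g2$truth@withheld)
  expect_error(syntheticSpec(nTargets = 2, nFamilies = 4))
  expect_error(generateReferenceDb(syntheticSpec(nTargets = 60L)),
               "exhausted")
})

test_that("planted cross-activity fractions are recovered by exact recount", {
  g <- generateReferenceDb(syntheticSpec())
  sp <- syntheticSpec()
  n <- sp$activesPerChemotype
  for (r in seq_len(nrow(sp$plantedCrossActivities))) {
    ct <- sp$plantedCrossActivities$chemotype[r]
    ot <- sp$plantedCrossActivities$off_target[r]
    nDb <- sum(grepl(paste0("^", ct, "_"), g$db@actives[[ot]]))
    nWh <- sum(g$truth@interactions$target_id == ot &
               grepl(paste0("^", ct, "_"), g$truth@interactions$mol_id))
    expect_identical(nDb + nWh, as.integer(round(0.3 * n)))
  }
})

test_that("a spec without cross-activities yields only primary ground truth", {
  g <- generateReferenceDb(syntheticSpec(nTargets = 2L, nFamilies = 1L,
                                         activesPerChemotype = 10L,
                                         crossFraction = 0,
                                         decoyCount = 5L))
  expect_identical(unique(g$truth@interactions$kind), "primary")
  # 20% withholding of a 10-member chemotype -> 2 queries each
  expect_identical(nrow(g$truth@withheld), 4L)
})

test_that("query sets have no leakage and bookkeep expected pairs", {
  g <- smallGen()
  q <- generateQuerySet(g$truth, g$db)
  qCanon <- vapply(q$queries, smiles, character(1))
  dbCanon <- vapply(g$db@compounds, smiles, character(1))
  expect_length(intersect(qCanon, dbCanon), 0L)
  expect_true(all(q$expected$mol_id %in% g$truth@withheld$mol_id))
  # a doctored truth that reuses a database molecule is caught
  bad <- g$truth
  bad@withheld$smiles[1] <- smiles(g$db@compounds[[1]])
  expect_error(generateQuerySet(bad, g$db), "leakage")
})

test_that("recovery metrics match their definitions on degenerate inputs", {
  expected <- data.frame(mol_id = c("a", "b"), target_id = c("T1", "T2"),
                         kind = c("primary", "planted_off_target"),
                         stringsAsFactors = FALSE)
  empty <- data.frame(mol_id = character(), target_id = character(),
                      SAS = numeric(), SAR = numeric(), SIM = numeric(),
                      SEA = numeric(), MLM = numeric(), XPI = numeric(),
                      consensus_pass = logical(), stringsAsFactors = FALSE)
  m0 <- evaluateRecovery(empty, expected)
  expect_equal(m0$recall_primary, 0)
  expect_equal(m0$capture_rate, 0)

  exact <- data.frame(mol_id = c("a", "b"), target_id = c("T1", "T2"),
                      SAS = 1, SAR = 1, SIM = 1, SEA = 1, MLM = 1, XPI = 1,
                      consensus_pass = TRUE, stringsAsFactors = FALSE)
  m1 <- evaluateRecovery(exact, expected)
  expect_equal(m1$recall_primary, 1)
  expect_equal(m1$capture_planted, 1)
  expect_equal(m1$precision, 1)
  expect_equal(m1$all_six_fraction, 1)
})

test_that("default-run per-method behavior is separable as designed", {
  run <- defaultRun()
  mr <- run$metrics$method_recall
  # near-duplicate actives make the similarity methods strong on expected pairs
  expect_gte(mr[["SIM"]], 0.9)
  # classifier methods generalize but imperfectly; they stay informative
  expect_gte(mr[["SAR"]], 0.5)
  expect_gte(mr[["MLM"]], 0.5)
})
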