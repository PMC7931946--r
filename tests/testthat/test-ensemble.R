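test_that("pseudo-score aggregation matches the stated examples", {
  expect_identical(aggregatePseudoScore(c(SIM = 0.1), inTraining = TRUE), 1.0)
  six <- stats::setNames(rep(0.9, 6), c("SAS","SAR","SIM","SEA","MLM","XPI"))
  expect_equal(aggregatePseudoScore(six), 0.9)
  expect_equal(aggregatePseudoScore(c(SIM = 0.6, SEA = 0.8)), 0.7)
  # absent-as-zero alternative divides by the full weight mass
  expect_equal(aggregatePseudoScore(c(SIM = 0.6), absentAsZero = TRUE), 0.1)
})

test_that("consensus filter matches the stated examples", {
  expect_true(consensusFilter(c(SAS = 0.7, SAR = 0.65, SIM = 0.61, SEA = 0.2)))
  expect_false(consensusFilter(c(SAS = 0.7, SAR = 0.65, SIM = 0.59,
                                 SEA = 0.59, MLM = 0.1, XPI = 0.0)))
  expect_true(consensusFilter(c(SIM = 0.1), inTraining = TRUE))
  # comparator switch: exactly at tau with ">" no longer counts
  at <- c(SAS = 0.6, SAR = 0.6, SIM = 0.6)
  expect_true(consensusFilter(at, comparator = ">="))
  expect_false(consensusFilter(at, comparator = ">"))
})

test_that("metabolite merging canonicalizes, deduplicates and tags roles", {
  parent <- parseMolecule("CCOc1ccccc1", "drug")
  out <- mergeMetaboliteList(parent, c("Oc1ccccc1", "c1ccccc1O", "CCOc1ccccc1"))
  expect_identical(length(out$queries), 2L)  # phenol once; parent dupe dropped
  expect_identical(out$roles$role, c("parent", "metabolite"))
  expect_identical(unique(out$roles$parent_id), "drug")
  expect_warning(mergeMetaboliteList(parent, c("((bad", ")))worse")),
                 "unparseable")
})

test_that("provenance classification distinguishes training, confirmed and new", {
  run <- defaultRun()
  pred <- run$pred
  expect_true(all(pred$provenance %in% c("training_set", "confirmed", "new")))
  # training rows score exactly 1 and always pass
  tr <- pred[pred$provenance == "training_set", ]
  if (nrow(tr)) {
    expect_true(all(tr$pseudo_score == 1))
    expect_true(all(tr$consensus_pass))
  }
  # with the expected pairs supplied as truth, those pairs become confirmed
  truth <- new("TruthTable",
               pairs = data.frame(mol_id = run$q$expected$mol_id,
                                  target_id = run$q$expected$target_id,
                                  source = "planted",
                                  stringsAsFactors = FALSE))
  pred2 <- predictTargets(run$model, run$q$queries[1], truth = truth)
  exp1 <- run$q$expected[run$q$expected$mol_id == molId(run$q$queries[[1]]), ]
  hit <- pred2[paste(pred2$mol_id, pred2$target_id) %in%
               paste(exp1$mol_id, exp1$target_id), ]
  expect_true(all(hit$provenance == "confirmed"))
})

test_that("a training-set query gets pseudo-score 1 on its annotated target", {
  run <- defaultRun()
  db <- run$g$db
  aid <- db@actives[["T01"]][1]
  q <- parseMolecule(smiles(db@compounds[[aid]]), "resubmitted")
  pred <- predictTargets(run$model, list(q))
  row <- pred[pred$target_id == "T01", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$provenance, "training_set")
  expect_identical(row$pseudo_score, 1.0)
  expect_true(row$consensus_pass)
})

test_that("expression filtering keeps unknown targets and validates the tissue", {
  pred <- data.frame(mol_id = "m", target_id = c("T1", "T2", "T9"),
                     consensus_pass = TRUE, stringsAsFactors = FALSE)
  vals <- matrix(c(5, 0.2), nrow = 2,
                 dimnames = list(c("T1", "T2"), "liver"))
  expr <- new("ExpressionMatrix", values = vals, species = "human")
  out <- filterByExpression(pred, expr, "liver", minExpr = 1)
  expect_setequal(out$target_id, c("T1", "T9"))
  expect_identical(out$expression_status[out$target_id == "T9"], "unknown")
  # min_expr = 0 is the identity filter
  expect_identical(nrow(filterByExpression(pred, expr, "liver", 0)), 3L)
  expect_error(filterByExpression(pred, expr, "kidney"), "liver")
})

test_that("report ranking, conservation and coverage arithmetic are recount-exact", {
  run <- defaultRun()
  report <- generateReport(run$pred)
  p <- predictions(report)
  # ranked within compound: descending S, ties by n_methods_above, target id
  for (m in unique(p$mol_id)) {
    sub <- p[p$mol_id == m, ]
    key <- order(-sub$pseudo_score, -sub$n_methods_above, sub$target_id)
    expect_identical(key, seq_len(nrow(sub)))
  }
  s <- cohortSummary(report)
  expect_identical(s$total_interactions,
                   s$confirmed + s$new + s$training_set)
  # brute-force recount of one method's coverage
  nonTrain <- p[p$provenance != "training_set", ]
  expect_equal(s$method_coverage[["SIM"]],
               mean(!is.na(nonTrain$SIM) & nonTrain$SIM >= 0.6))
  expect_equal(s$mean_interactions_per_compound,
               nrow(p) / length(unique(run$pred$mol_id)))
  # empty prediction set: zero counts, no failure
  emptyRep <- generateReport(run$pred[0, ])
  expect_identical(cohortSummary(emptyRep)$total_interactions, 0L)
})

test_that("written reports round-trip and alert tables join", {
  run <- defaultRun()
  alerts <- data.frame(target_id = "T01", alert = "arrhythmia",
                       stringsAsFactors = FALSE)
  report <- generateReport(run$pred, alertTable = alerts)
  dir <- tempfile()
  writeReport(report, dir)
  expect_true(file.exists(file.path(dir, "predictions.tsv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- utils::read.delim(file.path(dir, "predictions.tsv"))
  expect_identical(nrow(back), nrow(predictions(report)))
  expect_true("alert" %in% names(back))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_identical(js$total_interactions,
                   cohortSummary(report)$total_interactions)
})
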