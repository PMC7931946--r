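test_that("raw set score matches a brute-force double loop", {
  g <- smallGen()
  cfg <- otsaConfig()
  ids <- names(g$db@compounds)[1:12]
  desc <- otsa:::.descriptorSet(g$db@compounds[ids], cfg)
  M <- otsa:::.fpMatrix(desc, cfg$fpBits)
  rowsA <- 1:4; rowsB <- 5:12
  fast <- otsa:::.rawSetScore(M, rowsA, rowsB, 0.57)
  slow <- 0
  for (i in rowsA) for (j in rowsB) {
    tc <- tanimoto(desc[[ids[i]]]$fp, desc[[ids[j]]]$fp)
    if (tc >= 0.57) slow <- slow + tc
  }
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("label-path containment agrees with hand-worked cases", {
  mol <- parseMolecule("NCCc1ccccc1", "pea")   # phenethylamine
  red <- list(labels = otsa:::.atomLabelStrings(assignFeatures(mol), "six"),
              nb = otsa:::.neighborList(mol@graph))
  # labels are sorted feature-letter strings: amine N = "ADP", ring C = "HR"
  expect_true(otsa:::.containsLabelPath(red, "HR"))
  expect_true(otsa:::.containsLabelPath(red, c("ADP", "0", "H", "HR")))
  expect_false(otsa:::.containsLabelPath(red, "N"))      # no acidic feature
  expect_false(otsa:::.containsLabelPath(red, c("HR", "ADP")))  # not adjacent
  # reading direction must not matter
  expect_true(otsa:::.containsLabelPath(red, c("HR", "H", "0", "ADP")))
})

test_that("fitted methods are deterministic and carry the database fingerprint", {
  g <- smallGen()
  m1 <- suppressMessages(fitMethod("SAR", g$db, seed = 11L))
  m2 <- suppressMessages(fitMethod("SAR", g$db, seed = 11L))
  expect_identical(m1@dbFingerprint, m2@dbFingerprint)
  q <- parseMolecule(g$truth@withheld$smiles[1], "q")
  s1 <- scoreMethod(m1, q, g$db)
  s2 <- scoreMethod(m2, q, g$db)
  expect_identical(s1, s2)
})

test_that("SIM scores a training molecule on its own target at 1", {
  model <- smallModel()
  g <- smallGen()
  aid <- g$db@actives[["T01"]][1]
  q <- parseMolecule(smiles(g$db@compounds[[aid]]), "copy")
  s <- scoreMethod(model@methods$SIM, q, g$db, model@config,
                   descriptors = model@descriptors)
  expect_equal(s$score[s$target_id == "T01"], 1, tolerance = 1e-12)
})

test_that("XPI matrix matches its definition on a hand-built database", {
  path <- writeActivityTSV(list(
    c("a", "CCO", "T1", "active"),
    c("b", "CCN", "T1", "active"),
    c("b", "CCN", "T2", "active"),
    c("c", "CCC", "T2", "active"),
    c("d", "CCCC", "T2", "active")))
  db <- suppressMessages(loadReferenceDatabase(path, quiet = TRUE))
  X <- otsa:::.xpiMatrix(db)
  expect_equal(X["T1", "T2"], 1 / 2)  # |{b}| / min(2, 3)
  expect_equal(X["T2", "T1"], 1 / 2)
  expect_equal(diag(X), c(T1 = 1, T2 = 1))
})

test_that("SEA calibration produces a usable background and refuses degenerate input", {
  model <- smallModel()
  bg <- model@methods$SEA@state$background
  expect_true(bg$a > 0 && bg$c > 0)
  expect_true(is.finite(bg$b) && is.finite(bg$e))
  # sigma grows with set-size product; z decreases in set size for fixed raw
  z1 <- seaStatistics(5, 1, 5, bg, 8)$z
  z2 <- seaStatistics(5, 1, 50, bg, 8)$z
  expect_gt(z1, z2)
  # too few compounds for calibration is fatal
  path <- writeActivityTSV(list(c("a", "CCO", "T1", "active")))
  tiny <- suppressMessages(loadReferenceDatabase(path, quiet = TRUE))
  expect_error(seaCalibrate(tiny), ">= 20 compounds")
})

test_that("method scores are bounded, floored and ordered deterministically", {
  model <- smallModel()
  g <- smallGen()
  q <- parseMolecule(g$truth@withheld$smiles[1],
                     g$truth@withheld$mol_id[1])
  long <- scoreAll(model, list(q))
  expect_true(all(long$score >= model@config$reportFloor))
  expect_true(all(long$score <= 1))
  expect_false(is.unsorted(paste(long$mol_id, long$target_id, long$method)))
  # repeated scoring is identical
  expect_identical(long, scoreAll(model, list(q)))
})
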