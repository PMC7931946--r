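test_that("parseMolecule canonicalizes, strips stereo and keeps the largest fragment", {
  m <- parseMolecule("CCO", "ethanol")
  expect_identical(molId(m), "ethanol")
  expect_identical(atomCount(m), 3L)
  # enantiomers collapse to one canonical form
  expect_identical(canonicalize("C[C@H](N)O"), canonicalize("C[C@@H](N)O"))
  # salt: the counter-ion is dropped
  expect_identical(canonicalize("CCN.Cl"), canonicalize("CCN"))
  expect_error(parseMolecule("not-a-smiles(", "bad"))
})

test_that("readMoleculeTable handles smiles-list, tsv and sdf with a parse report", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "CCC prop", "((bogus bad"), smi)
  ms <- readMoleculeTable(smi, format = "smiles-list")
  expect_identical(length(ms), 2L)
  rep <- parseReport(ms)
  expect_identical(sum(rep$status == "skipped"), 1L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("mol_id\tsmiles", "a\tCCO", "b\tc1ccccc1"), tsv)
  ms2 <- readMoleculeTable(tsv, format = "tsv")
  expect_identical(length(ms2), 2L)
  expect_identical(molId(ms2[[2]]), "b")

  # SDF round-trip: text generated by the external toolkit, read back
  sdfText <- ChemmineOB::convertFormat("SMI", "SDF", "CCO ethmol\n")
  sdf <- tempfile(fileext = ".sdf")
  writeLines(sdfText, sdf)
  ms3 <- readMoleculeTable(sdf, format = "sdf")
  expect_identical(length(ms3), 1L)
  expect_identical(smiles(ms3[[1]]), canonicalize("CCO"))
})

test_that("loadReferenceDatabase deduplicates by canonical SMILES and validates labels", {
  path <- writeActivityTSV(list(
    c("m1", "CCO", "T1", "active"),
    c("m2", "OCC", "T1", "active"),      # same molecule, different spelling
    c("m3", "CCC", "T1", "inactive"),
    c("m4", "CCN", "T2", "active")))
  db <- suppressMessages(loadReferenceDatabase(path, quiet = TRUE))
  expect_identical(length(db@compounds), 3L)          # m2 aliased to m1
  expect_identical(unname(db@aliases["m2"]), "m1")
  expect_identical(activeLigands(db, "T1"), "m1")
  expect_identical(targetIds(db), c("T1", "T2"))

  conflict <- writeActivityTSV(list(
    c("m1", "CCO", "T1", "active"),
    c("m1", "CCO", "T1", "inactive")))
  expect_error(suppressMessages(loadReferenceDatabase(conflict, quiet = TRUE)),
               "conflicting")

  zeroActive <- writeActivityTSV(list(
    c("m1", "CCO", "T1", "active"),
    c("m2", "CCC", "T2", "inactive")))
  expect_warning(db2 <- loadReferenceDatabase(zeroActive, quiet = TRUE),
                 "zero actives")
  expect_identical(targetIds(db2), "T1")
})

test_that("truth table and expression matrix loaders validate their inputs", {
  tt <- tempfile(fileext = ".tsv")
  writeLines(c("mol_id\ttarget_id", "m1\tT1", "m1\tT1", "m2\tT2"), tt)
  truth <- loadTruthTable(tt)
  expect_identical(nrow(truth@pairs), 2L)

  ex <- tempfile(fileext = ".tsv")
  writeLines(c("target_id\tliver\tbrain", "T1\t5\t0", "T2\t0.5\t2"), ex)
  expr <- loadExpressionMatrix(ex)
  expect_identical(expressionValue(expr, "T1", "liver"), 5)
  expect_true(is.na(expressionValue(expr, "T9", "liver")))
  expect_error(expressionValue(expr, "T1", "kidney"), "liver, brain")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("target_id\tliver", "T1\t-1"), neg)
  expect_error(loadExpressionMatrix(neg), "negative")
})
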