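test_that("feature assignment follows the pattern table", {
  et <- parseMolecule("CCO", "ethanol")
  f <- assignFeatures(et)
  # atom order follows the canonical SMILES CCO: C, C, O
  expect_true("H" %in% f[[1]])               # terminal carbon: all-C neighbors
  expect_identical(f[[2]], character(0))     # carbon bonded to O: featureless
  expect_setequal(f[[3]], c("A", "D"))       # hydroxyl oxygen

  benz <- parseMolecule("c1ccccc1", "benzene")
  fb <- assignFeatures(benz)
  expect_true(all(vapply(fb, function(x) "R" %in% x, logical(1))))
})

test_that("FPD and SHED match hand-computed histograms", {
  et <- parseMolecule("CCO", "ethanol")
  fpd <- computeFPD(et)
  expect_equal(sum(fpd), 1)
  nz <- fpd[fpd > 0]
  expect_setequal(names(nz), c("A:H|2", "D:H|2"))
  expect_equal(unname(nz[["A:H|2"]]), 0.5)

  hx <- parseMolecule("CCCCCC", "hexane")
  sh <- computeSHED(hx)
  # distance histogram over H:H pairs of n-hexane: counts 5,4,3,2,1
  q <- c(5, 4, 3, 2, 1) / 15
  expect_equal(unname(sh[["H:H"]]), -sum(q * log(q)), tolerance = 1e-12)
  expect_true(all(sh >= 0 & sh <= log(10)))
  expect_equal(shedDistance(sh, sh), 0)
})

test_that("PHRAG fragments are canonical and similarity is a bounded Tanimoto", {
  et <- parseMolecule("CCO", "ethanol")
  ph <- computePHRAG(et)
  expect_true(all(ph >= 1))
  expect_equal(phragSimilarity(ph, ph), 1)
  pr <- computePHRAG(parseMolecule("CCCO", "propanol"))
  s <- phragSimilarity(ph, pr)
  expect_gte(s, 0); expect_lte(s, 1)
  # canonical direction: every stored fragment is the lexicographic minimum
  # of its two reading directions
  revs <- vapply(strsplit(names(pr), "-"), function(x)
    paste(rev(x), collapse = "-"), character(1))
  expect_true(all(names(pr) <= revs))
})

test_that("fingerprints are order- and stereo-invariant with exact self-similarity", {
  a <- computeFingerprint(parseMolecule("OCC", "a"))
  b <- computeFingerprint(parseMolecule("CCO", "b"))
  expect_identical(a, b)
  expect_equal(tanimoto(a, b), 1)
  c2 <- computeFingerprint(parseMolecule("c1ccccc1C(N)=O", "c"))
  tc <- tanimoto(a, c2)
  expect_gte(tc, 0); expect_lte(tc, 1)
  expect_equal(tanimoto(a, c2), tanimoto(c2, a))
})

test_that("descriptor matrix export is deterministic", {
  mols <- list(parseMolecule("CCO", "a"), parseMolecule("CCN", "b"))
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  descriptorMatrix(mols, path = p1)
  descriptorMatrix(mols, path = p2)
  expect_identical(readLines(p1), readLines(p2))
})
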