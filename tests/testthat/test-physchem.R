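test_that("computed properties match hand counts on small molecules", {
  et <- computeProperties(parseMolecule("CCO", "ethanol"))
  expect_identical(et$HBD, 1L)
  expect_identical(et$HBA, 1L)
  expect_identical(et$n_rotatable, 0L)
  expect_identical(et$n_sp3_carbon, 2L)
  expect_equal(et$MW, 46.068, tolerance = 1e-3)
  expect_equal(et$TPSA, 20.23, tolerance = 1e-2)

  bu <- computeProperties(parseMolecule("CCCC", "butane"))
  expect_identical(bu$n_rotatable, 1L)

  # amide C-N bond is not rotatable
  am <- computeProperties(parseMolecule("CC(=O)NC", "nma"))
  expect_identical(am$n_rotatable, 0L)

  benzoic <- computeProperties(parseMolecule("OC(=O)c1ccccc1", "ba"))
  expect_equal(benzoic$pKa_acidic, 4.2)
  expect_true(is.na(benzoic$pKa_basic))
})

test_that("pKa pattern table assigns the documented values", {
  cases <- list(
    list("CCN", 10.6),            # aliphatic amine
    list("Nc1ccccc1", 4.6),       # aniline
    list("c1ccncc1", 5.2),        # pyridine
    list("c1c[nH]cn1", 7.0))      # imidazole
  for (cs in cases) {
    p <- computeProperties(parseMolecule(cs[[1]], "x"))
    expect_equal(p$pKa_basic, cs[[2]],
                 info = cs[[1]])
  }
  phenol <- computeProperties(parseMolecule("Oc1ccccc1", "ph"))
  expect_equal(phenol$pKa_acidic, 10.0)
})

test_that("3/75 boundaries are inclusive and Ro5 counts are exact", {
  prof <- data.frame(mol_id = "x", MW = 499.9, clogP = 3, TPSA = 75,
                     HBD = 5, HBA = 10, pKa_basic = NA_real_)
  r <- classifyRules(prof)
  expect_true(r$compliant_3_75)
  expect_identical(r$ro5_violations, 0L)
  prof2 <- within(prof, { MW <- 500; clogP <- 5; HBD <- 6; HBA <- 11 })
  expect_identical(classifyRules(prof2)$ro5_violations, 4L)
})

test_that("promiscuity profile counts off-targets per property bin with percentages", {
  profiles <- propertyProfiles(list(parseMolecule("CCO", "m1"),
                                    parseMolecule("CCCCCCCCCCCCCCCC", "m2")))
  pred <- data.frame(
    mol_id = c("m1", "m1", "m2", "m2", "m2"),
    target_id = paste0("T", 1:5),
    consensus_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    provenance = c("new", "confirmed", "new", "new", "new"),
    stringsAsFactors = FALSE)
  pp <- promiscuityProfile(pred, profiles)
  expect_equal(sum(pp$MW$n_offtargets), 4)      # only consensus-passing rows
  expect_equal(sum(pp$MW$percent), 100, tolerance = 1e-9)
  expect_identical(pp$MW$n_offtargets[pp$MW$bin == "<200"], 2L)  # ethanol
})

test_that("property profiles are stereo-invariant", {
  p1 <- computeProperties(parseMolecule("C[C@H](N)C(O)=O", "ala1"))
  p2 <- computeProperties(parseMolecule("C[C@@H](N)C(O)=O", "ala2"))
  p1$mol_id <- p2$mol_id <- "ala"
  expect_identical(p1, p2)
})
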