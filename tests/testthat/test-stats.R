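test_that("group summaries match closed forms", {
  s <- summarizeGroup(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$median, 2); expect_equal(s$sd, 1)
  one <- summarizeGroup(5)
  expect_equal(one$mean, 5); expect_equal(one$sd, 0)
  expect_true(one$sd_singleton)
  expect_error(summarizeGroup(numeric(0)), "empty")
  # even-n median by midpoint rule
  expect_equal(summarizeGroup(c(1, 2, 3, 10))$median, 2.5)
  # Monte-Carlo sanity bound
  set.seed(17)
  expect_lt(abs(summarizeGroup(stats::rnorm(1000, 5, 2))$mean - 5), 0.2)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(3)
  g1 <- stats::rnorm(12); g2 <- stats::rnorm(9, 0.5)
  cmp <- compareGroups(list(a = g1, b = g2))
  t2 <- stats::t.test(g1, g2, var.equal = TRUE)$statistic^2
  expect_equal(cmp$anova$F, unname(t2), tolerance = 1e-9)
  expect_identical(names(cmp$pairwise),
                   c("group_a", "group_b", "p_welch", "p_wilcoxon", "p_tukey"))
})

test_that("identical small groups give Wilcoxon p = 1 and separation gives small p", {
  # identical groups: the statistic sits at the null center, p = 1
  cmp <- compareGroups(list(a = 1:10, b = 1:10))
  expect_equal(cmp$pairwise$p_wilcoxon, 1)

  set.seed(5)
  lo <- c(0, 0, 0, 0) + stats::rnorm(4, 0, 1e-6)
  hi <- c(10, 10, 10, 10) + stats::rnorm(4, 0, 1e-6)
  cmp2 <- compareGroups(list(a = lo, b = hi))
  expect_lt(cmp2$pairwise$p_welch, 0.01)
  expect_lt(cmp2$pairwise$p_wilcoxon, 0.05)
  expect_lt(cmp2$anova$p, 0.01)
})

test_that("all-constant equal-mean groups are flagged degenerate with p = 1", {
  cmp <- compareGroups(list(a = rep(2, 5), b = rep(2, 7)))
  expect_true(cmp$anova$degenerate)
  expect_equal(cmp$anova$p, 1)
  expect_equal(cmp$pairwise$p_welch, 1)
})

test_that("tests are invariant to group-label order", {
  set.seed(11)
  g1 <- stats::rnorm(10); g2 <- stats::rnorm(12, 1); g3 <- stats::rnorm(8)
  c1 <- compareGroups(list(x = g1, y = g2, z = g3))
  c2 <- compareGroups(list(z = g3, x = g1, y = g2))
  expect_equal(c1$anova$p, c2$anova$p)
  expect_equal(c1$pairwise, c2$pairwise)
})

test_that("BH controls empirical FDR on null p-values", {
  set.seed(99)
  fdr <- vapply(seq_len(2000), function(i) {
    p <- stats::runif(20)
    mean(bhAdjust(p)$reject)  # all nulls: any rejection is a false discovery
  }, numeric(1))
  expect_lte(mean(fdr > 0), 0.07)  # P(any false rejection) <= q* + 2%
})

test_that("profile comparison emits raw and adjusted p per descriptor", {
  set.seed(21)
  mkProf <- function(shift) data.frame(
    mol_id = paste0("m", 1:15),
    MW = stats::rnorm(15, 300 + shift, 20),
    clogP = stats::rnorm(15, 2, 0.5),
    stringsAsFactors = FALSE)
  cmp <- compareProfiles(list(A = mkProf(0), B = mkProf(80)),
                         descriptors = c("MW", "clogP"))
  expect_setequal(unique(cmp$descriptor), c("MW", "clogP"))
  expect_true(all(cmp$q_anova >= cmp$p_anova - 1e-12))
  expect_true(all(cmp$significant[cmp$descriptor == "MW"]))
  expect_false(any(cmp$significant[cmp$descriptor == "clogP"]))
})

test_that("density tables share a grid across groups", {
  set.seed(4)
  dt <- densityTable(list(a = stats::rnorm(30), b = stats::rnorm(40, 2)),
                     nGrid = 64L)
  expect_identical(nrow(dt), 128L)
  expect_identical(dt$x[1:64], dt$x[65:128])
  expect_true(all(dt$density >= 0))
})
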