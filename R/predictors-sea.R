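# Set-wise similarity statistics: raw score against a target's ligand set,
# a size-dependent random background calibrated once per database, and the
# extreme-value tail that converts the z-score into a p-value and E-value.

.EULER_MASCHERONI <- 0.5772156649

# dense logical fingerprint matrix for fast set-vs-set Tanimoto
.fpMatrix <- function(descriptors, nbits) {
  ids <- names(descriptors)
  M <- matrix(FALSE, nrow = length(ids), ncol = nbits, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) M[i, descriptors[[ids[i]]]$fp + 1L] <- TRUE
  M
}

# sum of pairwise Tanimoto coefficients >= tauT between two row-index sets
.rawSetScore <- function(M, rowsA, rowsB, tauT) {
  A <- M[rowsA, , drop = FALSE] * 1
  B <- M[rowsB, , drop = FALSE] * 1
  inter <- A %*% t(B)
  na <- rowSums(A); nb <- rowSums(B)
  uni <- outer(na, nb, "+") - inter
  tc <- ifelse(uni > 0, inter / uni, 0)
  sum(tc[tc >= tauT])
}

# least-squares power-law fit mu = a * x^b on positive (x, y) pairs
.powerLawFit <- function(x, y) {
  keep <- x > 0 & y > 0
  if (sum(keep) < 2) return(NULL)
  fit <- stats::lm(log(y[keep]) ~ log(x[keep]))
  c(a = unname(exp(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
}

#' Calibrate the random-set similarity background of a database
#'
#' Samples pairs of random compound sets with sizes log-uniform in
#' [2, min(200, n/2)], computes each pair's raw score (the sum of pairwise
#' fingerprint Tanimoto coefficients at or above \code{tauT}) and fits the
#' mean and spread of the raw score as power laws of the set-size product
#' n1*n2 by least squares on the log scale.
#'
#' @param db a [ReferenceDatabase-class] with at least 20 compounds.
#' @param tauT Tanimoto threshold (default from config, 0.57).
#' @param nRandomSets number of random set pairs.
#' @param seed RNG seed.
#' @param config an [otsaConfig()] list (fingerprint parameters).
#' @param descriptors optional precomputed descriptor set.
#' @return list with power-law coefficients \code{a}, \code{b} (mean) and
#'   \code{c}, \code{e} (spread), plus \code{tauT}, \code{nRandomSets},
#'   \code{seed}.
#' @export
seaCalibrate <- function(db, tauT = 0.57, nRandomSets = 300L, seed = 17L,
                         config = otsaConfig(), descriptors = NULL) {
  ids <- sort(names(db@compounds))
  if (length(ids) < 20) stop("background calibration needs >= 20 compounds")
  if (is.null(descriptors))
    descriptors <- .descriptorSet(db@compounds[ids], config)
  M <- .fpMatrix(descriptors[ids], config$fpBits)
  szMax <- min(200L, floor(length(ids) / 2))
  set.seed(seed)
  sizes <- function() max(2L, min(szMax, round(exp(stats::runif(1, log(2), log(szMax))))))
  res <- data.frame(prod = numeric(nRandomSets), raw = numeric(nRandomSets))
  for (k in seq_len(nRandomSets)) {
    n1 <- sizes(); n2 <- sizes()
    rowsA <- sample(length(ids), n1)
    rowsB <- sample(length(ids), n2)
    res$prod[k] <- n1 * n2
    res$raw[k] <- .rawSetScore(M, rowsA, rowsB, tauT)
  }
  if (all(res$raw == 0))
    stop("degenerate background: every raw score is 0; lower tauT")
  bins <- cut(log(res$prod), breaks = 8)
  mu <- tapply(res$raw, bins, mean)
  sdv <- tapply(res$raw, bins, stats::sd)
  xm <- tapply(res$prod, bins, mean)
  fitMu <- .powerLawFit(xm, mu)
  fitSd <- .powerLawFit(xm, sdv)
  if (is.null(fitMu) || is.null(fitSd))
    stop("degenerate background fit; lower tauT or raise nRandomSets")
  list(a = fitMu[["a"]], b = fitMu[["b"]],
       c = fitSd[["a"]], e = fitSd[["b"]],
       tauT = tauT, nRandomSets = nRandomSets, seed = seed)
}

#' Extreme-value statistics for a raw set-similarity score
#'
#' z-standardizes the raw score against the calibrated background at set-size
#' product n1*n2 and applies the extreme-value tail
#' p = 1 - exp(-exp(-z*pi/sqrt(6) - gamma)) (gamma the Euler-Mascheroni
#' constant), then E = p * n_targets. At z = 0, p is about 0.4296; p -> 0 as
#' z -> +Inf and p -> 1 as z -> -Inf.
#'
#' @param raw raw score.
#' @param n1,n2 the two set sizes (>= 1).
#' @param bg background from [seaCalibrate()].
#' @param nTargets number of targets searched (Bonferroni-style factor).
#' @return list with \code{z}, \code{p}, \code{E}.
#' @export
seaStatistics <- function(raw, n1, n2, bg, nTargets) {
  stopifnot(n1 >= 1, n2 >= 1)
  x <- n1 * n2
  mu <- bg$a * x^bg$b
  sigma <- bg$c * x^bg$e
  if (!is.finite(sigma) || sigma <= 0)
    stop("invalid background: sigma <= 0 at n1*n2 = ", x)
  z <- (raw - mu) / sigma
  xev <- -z * pi / sqrt(6) - .EULER_MASCHERONI
  # stable 1 - exp(-exp(xev)) for very negative xev
  p <- -expm1(-exp(xev))
  list(z = z, p = p, E = p * nTargets)
}

# map an E-value to a bounded method score: -log10(E)/scale, clipped to
# [0,1]. At the default scale of 10, E <= 1e-6 (ten-thousand-fold beyond an
# E = 0.01 significance level) clears the consensus threshold of 0.6; E >= 1
# scores 0. The scale sets how much evidence beyond significance is demanded
# and should grow with the size of the reference database.
.seaScoreFromE <- function(E, scale = 10) {
  if (E >= 1) return(0)
  min(1, -log10(max(E, 1e-300)) / scale)
}
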