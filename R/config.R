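#' Default configuration for the prediction framework
#'
#' Every threshold used anywhere in the pipeline is named here and can be
#' overridden by argument or loaded from YAML ([loadConfig()]).
#'
#' \describe{
#'   \item{tau, k}{consensus rule: an interaction passes when at least
#'     \code{k} of the six methods score at or above \code{tau}
#'     (defaults 0.6 and 3; comparator \code{">="} — the inclusive reading).}
#'   \item{weights}{per-method weights of the normalized linear combination
#'     behind the pseudo-score; equal by default.}
#'   \item{tauT}{Tanimoto threshold of the set-similarity raw score
#'     (0.57, the conventional choice for this statistic).}
#'   \item{nRandomSets}{random set pairs used to calibrate the set-similarity
#'     background.}
#'   \item{L}{topological distance cap (bonds) for feature-pair descriptors;
#'     longer distances pool into bin L.}
#'   \item{featureSet}{"six" (D,A,H,R,P,N; 21 pairs) or "four" (D,A,H,R;
#'     10 pairs).}
#'   \item{fpBits, fpRadius}{hashed circular fingerprint width and radius.}
#'   \item{sigmaS}{length scale mapping entropy-descriptor distance to a
#'     similarity, exp(-d/sigmaS).}
#'   \item{reportFloor}{method scores below this are not emitted (0.2).}
#'   \item{fA, fB}{active-subgraph mining thresholds: minimum fraction of
#'     actives containing the subgraph (0.8) and maximum fraction of a
#'     size-matched background sample (0.1).}
#'   \item{minActives}{targets with fewer actives are excluded from
#'     SAR/MLM/SAS fitting (still scoreable by SIM/SEA/XPI).}
#'   \item{decoyRatio}{decoys per active for SAR/MLM training (3).}
#'   \item{xpiExclude}{targets with cross-pharmacology index above this are
#'     excluded from a target's decoy pool (0.8).}
#'   \item{mlmVotes}{classifiers (of 3) that must vote positive for the
#'     machine-learning consensus (2).}
#'   \item{mlmCap}{score cap when the vote fails (0.45, below tau).}
#'   \item{absentAsZero}{treat method scores a method never produced as 0 in
#'     the pseudo-score instead of excluding them (default FALSE).}
#'   \item{seed}{default seed for every stochastic step.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return a named list.
#' @export
otsaConfig <- function(...) {
  cfg <- list(
    tau = 0.6,
    k = 3L,
    comparator = ">=",
    weights = c(SAS = 1, SAR = 1, SIM = 1, SEA = 1, MLM = 1, XPI = 1),
    tauT = 0.57,
    nRandomSets = 300L,
    L = 10L,
    featureSet = "six",
    fpBits = 2048L,
    fpRadius = 2L,
    sigmaS = 1.0,
    reportFloor = 0.2,
    fA = 0.8,
    fB = 0.1,
    minActives = 5L,
    decoyRatio = 3L,
    xpiExclude = 0.8,
    mlmVotes = 2L,
    mlmCap = 0.45,
    seaScoreScale = 10,
    absentAsZero = FALSE,
    seed = 17L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$tau >= 0, cfg$tau <= 1, cfg$k >= 1,
            cfg$featureSet %in% c("six", "four"),
            all(cfg$weights >= 0), cfg$fA > 0, cfg$fA <= 1,
            cfg$fB >= 0, cfg$fB <= 1)
  cfg
}

#' Load configuration overrides from a YAML file
#' @param path YAML file whose top-level keys are [otsaConfig()] options.
#' @export
loadConfig <- function(path) {
  over <- yaml::read_yaml(path)
  if (!is.null(over$weights)) over$weights <- unlist(over$weights)
  do.call(otsaConfig, over)
}
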