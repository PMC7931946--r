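# Fitting the six ligand-centric methods against a reference database.

.dbHash <- function(db) {
  sig <- paste(c(vapply(db@compounds, smiles, character(1)),
                 paste(db@interactions$mol_id, db@interactions$target_id,
                       db@interactions$label)), collapse = ";")
  sprintf("%010.0f", .hashInts(utf8ToInt(sig)))
}

.sarFeatures <- function(bundle) {
  c(bundle$fpd,
    stats::setNames(bundle$shed, paste0("SHED_", names(bundle$shed))),
    bundle$props)
}

.xpiMatrix <- function(db) {
  t_ids <- targetIds(db)
  X <- matrix(0, length(t_ids), length(t_ids), dimnames = list(t_ids, t_ids))
  for (i in seq_along(t_ids)) for (j in seq_along(t_ids)) {
    ai <- db@actives[[t_ids[i]]]; aj <- db@actives[[t_ids[j]]]
    X[i, j] <- length(intersect(ai, aj)) / min(length(ai), length(aj))
  }
  diag(X) <- 1
  X
}

# decoy pool for one target: other targets' actives, excluding the target's
# own actives and actives of cross-pharmacology neighbors (X > xpiExclude);
# topped up with unannotated compounds when short
.decoyPool <- function(db, target, X, config) {
  t_ids <- targetIds(db)
  excl <- t_ids[X[, target] > config$xpiExclude]
  pool <- setdiff(unique(unlist(db@actives[setdiff(t_ids, excl)])),
                  db@actives[[target]])
  inactivePool <- setdiff(names(db@compounds),
                          c(unique(unlist(db@actives)), db@actives[[target]]))
  list(primary = sort(pool), fallback = sort(inactivePool))
}

.sampleDecoys <- function(pool, nWanted) {
  primary <- pool$primary
  picked <- if (length(primary) <= nWanted) primary
            else sample(primary, nWanted)
  short <- nWanted - length(picked)
  if (short > 0 && length(pool$fallback) > 0)
    picked <- c(picked, sample(pool$fallback, min(short, length(pool$fallback))))
  picked
}

.trainMatrix <- function(ids, decoys, descriptors, featureFun) {
  rows <- lapply(c(ids, decoys), function(id) featureFun(descriptors[[id]]))
  x <- do.call(rbind, rows)
  rownames(x) <- c(ids, decoys)
  y <- c(rep(1L, length(ids)), rep(0L, length(decoys)))
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  list(x = x[, keep, drop = FALSE], y = y, cols = colnames(x)[keep])
}

#' Fit one target-prediction method on a reference database
#'
#' \describe{
#'   \item{SIM}{stores per-target descriptor sets of the actives; no training.}
#'   \item{SEA}{stores per-target fingerprint sets and the calibrated random
#'     background ([seaCalibrate()]).}
#'   \item{SAS}{mines, per target, up to 3 minimal labeled paths present in
#'     at least \code{fA} of the actives and at most \code{fB} of a
#'     size-matched background sample.}
#'   \item{SAR}{per target, a ridge-regularized logistic classifier on
#'     standardized FPD + SHED + global-property vectors, actives vs 1:3
#'     decoys from other targets' actives, class-weighted.}
#'   \item{MLM}{per target, three classifiers on FPD vectors — a decision-tree
#'     ensemble, a kernel max-margin classifier and a small feed-forward
#'     network — same decoy scheme; scored by consensus.}
#'   \item{XPI}{the target-target cross-pharmacology matrix
#'     X(t,u) = |actives(t) ∩ actives(u)| / min(|actives|), diagonal 1.}
#' }
#' Targets with fewer than \code{minActives} actives are excluded from
#' SAS/SAR/MLM fitting (still scoreable by SIM/SEA/XPI).
#'
#' @param methodId one of "SAS","SAR","SIM","SEA","MLM","XPI".
#' @param db a [ReferenceDatabase-class].
#' @param config an [otsaConfig()] list.
#' @param seed seed for the method's stochastic steps.
#' @param descriptors optional precomputed descriptor set for the db
#'   compounds (computed if missing).
#' @return a [MethodModel-class].
#' @export
fitMethod <- function(methodId, db, config = otsaConfig(),
                      seed = config$seed, descriptors = NULL) {
  methodId <- match.arg(methodId, c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI"))
  if (is.null(descriptors))
    descriptors <- .descriptorSet(db@compounds, config)
  t_ids <- targetIds(db)
  nAct <- lengths(db@actives[t_ids])
  eligible <- t_ids[nAct >= config$minActives]
  skipped <- setdiff(t_ids, eligible)
  X <- .xpiMatrix(db)

  state <- switch(methodId,
    SIM = list(actives = db@actives),
    SEA = list(actives = db@actives,
               background = seaCalibrate(db, tauT = config$tauT,
                                         nRandomSets = config$nRandomSets,
                                         seed = seed, config = config,
                                         descriptors = descriptors),
               nTargets = length(t_ids)),
    XPI = list(X = X, actives = db@actives),
    SAS = {
      set.seed(seed)
      per <- list()
      for (t in eligible) {
        act <- db@actives[[t]]
        others <- setdiff(names(db@compounds), act)
        bgIds <- if (length(others) <= length(act)) others
                 else sample(sort(others), length(act))
        activeReds <- lapply(descriptors[act], `[[`, "reduced")
        bgReds <- lapply(descriptors[bgIds], `[[`, "reduced")
        mk <- function(ids, reds) Map(function(id, r)
          list(labels = r, nb = .neighborList(db@compounds[[id]]@graph)),
          ids, reds)
        per[[t]] <- .mineSAS(mk(act, activeReds), mk(bgIds, bgReds),
                             fA = config$fA, fB = config$fB)
      }
      list(sas = per, skipped = skipped)
    },
    SAR = {
      set.seed(seed)
      per <- list()
      for (t in eligible) {
        act <- sort(db@actives[[t]])
        pool <- .decoyPool(db, t, X, config)
        dec <- .sampleDecoys(pool, config$decoyRatio * length(act))
        tm <- .trainMatrix(act, dec, descriptors, .sarFeatures)
        ctr <- colMeans(tm$x); scl <- apply(tm$x, 2, stats::sd)
        xs <- scale(tm$x, center = ctr, scale = scl)
        w <- ifelse(tm$y == 1, length(dec) / length(act), 1)
        fit <- glmnet::glmnet(xs, tm$y, family = "binomial", alpha = 0,
                              lambda = 0.05, weights = w, standardize = FALSE)
        per[[t]] <- list(fit = fit, center = ctr, scale = scl, cols = tm$cols)
      }
      list(models = per, skipped = skipped)
    },
    MLM = {
      per <- list()
      for (t in eligible) {
        set.seed(seed + .hashInts(utf8ToInt(t)) %% 10000L)
        act <- sort(db@actives[[t]])
        pool <- .decoyPool(db, t, X, config)
        dec <- .sampleDecoys(pool, config$decoyRatio * length(act))
        tm <- .trainMatrix(act, dec, descriptors, function(b) b$fpd)
        # standardize: FPD entries are tiny normalized counts, and both the
        # kernel classifier and the network are scale-sensitive
        ctr <- colMeans(tm$x); scl <- apply(tm$x, 2, stats::sd)
        xs <- scale(tm$x, center = ctr, scale = scl)
        yf <- factor(tm$y, levels = c(0, 1))
        wpos <- length(dec) / length(act)
        rf <- randomForest::randomForest(xs, yf, ntree = 200,
                                         classwt = c("0" = 1, "1" = wpos))
        sv <- e1071::svm(xs, yf, probability = TRUE, kernel = "radial",
                         scale = FALSE,
                         class.weights = c("0" = 1, "1" = wpos))
        nn <- nnet::nnet(xs, tm$y, size = 4, decay = 0.05, maxit = 300,
                         entropy = TRUE, trace = FALSE,
                         weights = ifelse(tm$y == 1, wpos, 1))
        per[[t]] <- list(rf = rf, svm = sv, nnet = nn, cols = tm$cols,
                         center = ctr, scale = scl)
      }
      list(models = per, skipped = skipped)
    })
  if (length(skipped) && methodId %in% c("SAS", "SAR", "MLM"))
    message(methodId, ": skipped target(s) with < ", config$minActives,
            " actives: ", paste(skipped, collapse = ", "))
  new("MethodModel", methodId = methodId, state = state,
      dbFingerprint = .dbHash(db), seed = as.integer(seed))
}

#' Fit all six methods
#'
#' @inheritParams fitMethod
#' @return an [OTSAModel-class] bundling the fitted methods, the database,
#'   the configuration and the cached descriptor tables.
#' @export
fitOTSA <- function(db, config = otsaConfig(), seed = config$seed) {
  descriptors <- .descriptorSet(db@compounds, config)
  ids <- c("SIM", "SEA", "SAS", "SAR", "MLM", "XPI")
  methods <- lapply(ids, fitMethod, db = db, config = config, seed = seed,
                    descriptors = descriptors)
  names(methods) <- ids
  new("OTSAModel", db = db, methods = methods, config = config,
      descriptors = descriptors)
}
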