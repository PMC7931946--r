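# Pseudo-score aggregation, the consensus rule, interaction bookkeeping
# (training-set / confirmed / new), tissue-expression filtering, metabolite
# query sets, and the report generator with the cohort summary arithmetic.

.METHODS <- c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI")

#' Combine a parent compound with its metabolites into one query set
#'
#' The parent plus every parseable metabolite, canonicalized and
#' deduplicated; each query is tagged with the parent id and its role
#' (parent/metabolite) so downstream predictions can be traced back. If all
#' metabolites fail to parse, the query set is the parent alone (warning).
#'
#' @param parent a [Molecule-class].
#' @param metabolites character vector of metabolite SMILES.
#' @return list with \code{queries} (list of [Molecule-class]) and
#'   \code{roles} (data.frame: mol_id, parent_id, role).
#' @export
mergeMetaboliteList <- function(parent, metabolites = character()) {
  stopifnot(is(parent, "Molecule"))
  queries <- list(parent)
  roles <- data.frame(mol_id = molId(parent), parent_id = molId(parent),
                      role = "parent", stringsAsFactors = FALSE)
  seen <- smiles(parent)
  nbad <- 0L
  for (k in seq_along(metabolites)) {
    m <- tryCatch(parseMolecule(metabolites[k],
                                paste0(molId(parent), "_M", k)),
                  error = function(e) NULL)
    if (is.null(m)) { nbad <- nbad + 1L; next }
    if (smiles(m) %in% seen) next
    seen <- c(seen, smiles(m))
    queries[[length(queries) + 1L]] <- m
    roles <- rbind(roles, data.frame(mol_id = molId(m),
                                     parent_id = molId(parent),
                                     role = "metabolite",
                                     stringsAsFactors = FALSE))
  }
  if (nbad > 0 && nbad == length(metabolites))
    warning("all metabolites unparseable; query set is the parent alone")
  list(queries = queries, roles = roles)
}

#' Aggregate per-method scores into the pseudo-score
#'
#' A pseudo-score of 1.00 reflects certainty and is assigned whenever the
#' query is present in the training set with that mechanism of action.
#' Otherwise the pseudo-score is the weighted mean of the method scores that
#' are present (the normalized linear combination), with absent methods
#' excluded by default — a target a method could not score is not penalized
#' (set \code{absentAsZero} to treat absences as zeros instead).
#'
#' @param scores named numeric vector of per-method scores in [0,1]
#'   (subset of SAS/SAR/SIM/SEA/MLM/XPI).
#' @param inTraining TRUE when the (query, target, active) triple is in the
#'   reference database.
#' @param weights named non-negative weights (default equal).
#' @param absentAsZero treat missing methods as scoring 0.
#' @return pseudo-score in [0,1]; NA when no method produced a score (the
#'   pair belongs in the no-signal tally, not the report).
#' @export
aggregatePseudoScore <- function(scores, inTraining = FALSE,
                                 weights = c(SAS = 1, SAR = 1, SIM = 1,
                                             SEA = 1, MLM = 1, XPI = 1),
                                 absentAsZero = FALSE) {
  if (inTraining) return(1.0)
  scores <- scores[!is.na(scores)]
  if (absentAsZero) {
    full <- stats::setNames(rep(0, length(weights)), names(weights))
    full[names(scores)] <- scores
    scores <- full
  }
  if (length(scores) == 0) return(NA_real_)
  stopifnot(all(scores >= 0 & scores <= 1), all(weights >= 0))
  w <- weights[names(scores)]
  sum(w * scores) / sum(w)
}

#' The consensus filter
#'
#' An interaction is high-confidence when at least \code{k} of the six
#' methods score at or above \code{tau} (defaults 3 and 0.6). Training-set
#' predictions pass unconditionally. The rule is monotone: raising any
#' method score never flips a pass into a fail.
#'
#' @param scores named numeric vector of per-method scores (absent methods
#'   simply missing).
#' @param tau score threshold.
#' @param k minimum number of methods at or above tau.
#' @param inTraining training-set override.
#' @param comparator ">=" (default) or ">".
#' @return logical.
#' @export
consensusFilter <- function(scores, tau = 0.6, k = 3L, inTraining = FALSE,
                            comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (inTraining) return(TRUE)
  scores <- scores[!is.na(scores)]
  nAbove <- if (comparator == ">=") sum(scores >= tau) else sum(scores > tau)
  nAbove >= k
}

# canonical-SMILES lookup of queries against the database compound table
.dbMatchByCanon <- function(queries, db) {
  canonToDb <- stats::setNames(names(db@compounds),
                               vapply(db@compounds, smiles, character(1)))
  qcan <- vapply(queries, smiles, character(1))
  stats::setNames(unname(canonToDb[qcan]), vapply(queries, molId, character(1)))
}

#' Predict targets for a query set and assemble interaction predictions
#'
#' Runs all six methods, pivots the method scores per (query, target) pair,
#' adds training-set pairs (exact canonical-SMILES match with an active
#' annotation), aggregates the pseudo-score and applies the consensus filter.
#'
#' @param model an [OTSAModel-class].
#' @param queries a [MoleculeSet-class] or list of [Molecule-class].
#' @param truth optional [TruthTable-class] for provenance classification.
#' @return data.frame: mol_id, target_id, one column per method (NA when the
#'   method emitted no score), pseudo_score, n_methods_above, consensus_pass,
#'   provenance.
#' @export
predictTargets <- function(model, queries, truth = NULL) {
  if (is(queries, "MoleculeSet")) queries <- queries@molecules
  cfg <- model@config
  long <- scoreAll(model, queries)
  dbMatch <- .dbMatchByCanon(queries, model@db)

  pairKey <- unique(long[, c("mol_id", "target_id")])
  # training pairs present even if a method missed them
  trainPairs <- do.call(rbind, lapply(names(dbMatch), function(q) {
    dbid <- dbMatch[[q]]
    if (is.na(dbid)) return(NULL)
    ts <- targetIds(model@db)[vapply(targetIds(model@db), function(t)
      dbid %in% model@db@actives[[t]], logical(1))]
    if (!length(ts)) return(NULL)
    data.frame(mol_id = q, target_id = ts, stringsAsFactors = FALSE)
  }))
  pairKey <- unique(rbind(pairKey, trainPairs))
  pairKey <- pairKey[order(pairKey$mol_id, pairKey$target_id), , drop = FALSE]

  wide <- matrix(NA_real_, nrow = nrow(pairKey), ncol = length(.METHODS),
                 dimnames = list(NULL, .METHODS))
  idx <- match(paste(long$mol_id, long$target_id),
               paste(pairKey$mol_id, pairKey$target_id))
  for (r in seq_len(nrow(long)))
    wide[idx[r], long$method[r]] <- long$score[r]

  inTraining <- vapply(seq_len(nrow(pairKey)), function(r) {
    dbid <- dbMatch[[pairKey$mol_id[r]]]
    !is.na(dbid) && dbid %in% model@db@actives[[pairKey$target_id[r]]]
  }, logical(1))

  S <- vapply(seq_len(nrow(pairKey)), function(r)
    aggregatePseudoScore(wide[r, ], inTraining = inTraining[r],
                         weights = cfg$weights,
                         absentAsZero = cfg$absentAsZero), numeric(1))
  nAbove <- vapply(seq_len(nrow(pairKey)), function(r) {
    s <- wide[r, ]; s <- s[!is.na(s)]
    if (cfg$comparator == ">=") sum(s >= cfg$tau) else sum(s > cfg$tau)
  }, integer(1))
  pass <- vapply(seq_len(nrow(pairKey)), function(r)
    consensusFilter(wide[r, ], tau = cfg$tau, k = cfg$k,
                    inTraining = inTraining[r],
                    comparator = cfg$comparator), logical(1))

  out <- cbind(pairKey, as.data.frame(wide),
               data.frame(pseudo_score = S, n_methods_above = nAbove,
                          consensus_pass = pass, in_training = inTraining))
  out <- out[!is.na(out$pseudo_score), , drop = FALSE]
  rownames(out) <- NULL
  classifyInteractions(out, model@db, truth,
                       dbMatch = dbMatch[unique(out$mol_id)])
}

#' Classify predictions as training-set, confirmed or new
#'
#' Provenance is training_set when the (compound, target, active) triple is
#' in the reference database (exact canonical-SMILES match), else confirmed
#' when the pair is in the truth table, else new. Exactly one value per
#' prediction; partition sizes over the consensus-passing subset satisfy
#' total = training_set + confirmed + new.
#'
#' @param predictionTable data.frame from [predictTargets()] (or with at
#'   least mol_id, target_id, in_training columns).
#' @param db the [ReferenceDatabase-class].
#' @param truth optional [TruthTable-class].
#' @param dbMatch optional precomputed query-to-db id map.
#' @return the table with a \code{provenance} column.
#' @export
classifyInteractions <- function(predictionTable, db, truth = NULL,
                                 dbMatch = NULL) {
  truthKey <- if (is.null(truth)) character(0) else
    paste(truth@pairs$mol_id, truth@pairs$target_id)
  prov <- character(nrow(predictionTable))
  for (r in seq_len(nrow(predictionTable))) {
    q <- predictionTable$mol_id[r]; t <- predictionTable$target_id[r]
    if (isTRUE(predictionTable$in_training[r])) { prov[r] <- "training_set"; next }
    dbid <- if (!is.null(dbMatch)) dbMatch[[q]] else NA_character_
    inTruth <- paste(q, t) %in% truthKey ||
      (!is.na(dbid) && paste(dbid, t) %in% truthKey)
    prov[r] <- if (inTruth) "confirmed" else "new"
  }
  predictionTable$provenance <- prov
  predictionTable
}

#' Filter predictions by tissue expression
#'
#' Keeps predictions whose target is expressed at or above \code{minExpr} in
#' the tissue; targets absent from the matrix are retained and flagged
#' expression-unknown (the filter only removes what the data can rule out).
#'
#' @param predictionTable prediction data.frame.
#' @param expr an [ExpressionMatrix-class].
#' @param tissue tissue name (fatal if unknown, listing available tissues).
#' @param minExpr minimum expression to retain.
#' @return filtered table with an \code{expression_status} column
#'   ("expressed" or "unknown").
#' @export
filterByExpression <- function(predictionTable, expr, tissue, minExpr = 1) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (!tissue %in% colnames(expr@values))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(expr@values), collapse = ", "))
  known <- predictionTable$target_id %in% rownames(expr@values)
  val <- rep(NA_real_, nrow(predictionTable))
  val[known] <- expr@values[predictionTable$target_id[known], tissue]
  keep <- !known | val >= minExpr
  out <- predictionTable[keep, , drop = FALSE]
  out$expression_status <- ifelse(known[keep], "expressed", "unknown")
  rownames(out) <- NULL
  out
}

#' Cohort summary arithmetic
#'
#' The printed-report arithmetic on interaction counts: provenance
#' conservation, mean interactions per compound (one decimal when rendered)
#' and provenance percentages.
#'
#' @param total,confirmed,new,training counts of consensus-passing
#'   interactions by provenance (total = confirmed + new + training).
#' @param nCompounds cohort size.
#' @return list of the derived statistics.
#' @export
cohortArithmetic <- function(total, confirmed, new, training, nCompounds) {
  if (total != confirmed + new + training)
    stop("conservation violated: total != confirmed + new + training")
  list(
    total_interactions = total,
    confirmed = confirmed, new = new, training_set = training,
    n_compounds = nCompounds,
    mean_interactions_per_compound = total / nCompounds,
    mean_interactions_rendered = round(total / nCompounds, 1),
    pct_new = if (total > training) 100 * new / (total - training) else 0,
    pct_confirmed = if (total > training) 100 * confirmed / (total - training) else 0,
    pct_training = if (total > 0) 100 * training / total else 0)
}

#' Generate the off-target report
#'
#' Per-compound prediction lists ranked by descending pseudo-score (ties by
#' n_methods_above, then target id) over the consensus-passing subset, plus
#' the cohort summary: totals by provenance, mean interactions per compound,
#' per-method coverage fractions among non-training interactions (fraction
#' the method scored at or above tau) and the all-six-methods fraction.
#'
#' @param predictionTable data.frame from [predictTargets()].
#' @param nCompounds cohort size (defaults to the number of distinct query
#'   ids in the table — pass the true cohort size when some compounds got no
#'   predictions).
#' @param alertTable optional data.frame (target_id, alert) joined as an
#'   annotation column.
#' @param tau consensus score threshold used for the coverage fractions.
#' @return an [OTSAReport-class].
#' @export
generateReport <- function(predictionTable, nCompounds = NULL,
                           alertTable = NULL, tau = 0.6) {
  pass <- predictionTable[predictionTable$consensus_pass, , drop = FALSE]
  ord <- order(pass$mol_id, -pass$pseudo_score, -pass$n_methods_above,
               pass$target_id)
  pass <- pass[ord, , drop = FALSE]
  rownames(pass) <- NULL
  if (!is.null(alertTable)) {
    pass$alert <- alertTable$alert[match(pass$target_id, alertTable$target_id)]
  }
  if (is.null(nCompounds))
    nCompounds <- length(unique(predictionTable$mol_id))

  total <- nrow(pass)
  training <- sum(pass$provenance == "training_set")
  confirmed <- sum(pass$provenance == "confirmed")
  newN <- sum(pass$provenance == "new")
  nonTrain <- pass[pass$provenance != "training_set", , drop = FALSE]
  coverage <- vapply(.METHODS, function(m) {
    if (nrow(nonTrain) == 0) return(NA_real_)
    mean(!is.na(nonTrain[[m]]) & nonTrain[[m]] >= tau)
  }, numeric(1))
  allSix <- if (nrow(nonTrain) == 0) NA_real_ else
    mean(apply(as.matrix(nonTrain[, .METHODS]), 1,
               function(s) all(!is.na(s) & s >= tau)))

  summary <- c(
    cohortArithmetic(total, confirmed, newN, training,
                     max(nCompounds, 1L)),
    list(method_coverage = coverage, all_six_fraction = allSix))
  new("OTSAReport", predictions = pass, summary = summary)
}

#' Write a report to disk
#'
#' Emits \code{predictions.tsv} and \code{summary.json} in \code{dir}.
#'
#' @param report an [OTSAReport-class].
#' @param dir output directory (created if needed).
#' @param parseReport optional parse report data.frame, written as
#'   \code{parse_report.txt}.
#' @export
writeReport <- function(report, dir, parseReport = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report@predictions, file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report@summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(parseReport))
    utils::write.table(parseReport, file.path(dir, "parse_report.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
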