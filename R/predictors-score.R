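# Scoring a query molecule against a fitted method. Every emitted score lies
# in [0,1]; scores below the report floor are not emitted; a target a method
# could not be fitted for is absent from that method's list (not zero).

.clip01 <- function(x) pmin(1, pmax(0, x))

.scoreRow <- function(molIdv, target, method, score, evidence) {
  data.frame(mol_id = molIdv, target_id = target, method = method,
             score = score, evidence = evidence, stringsAsFactors = FALSE)
}

#' Score a query molecule with one fitted method
#'
#' Scoring rules per method: \strong{SIM} max over the target's actives of the
#' mean of fingerprint Tanimoto, fragment-multiset similarity and
#' exp(-d/sigmaS) of the entropy-descriptor distance. \strong{SEA} maps the
#' E-value of the query against the target's ligand set to
#' min(1, -log10(E)/40) (0 when E >= 1). \strong{SAS} 0 unless a mined
#' subgraph matches the query's reduced graph, else 0.6 + 0.4 x the best
#' matching subgraph's background specificity. \strong{SAR}/\strong{MLM}
#' class probability of the positive class (MLM: mean of three classifiers if
#' at least 2 vote positive, else capped at 0.45). \strong{XPI} max over
#' targets u of (nearest-neighbor fingerprint similarity to u's actives) x
#' X(u, t).
#'
#' @param model a fitted [MethodModel-class].
#' @param query a [Molecule-class].
#' @param db the [ReferenceDatabase-class] the model was fitted on.
#' @param config an [otsaConfig()] list.
#' @param descriptors the database descriptor cache (as in [OTSAModel-class]).
#' @param queryBundle optional precomputed descriptor bundle for the query.
#' @return data.frame with columns mol_id, target_id, method, score,
#'   evidence; only scores >= \code{config$reportFloor} are emitted.
#' @export
scoreMethod <- function(model, query, db, config = otsaConfig(),
                        descriptors = NULL, queryBundle = NULL) {
  stopifnot(is(model, "MethodModel"), is(query, "Molecule"))
  if (is.null(descriptors)) descriptors <- .descriptorSet(db@compounds, config)
  if (is.null(queryBundle)) queryBundle <- .descriptorBundle(query, config)
  qid <- molId(query)
  t_ids <- targetIds(db)
  rows <- list()
  mid <- model@methodId

  if (mid == "SIM") {
    for (t in t_ids) {
      best <- 0; bestId <- ""
      for (aid in model@state$actives[[t]]) {
        b <- descriptors[[aid]]
        s <- mean(c(as.numeric(tanimoto(queryBundle$fp, b$fp)),
                    as.numeric(phragSimilarity(queryBundle$phrag, b$phrag)),
                    exp(-shedDistance(queryBundle$shed, b$shed) / config$sigmaS)))
        if (s > best) { best <- s; bestId <- aid }
      }
      if (best > 0)
        rows[[length(rows) + 1L]] <- .scoreRow(qid, t, "SIM", .clip01(best),
                                               paste0("nn=", bestId))
    }
  } else if (mid == "SEA") {
    bg <- model@state$background
    for (t in t_ids) {
      act <- model@state$actives[[t]]
      tc <- vapply(act, function(aid)
        as.numeric(tanimoto(queryBundle$fp, descriptors[[aid]]$fp)), numeric(1))
      raw <- sum(tc[tc >= bg$tauT])
      st <- seaStatistics(raw, 1L, length(act), bg, model@state$nTargets)
      s <- .seaScoreFromE(st$E, config$seaScoreScale)
      rows[[length(rows) + 1L]] <- .scoreRow(qid, t, "SEA", .clip01(s),
                                             sprintf("E=%.3g;z=%.2f", st$E, st$z))
    }
  } else if (mid == "SAS") {
    red <- list(labels = queryBundle$reduced,
                nb = .neighborList(query@graph))
    for (t in names(model@state$sas)) {
      cands <- model@state$sas[[t]]
      if (!length(cands)) next
      matched <- Filter(function(cc) .containsLabelPath(red, cc$labels), cands)
      if (!length(matched)) next
      best <- matched[[which.max(vapply(matched, `[[`, numeric(1), "specificity"))]]
      s <- 0.6 + 0.4 * best$specificity
      rows[[length(rows) + 1L]] <- .scoreRow(qid, t, "SAS", .clip01(s),
                                             paste0("sas=", best$pattern))
    }
  } else if (mid == "SAR") {
    xall <- .sarFeatures(queryBundle)
    for (t in names(model@state$models)) {
      m <- model@state$models[[t]]
      xv <- xall[m$cols]
      xs <- (xv - m$center) / m$scale
      p <- as.numeric(stats::predict(m$fit, newx = matrix(xs, nrow = 1),
                                     type = "response"))
      rows[[length(rows) + 1L]] <- .scoreRow(qid, t, "SAR", .clip01(p),
                                             sprintf("p=%.3f", p))
    }
  } else if (mid == "MLM") {
    for (t in names(model@state$models)) {
      m <- model@state$models[[t]]
      xv <- matrix((queryBundle$fpd[m$cols] - m$center) / m$scale,
                   nrow = 1, dimnames = list(NULL, m$cols))
      pRf <- stats::predict(m$rf, xv, type = "prob")[, "1"]
      pSv <- attr(stats::predict(m$svm, xv, probability = TRUE),
                  "probabilities")[, "1"]
      pNn <- as.numeric(stats::predict(m$nnet, xv))
      probs <- c(rf = pRf, svm = pSv, nnet = pNn)
      votes <- sum(probs >= 0.5)
      s <- if (votes >= config$mlmVotes) mean(probs)
           else min(mean(probs), config$mlmCap)
      rows[[length(rows) + 1L]] <- .scoreRow(
        qid, t, "MLM", .clip01(s),
        sprintf("votes=%d;rf=%.2f;svm=%.2f;nn=%.2f", votes, pRf, pSv, pNn))
    }
  } else if (mid == "XPI") {
    X <- model@state$X
    simNN <- vapply(t_ids, function(u) {
      max(vapply(model@state$actives[[u]], function(aid)
        as.numeric(tanimoto(queryBundle$fp, descriptors[[aid]]$fp)),
        numeric(1)))
    }, numeric(1))
    for (t in t_ids) {
      vals <- simNN * X[t_ids, t]
      s <- max(vals)
      if (s > 0) {
        u <- t_ids[which.max(vals)]
        rows[[length(rows) + 1L]] <- .scoreRow(qid, t, "XPI", .clip01(s),
                                               paste0("via=", u))
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    .scoreRow(character(0), character(0), character(0), numeric(0), character(0))
  out <- out[out$score >= config$reportFloor, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score queries with all six fitted methods
#'
#' @param model an [OTSAModel-class] from [fitOTSA()].
#' @param queries a [MoleculeSet-class] or list of [Molecule-class].
#' @return long data.frame of method scores (mol_id, target_id, method,
#'   score, evidence), sorted for reproducibility.
#' @export
scoreAll <- function(model, queries) {
  if (is(queries, "MoleculeSet")) queries <- queries@molecules
  cfg <- model@config
  out <- list()
  for (q in queries) {
    qb <- .descriptorBundle(q, cfg)
    for (m in model@methods) {
      out[[length(out) + 1L]] <- scoreMethod(m, q, model@db, cfg,
                                             descriptors = model@descriptors,
                                             queryBundle = qb)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mol_id, res$target_id, res$method), ]
  rownames(res) <- NULL
  res
}
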