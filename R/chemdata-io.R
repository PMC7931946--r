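# Readers for the plain-text formats the framework consumes: SMILES lists,
# tabular TSV (tab-separated, UTF-8, '#' comments, header row required for
# tables), SDF v2000, truth tables and expression matrices.

.readTSV <- function(path, requireCols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineNo <- which(keep)
  if (length(lines) < 1L) stop("no header row in ", path)
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(requireCols, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  attr(df, "lineNo") <- lineNo[-1]
  df
}

.parseRecords <- function(ids, smiles, lineNo) {
  mols <- vector("list", length(ids))
  status <- rep("ok", length(ids))
  note <- rep("", length(ids))
  for (k in seq_along(ids)) {
    m <- tryCatch(parseMolecule(smiles[k], ids[k]), error = function(e) e)
    if (inherits(m, "error")) {
      status[k] <- "skipped"
      note[k] <- conditionMessage(m)
    } else {
      mols[[k]] <- m
      nfrag <- length(strsplit(smiles[k], ".", fixed = TRUE)[[1]])
      if (nfrag > 1L) note[k] <- "largest fragment retained"
    }
  }
  report <- data.frame(line = lineNo, input = smiles, status = status,
                       note = note, stringsAsFactors = FALSE)
  ok <- status == "ok"
  if (!any(ok)) stop("zero parseable records")
  mols <- mols[ok]
  ids <- vapply(mols, molId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate mol_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  new("MoleculeSet", molecules = mols, parseReport = report)
}

#' Read query molecules from a file
#'
#' Supported formats: \code{"smiles-list"} (one molecule per line, optional
#' whitespace-separated id after the SMILES), \code{"tsv"} (header row; id and
#' SMILES column names configurable) and \code{"sdf"} (v2000, records split on
#' \code{$$$$}). Unparseable records are skipped and reported with their line
#' or record number in the parse report — never silently dropped.
#'
#' @param path input file.
#' @param format one of \code{"smiles-list"}, \code{"tsv"}, \code{"sdf"}.
#' @param idColumn,smilesColumn column names for \code{format = "tsv"}.
#' @return a [MoleculeSet-class]; inspect [parseReport()] for skipped records.
#' @export
readMoleculeTable <- function(path, format = c("smiles-list", "tsv", "sdf"),
                              idColumn = "mol_id", smilesColumn = "smiles") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles-list") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
    smi <- vapply(toks, `[`, character(1), 1)
    ids <- vapply(seq_along(toks), function(k)
      if (length(toks[[k]]) > 1) toks[[k]][2] else paste0("mol", k), character(1))
    .parseRecords(ids, smi, lineNo)
  } else if (format == "tsv") {
    df <- .readTSV(path, requireCols = c(idColumn, smilesColumn))
    .parseRecords(df[[idColumn]], df[[smilesColumn]], attr(df, "lineNo"))
  } else {
    txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
    breaks <- c(0L, which(grepl("^\\${4}", txt)))
    recs <- list(); recNo <- integer()
    for (k in seq_len(length(breaks) - 1L)) {
      block <- txt[(breaks[k] + 1L):(breaks[k + 1L] - 1L)]
      if (any(nzchar(trimws(block)))) {
        recs[[length(recs) + 1L]] <- paste(c(block, "$$$$"), collapse = "\n")
        recNo <- c(recNo, k)
      }
    }
    if (!length(recs)) stop("zero parseable records")
    ids <- character(length(recs)); smi <- character(length(recs))
    status <- rep("ok", length(recs)); note <- rep("", length(recs))
    mols <- vector("list", length(recs))
    for (k in seq_along(recs)) {
      obm <- .obRead(recs[[k]], format = "sdf")
      if (is.null(obm)) { status[k] <- "skipped"; note[k] <- "unreadable SDF record"; next }
      title <- trimws(strsplit(recs[[k]], "\n")[[1]][1])
      ids[k] <- if (nzchar(title)) title else paste0("mol", recNo[k])
      smi[k] <- .obCanonicalSmiles(obm, stripStereo = FALSE)
      m <- tryCatch(parseMolecule(smi[k], ids[k]), error = function(e) e)
      if (inherits(m, "error")) { status[k] <- "skipped"; note[k] <- conditionMessage(m) }
      else mols[[k]] <- m
    }
    report <- data.frame(line = recNo, input = smi, status = status,
                         note = note, stringsAsFactors = FALSE)
    ok <- status == "ok"
    if (!any(ok)) stop("zero parseable records")
    mols <- mols[ok]
    outIds <- vapply(mols, molId, character(1))
    if (anyDuplicated(outIds))
      stop("duplicate mol_id: ", paste(unique(outIds[duplicated(outIds)]), collapse = ", "))
    new("MoleculeSet", molecules = mols, parseReport = report)
  }
}

#' Write molecules to a TSV table
#'
#' @param molecules a [MoleculeSet-class] or list of [Molecule-class].
#' @param path output path.
#' @export
writeMoleculeTable <- function(molecules, path) {
  if (is(molecules, "MoleculeSet")) molecules <- molecules@molecules
  df <- data.frame(
    mol_id = vapply(molecules, molId, character(1)),
    smiles = vapply(molecules, smiles, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a reference bioactivity database from a TSV activity table
#'
#' Required columns: \code{mol_id}, \code{smiles}, \code{target_id},
#' \code{label} (\code{active}/\code{inactive}); optional \code{potency}
#' (µM; carried but unused by the predictors, which are qualitative) and
#' \code{target_family}. Compounds are deduplicated by canonical SMILES
#' (first id wins, aliases recorded); targets with zero actives are dropped
#' with a warning; conflicting labels for one (compound, target) pair are a
#' fatal error.
#'
#' @param path TSV activity table.
#' @param quiet suppress the count message.
#' @return a [ReferenceDatabase-class].
#' @export
loadReferenceDatabase <- function(path, quiet = FALSE) {
  df <- .readTSV(path, requireCols = c("mol_id", "smiles", "target_id", "label"))
  if (!"target_family" %in% names(df)) df$target_family <- "unknown"
  if (!"potency" %in% names(df)) df$potency <- NA_character_
  bad <- !df$label %in% c("active", "inactive")
  if (any(bad)) stop("invalid label(s): ", paste(unique(df$label[bad]), collapse = ", "))

  # parse and deduplicate compounds by canonical SMILES
  firstRow <- !duplicated(df$mol_id)
  ids <- df$mol_id[firstRow]
  smis <- df$smiles[firstRow]
  compounds <- list()
  canonOwner <- character()   # canonical smiles -> retained id
  aliases <- character()
  idMap <- character()        # every input id -> retained id
  for (k in seq_along(ids)) {
    m <- parseMolecule(smis[k], ids[k])
    can <- smiles(m)
    if (can %in% names(canonOwner)) {
      keep <- canonOwner[[can]]
      aliases[ids[k]] <- keep
      idMap[ids[k]] <- keep
    } else {
      canonOwner[can] <- ids[k]
      compounds[[ids[k]]] <- m
      idMap[ids[k]] <- ids[k]
    }
  }

  inter <- data.frame(
    mol_id = unname(idMap[df$mol_id]),
    target_id = df$target_id,
    label = df$label,
    potency_uM = suppressWarnings(as.numeric(df$potency)),
    stringsAsFactors = FALSE)
  inter <- inter[order(inter$target_id, inter$mol_id, inter$label), ]
  inter <- inter[!duplicated(paste(inter$mol_id, inter$target_id, inter$label)), ]
  key <- paste(inter$mol_id, inter$target_id)
  if (anyDuplicated(key)) {
    conf <- unique(key[duplicated(key)])
    stop("conflicting labels for (mol_id, target_id): ",
         paste(head(conf, 10), collapse = "; "))
  }

  fam <- tapply(df$target_family, df$target_id, function(x) x[1])
  tids <- sort(unique(inter$target_id))
  actives <- lapply(tids, function(t)
    sort(unique(inter$mol_id[inter$target_id == t & inter$label == "active"])))
  names(actives) <- tids
  inactives <- lapply(tids, function(t)
    sort(unique(inter$mol_id[inter$target_id == t & inter$label == "inactive"])))
  names(inactives) <- tids

  dropped <- tids[lengths(actives) == 0L]
  if (length(dropped)) {
    warning("dropping target(s) with zero actives: ",
            paste(dropped, collapse = ", "))
    keepT <- setdiff(tids, dropped)
    actives <- actives[keepT]; inactives <- inactives[keepT]
    inter <- inter[inter$target_id %in% keepT, ]
    tids <- keepT
  }

  targets <- data.frame(target_id = tids,
                        target_family = unname(fam[tids]),
                        stringsAsFactors = FALSE)
  db <- new("ReferenceDatabase",
            compounds = compounds, targets = targets,
            actives = actives, inactives = inactives,
            interactions = inter, aliases = aliases)
  if (!quiet)
    message(sprintf("loaded %d compounds, %d targets, %d interactions (%d alias(es))",
                    length(compounds), nrow(targets), nrow(inter), length(aliases)))
  db
}

#' Load a known-interaction truth table
#'
#' TSV with columns \code{mol_id}, \code{target_id} and optional
#' \code{source}; duplicate pairs collapse (first source wins).
#'
#' @param path TSV path.
#' @return a [TruthTable-class].
#' @export
loadTruthTable <- function(path) {
  df <- .readTSV(path, requireCols = c("mol_id", "target_id"))
  if (!"source" %in% names(df)) df$source <- "user"
  df <- df[!duplicated(paste(df$mol_id, df$target_id)),
           c("mol_id", "target_id", "source")]
  rownames(df) <- NULL
  new("TruthTable", pairs = df)
}

#' Load a target-by-tissue expression matrix
#'
#' TSV whose first column is the target id and remaining columns are tissues;
#' all entries must parse as non-negative numbers.
#'
#' @param path TSV path.
#' @param species species label carried on the object.
#' @return an [ExpressionMatrix-class].
#' @export
loadExpressionMatrix <- function(path, species = "unspecified") {
  df <- .readTSV(path)
  if (ncol(df) < 2L) stop("expression matrix needs >= 1 tissue column")
  tid <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at row ", bad[1], ", column ", bad[2] + 1)
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at row ", bad[1], ", column ", bad[2] + 1)
  }
  rownames(num) <- tid
  new("ExpressionMatrix", values = num, species = species)
}

#' Look up an expression value
#' @param expr an [ExpressionMatrix-class].
#' @param target,tissue row and column names.
#' @export
expressionValue <- function(expr, target, tissue) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (!tissue %in% colnames(expr@values))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(expr@values), collapse = ", "))
  if (!target %in% rownames(expr@values)) return(NA_real_)
  expr@values[target, tissue]
}
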