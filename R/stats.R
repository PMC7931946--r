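# Cohort-comparison battery: group summaries, one-way ANOVA with Tukey HSD,
# pairwise Welch tests, Wilcoxon rank-sum (exact for small tie-free samples),
# and Benjamini-Hochberg adjustment. All tests delegate to base R stats.

#' Summarize one group of values
#'
#' @param values numeric vector, n >= 1.
#' @return list with n, mean, median, sd (sample SD, n-1 denominator; defined
#'   as 0 for n = 1 with \code{sd_singleton = TRUE}).
#' @export
summarizeGroup <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty group")
  if (anyNA(values)) stop("NA values in group")
  list(n = length(values), mean = mean(values), median = stats::median(values),
       sd = if (length(values) == 1) 0 else stats::sd(values),
       sd_singleton = length(values) == 1)
}

# Wilcoxon rank-sum p-value: exact enumeration iff both n <= 10 and no ties,
# else the normal approximation with tie correction (base R's rules, made
# explicit here so the exactness cutoff is a documented contract).
.wilcoxonP <- function(a, b) {
  exact <- length(a) <= 10 && length(b) <= 10 &&
    !any(duplicated(c(a, b)))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
}

#' Compare two or more groups per descriptor
#'
#' For each pair of groups: Welch's unequal-variance t-test, Wilcoxon
#' rank-sum (exact enumeration when both n <= 10 and there are no ties,
#' normal approximation with tie correction otherwise) and Tukey HSD
#' adjusted p (studentized range on the one-way fit). Plus the one-way ANOVA
#' F and p across all groups. When every group has zero variance and all
#' means are equal the comparison is degenerate: p = 1, flagged.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with \code{anova} (F, p, degenerate flag) and
#'   \code{pairwise} data.frame (group_a, group_b, p_welch, p_wilcoxon,
#'   p_tukey).
#' @export
compareGroups <- function(groups) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)),
            all(lengths(groups) >= 2))
  groups <- groups[sort(names(groups))]
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  degenerate <- all(vapply(groups, stats::var, numeric(1)) == 0) &&
    length(unique(vapply(groups, mean, numeric(1)))) == 1
  if (degenerate) {
    cmb <- utils::combn(names(groups), 2)
    pw <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                     p_welch = 1, p_wilcoxon = 1, p_tukey = 1,
                     stringsAsFactors = FALSE)
    return(list(anova = list(F = NA_real_, p = 1, degenerate = TRUE),
                pairwise = pw))
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  cmb <- utils::combn(names(groups), 2)
  pw <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                   p_welch = NA_real_, p_wilcoxon = NA_real_,
                   p_tukey = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pw))) {
    a <- groups[[pw$group_a[r]]]; b <- groups[[pw$group_b[r]]]
    pw$p_welch[r] <- stats::t.test(a, b, var.equal = FALSE)$p.value
    pw$p_wilcoxon[r] <- .wilcoxonP(a, b)
    key1 <- paste0(pw$group_b[r], "-", pw$group_a[r])
    key2 <- paste0(pw$group_a[r], "-", pw$group_b[r])
    pw$p_tukey[r] <- tk[intersect(c(key1, key2), rownames(tk))[1], "p adj"]
  }
  list(anova = list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                    degenerate = FALSE),
       pairwise = pw)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values (monotone by construction of the procedure) with
#' rejection at q <= qstar.
#'
#' @param pvalues numeric vector of p-values in [0,1].
#' @param qstar FDR level (default 0.05).
#' @return list with \code{q} and logical \code{reject}; empty in, empty out.
#' @export
bhAdjust <- function(pvalues, qstar = 0.05) {
  if (length(pvalues) == 0)
    return(list(q = numeric(0), reject = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= qstar)
}

#' Compare property profiles of two or more cohorts
#'
#' One comparison per shared numeric descriptor column: per-group summaries,
#' ANOVA, pairwise Welch / Wilcoxon / Tukey, then BH adjustment of the ANOVA
#' p-values across descriptors. Both raw and adjusted p-values are emitted.
#'
#' @param profiles named list of data.frames from [propertyProfiles()] (or
#'   any frames sharing numeric columns).
#' @param descriptors which columns to compare (default: all shared numeric
#'   columns except mol_id).
#' @param qstar FDR level for significance.
#' @return data.frame with one row per (descriptor, group): n, mean, median,
#'   sd, plus per-descriptor p_anova, q_anova, significant, and the minimum
#'   pairwise Welch/Wilcoxon p-values for orientation.
#' @export
compareProfiles <- function(profiles, descriptors = NULL, qstar = 0.05) {
  stopifnot(length(profiles) >= 2, !is.null(names(profiles)))
  shared <- Reduce(intersect, lapply(profiles, colnames))
  numeric_cols <- shared[vapply(shared, function(cn)
    is.numeric(profiles[[1]][[cn]]), logical(1))]
  if (is.null(descriptors)) descriptors <- setdiff(numeric_cols, "mol_id")
  stopifnot(all(descriptors %in% numeric_cols))

  rows <- list(); pAnova <- numeric(0)
  for (d in descriptors) {
    groups <- lapply(profiles, function(p) p[[d]][!is.na(p[[d]])])
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 2) next
    cmp <- compareGroups(groups)
    pAnova[d] <- cmp$anova$p
    for (gname in names(groups)) {
      s <- summarizeGroup(groups[[gname]])
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = d, group = gname, n = s$n, mean = s$mean,
        median = s$median, sd = s$sd, p_anova = cmp$anova$p,
        p_welch_min = min(cmp$pairwise$p_welch),
        p_wilcoxon_min = min(cmp$pairwise$p_wilcoxon),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  adj <- bhAdjust(pAnova, qstar)
  out$q_anova <- adj$q[match(out$descriptor, names(pAnova))]
  out$significant <- out$q_anova <= qstar
  rownames(out) <- NULL
  out
}

#' Kernel-density summary table for violin-style rendering
#'
#' A shared evaluation grid over the pooled range with the per-group kernel
#' density estimate at each grid point; rendering is left to the caller.
#'
#' @param groups named list of numeric vectors.
#' @param nGrid grid resolution.
#' @return data.frame: group, x, density.
#' @export
densityTable <- function(groups, nGrid = 128L) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            all(lengths(groups) >= 2))
  rng <- range(unlist(groups))
  grid <- seq(rng[1], rng[2], length.out = nGrid)
  out <- lapply(sort(names(groups)), function(gname) {
    d <- stats::density(groups[[gname]], from = rng[1], to = rng[2],
                        n = nGrid)
    data.frame(group = gname, x = grid, density = d$y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
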