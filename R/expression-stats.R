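## Dot-plot expression statistics: expressing-cell frequencies (always on raw
## counts), mean normalized expression, top-k gene panels, and the group
## comparisons used throughout (two-sided Mann-Whitney; one-/two-way ANOVA
## with Tukey or Dunnett post hoc tests).

.cluster_cells <- function(cells, cluster) {
  idx <- which(cells$cluster_label == cluster)
  if (!length(idx)) {
    stop("undefined value: cluster '", cluster, "' is empty", call. = FALSE)
  }
  idx
}

#' Fraction of cells expressing a gene
#'
#' The frequency of cells with at least one raw transcript of `gene` in
#' `cluster`; computed on the raw layer by contract, so it is invariant under
#' any normalization.
#'
#' @param counts a `count_matrix`.
#' @param cells cell table aligned with the matrix rows.
#' @param cluster cluster label.
#' @param gene gene symbol.
#' @return fraction in \[0, 1\].
#' @export
frac_expressing <- function(counts, cells, cluster, gene) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!gene %in% colnames(counts$raw)) {
    stop("unknown gene '", gene, "'", call. = FALSE)
  }
  idx <- .cluster_cells(cells, cluster)
  mean(counts$raw[idx, gene] >= 1)
}

#' Two-sided Mann-Whitney comparison
#'
#' Exact P value for small samples (both groups of 8 or fewer, no ties),
#' normal approximation with tie correction otherwise. No continuity
#' correction is applied, so identical multisets give P = 1 exactly.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `p`, `statistic` (the Mann-Whitney U of `a`), and
#'   `significant` (P < 0.05).
#' @export
compare_two_sided <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    ## every pooled value identical: no evidence of any shift
    return(list(p = 1, statistic = length(a) * length(b) / 2, significant = FALSE))
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  p <- min(1, ht$p.value)
  list(p = p, statistic = unname(ht$statistic), significant = p < 0.05)
}

#' ANOVA with post hoc pairwise comparisons
#'
#' One-way ANOVA with Tukey's HSD, or (two-way designs) ANOVA on two crossed
#' factors with Dunnett comparisons of `group` levels against the first
#' level. Degenerate inputs (all values equal) are flagged and reported as
#' P = 1.
#'
#' @param values numeric response.
#' @param group primary grouping factor (the factor compared post hoc).
#' @param design `"one_way"` or `"two_way"`.
#' @param posthoc `"tukey"` or `"dunnett"` (Dunnett compares against the
#'   first factor level).
#' @param group2 second factor, required for `design = "two_way"`.
#' @return list with `omnibus_p` (P for the `group` main effect),
#'   `posthoc` (data frame: comparison, estimate, p), and `degenerate` flag.
#' @export
anova_posthoc <- function(values, group,
                          design = c("one_way", "two_way"),
                          posthoc = c("tukey", "dunnett"),
                          group2 = NULL) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (length(unique(values)) == 1L) {
    cmp <- utils::combn(levels(group), 2)
    ph <- data.frame(comparison = paste(cmp[2, ], cmp[1, ], sep = " - "),
                     estimate = 0, p = 1, stringsAsFactors = FALSE)
    return(list(omnibus_p = 1, posthoc = ph, degenerate = TRUE))
  }
  df <- data.frame(y = values, g = group)
  if (design == "two_way") {
    if (is.null(group2)) stop("two_way design needs group2", call. = FALSE)
    df$g2 <- factor(group2)
    fit <- stats::aov(y ~ g + g2, data = df)
  } else {
    fit <- stats::aov(y ~ g, data = df)
  }
  tab <- summary(fit)[[1]]
  omnibus_p <- tab[["Pr(>F)"]][trimws(rownames(tab)) == "g"][1]
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit, which = "g")$g
    ph <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                     p = tk[, "p adj"], stringsAsFactors = FALSE,
                     row.names = NULL)
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    ph <- data.frame(comparison = names(sm$test$coefficients),
                     estimate = unname(sm$test$coefficients),
                     p = unname(as.vector(sm$test$pvalues)),
                     stringsAsFactors = FALSE)
  }
  list(omnibus_p = unname(omnibus_p), posthoc = ph, degenerate = FALSE)
}

#' Dot-plot table for a set of genes
#'
#' One row per cluster x condition x gene with the expressing-cell frequency
#' (raw layer), mean normalized expression, cell count, the Mann-Whitney P of
#' the cluster against all other clusters in the same condition, and (when
#' exactly two conditions are present) the Mann-Whitney P between conditions
#' within the cluster. Cells are pooled across donors within condition.
#'
#' @param counts a normalized `count_matrix` (see [normalize_counts()]).
#' @param cells cell table aligned with the matrix rows; needs
#'   `cluster_label` and `condition` columns.
#' @param genes genes to tabulate (must be in the panel).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"`, matching raw P < 0.05 calls
#'   (`"BH"` available).
#' @return data frame of class `dotplot_table`.
#' @export
dotplot_table <- function(counts, cells, genes, p_adjust = "none") {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(counts$normalized)) counts <- normalize_counts(counts)
  missing <- setdiff(genes, colnames(counts$raw))
  if (length(missing)) {
    stop("unknown gene '", missing[1], "'", call. = FALSE)
  }
  clusters <- sort(unique(cells$cluster_label))
  conditions <- unique(cells$condition)
  two_cond <- length(conditions) == 2L
  rows <- list()
  for (cl in clusters) {
    for (cond in conditions) {
      in_cl <- cells$cluster_label == cl & cells$condition == cond
      other <- cells$cluster_label != cl & cells$condition == cond
      for (g in genes) {
        v_cl <- counts$normalized[in_cl, g]
        p_other <- if (any(in_cl) && any(other)) {
          compare_two_sided(v_cl, counts$normalized[other, g])$p
        } else NA_real_
        p_cond <- if (two_cond) {
          oth_cond <- cells$cluster_label == cl & cells$condition != cond
          if (any(in_cl) && any(oth_cond)) {
            compare_two_sided(v_cl, counts$normalized[oth_cond, g])$p
          } else NA_real_
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, condition = cond, gene = g,
          n_cells = sum(in_cl),
          frac_expressing = if (any(in_cl)) mean(counts$raw[in_cl, g] >= 1) else NA_real_,
          mean_norm_expression = if (any(in_cl)) mean(v_cl) else NA_real_,
          p_vs_other_clusters = p_other,
          p_between_conditions = p_cond,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_vs_other_clusters <- stats::p.adjust(out$p_vs_other_clusters, p_adjust)
    out$p_between_conditions <- stats::p.adjust(out$p_between_conditions, p_adjust)
  }
  class(out) <- c("dotplot_table", "data.frame")
  out
}

#' Top-k expressed genes of a cluster
#'
#' Genes ranked by mean normalized expression within the cluster, descending;
#' ties broken lexicographically. The `k = 5` list doubles as the cluster's
#' primary gene signature for ROI enrichment scoring.
#'
#' @param counts a normalized `count_matrix`.
#' @param cells cell table aligned with the matrix rows.
#' @param cluster cluster label.
#' @param k number of genes (k > panel size is truncated with a warning).
#' @return character vector of gene symbols.
#' @export
top_k <- function(counts, cells, cluster, k) {
  stopifnot(inherits(counts, "count_matrix"), k >= 1)
  if (is.null(counts$normalized)) counts <- normalize_counts(counts)
  idx <- .cluster_cells(cells, cluster)
  means <- Matrix::colMeans(counts$normalized[idx, , drop = FALSE])
  genes <- colnames(counts$raw)
  if (k > length(genes)) {
    warning("k exceeds panel size; returning all ", length(genes), " genes")
    k <- length(genes)
  }
  ord <- order(-means, genes)
  genes[ord][seq_len(k)]
}

#' Percent change between two means
#'
#' `(mean_target - mean_reference) / mean_reference * 100`, the convention
#' behind statements such as "~660% more".
#'
#' @param mean_target,mean_reference means; the reference must be positive.
#' @return percent change.
#' @export
pct_change <- function(mean_target, mean_reference) {
  if (!is.finite(mean_reference) || mean_reference <= 0) {
    stop("undefined value: reference mean must be positive", call. = FALSE)
  }
  (mean_target - mean_reference) / mean_reference * 100
}
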