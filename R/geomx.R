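## GeoMx-style ROI pipeline: negative-probe limit of quantification, target
## filtering, upper-quartile (Q3) normalization and signature enrichment
## scores, with ANOVA-based group comparisons across pathology groups.

GEOMX_REGIONS <- c("epithelium", "subepithelium", "smooth_muscle")
GEOMX_PATHOLOGY <- c("healthy", "mild", "severe")

#' Construct a GeoMx-style experiment
#'
#' @param counts numeric matrix, targets (rows, named) by ROIs (columns,
#'   named); raw counts.
#' @param is_negative logical per target, `TRUE` for negative probes (no
#'   tissue target). At least 2 negative probes are required, otherwise the
#'   background s.d. is undefined.
#' @param roi_meta data frame with columns `roi_id`, `region`
#'   (epithelium/subepithelium/smooth_muscle), `pathology`
#'   (healthy/mild/severe) and `donor`, one row per ROI column.
#' @param k_sd background multiplier: the limit of quantification sits
#'   `k_sd` geometric standard deviations above the geometric mean of the
#'   negative probes (default 2).
#' @param raw_floor total raw read floor used by [filter_targets()]
#'   (default 5000).
#' @return a `geomx_experiment`.
#' @export
geomx_experiment <- function(counts, is_negative, roi_meta,
                             k_sd = 2, raw_floor = 5000) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_config("counts must be non-negative")
  if (length(is_negative) != nrow(counts)) {
    abort_config("is_negative must flag every target row")
  }
  if (ncol(counts) > 0 && sum(is_negative) < 2) {
    abort_config("at least 2 negative probes are required (s.d. undefined)")
  }
  stopifnot(is.data.frame(roi_meta),
            all(c("roi_id", "region", "pathology", "donor") %in% names(roi_meta)),
            nrow(roi_meta) == ncol(counts))
  if (!all(roi_meta$region %in% GEOMX_REGIONS)) {
    abort_config("region must be one of: epithelium, subepithelium, smooth_muscle")
  }
  if (!all(roi_meta$pathology %in% GEOMX_PATHOLOGY)) {
    abort_config("pathology must be one of: healthy, mild, severe")
  }
  structure(list(counts = counts, is_negative = as.logical(is_negative),
                 roi_meta = roi_meta, k_sd = k_sd, raw_floor = raw_floor,
                 normalized = NULL, detected = NULL),
            class = "geomx_experiment")
}

#' @export
print.geomx_experiment <- function(x, ...) {
  cat(sprintf(
    "geomx_experiment: %d targets (%d negative probes) x %d ROIs%s\n",
    nrow(x$counts), sum(x$is_negative), ncol(x$counts),
    if (!is.null(x$normalized)) ", Q3-normalized" else ""))
  invisible(x)
}

#' Read a GeoMx count table and ROI metadata from TSV
#'
#' Counts: targets as rows (first column `target`), ROIs as columns;
#' negative probes are recognized by a `NegProbe` name prefix. Metadata: one
#' row per ROI with `roi_id`, `region`, `pathology`, `donor`.
#'
#' @param counts_path,meta_path TSV paths.
#' @param ... passed to [geomx_experiment()].
#' @return a `geomx_experiment`.
#' @export
read_geomx <- function(counts_path, meta_path, ...) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"target" %in% names(df)) abort_format("missing required column 'target'")
  counts <- as.matrix(df[, setdiff(names(df), "target"), drop = FALSE])
  rownames(counts) <- df$target
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(counts), meta$roi_id), , drop = FALSE]
  geomx_experiment(counts, startsWith(df$target, "NegProbe"), meta, ...)
}

#' Per-ROI limit of quantification
#'
#' `LOQ = exp(mean(log(neg)) + k_sd * sd(log(neg)))`: k_sd geometric standard
#' deviations above the geometric mean of the negative probes (sample s.d.,
#' n - 1). Computed in log space by default; `space = "arithmetic"` uses the
#' arithmetic mean/s.d. of the raw probe counts instead.
#'
#' @param experiment a `geomx_experiment`.
#' @param space `"geometric"` (default) or `"arithmetic"`.
#' @return named numeric vector, one LOQ per ROI.
#' @export
loq <- function(experiment, space = c("geometric", "arithmetic")) {
  space <- match.arg(space)
  neg <- experiment$counts[experiment$is_negative, , drop = FALSE]
  if (space == "geometric" && any(neg <= 0)) {
    stop("negative probe count <= 0: log undefined (use space = 'arithmetic' ",
         "or add a pseudo-count upstream)", call. = FALSE)
  }
  k <- experiment$k_sd
  out <- apply(neg, 2, function(v) {
    if (space == "geometric") exp(mean(log(v)) + k * stats::sd(log(v)))
    else mean(v) + k * stats::sd(v)
  })
  stats::setNames(out, colnames(experiment$counts))
}

#' Remove negative probes and consistently-undetected targets
#'
#' Negative probes leave the target space. A target is removed when it is
#' below its ROI's LOQ in every ROI ("consistently below") and its summed
#' raw reads across ROIs fall under `raw_floor`; `rule = "or"` switches to
#' the disjunctive reading. The per-ROI detected flag (`count > LOQ`) is
#' stored on the returned experiment.
#'
#' @param experiment a `geomx_experiment`.
#' @param rule `"and"` (default) or `"or"` combination of the two criteria.
#' @return the filtered `geomx_experiment`.
#' @export
filter_targets <- function(experiment, rule = c("and", "or")) {
  rule <- match.arg(rule)
  l <- loq(experiment)
  counts <- experiment$counts[!experiment$is_negative, , drop = FALSE]
  detected <- sweep(counts, 2, l, ">")
  below_everywhere <- rowSums(detected) == 0
  under_floor <- rowSums(counts) < experiment$raw_floor
  drop <- if (rule == "and") below_everywhere & under_floor
          else below_everywhere | under_floor
  keep <- !drop
  out <- experiment
  out$counts <- counts[keep, , drop = FALSE]
  out$is_negative <- rep(FALSE, sum(keep))
  out$detected <- detected[keep, , drop = FALSE]
  out$loq <- l
  out
}

#' Upper-quartile (Q3) normalization
#'
#' Each ROI is scaled by (geometric mean of all ROI Q3s) / (its own Q3),
#' where Q3 is the 75th percentile of the ROI's filtered target counts
#' (linear interpolation). After normalization every ROI has the same Q3, so
#' the operation is idempotent.
#'
#' @param experiment a filtered `geomx_experiment`.
#' @return the experiment with a `normalized` matrix added.
#' @export
q3_normalize <- function(experiment) {
  counts <- experiment$normalized %||% experiment$counts
  q3 <- apply(counts, 2, stats::quantile, probs = 0.75, names = FALSE)
  if (any(q3 <= 0)) {
    stop("ROI '", colnames(counts)[which(q3 <= 0)[1]],
         "' has Q3 = 0; cannot normalize", call. = FALSE)
  }
  factors <- geomean(q3) / q3
  out <- experiment
  out$normalized <- sweep(counts, 2, factors, "*")
  out$q3_factors <- factors
  out
}

#' Single-sample signature enrichment score
#'
#' Rank-based running-sum enrichment of a gene signature in one ROI profile
#' (ssGSEA-style). Genes are ranked by decreasing expression; walking down
#' the ranking, signature genes advance the running sum proportionally to
#' their rank statistic raised to `alpha`, other genes retreat it uniformly;
#' the score is the sum of the running-sum deviations. Positive when the
#' signature occupies top ranks, negative when it sits at the bottom;
#' invariant under strictly monotone transforms of the profile.
#'
#' @param profile named numeric vector (one ROI's expression over the
#'   filtered target space).
#' @param signature character vector of signature genes; at least one must
#'   be measured.
#' @param alpha rank weighting exponent (default 0.25).
#' @return numeric enrichment score.
#' @export
enrichment_score <- function(profile, signature, alpha = 0.25) {
  genes <- names(profile)
  signature <- intersect(signature, genes)
  if (!length(signature)) {
    stop("undefined score: no signature gene measured", call. = FALSE)
  }
  n <- length(profile)
  m <- length(signature)
  if (m == n) stop("signature covers the whole target space", call. = FALSE)
  ord <- order(-profile, genes)         # ties broken lexicographically
  in_sig <- genes[ord] %in% signature
  r <- (n:1)^alpha                      # rank statistic by list position
  step_in <- ifelse(in_sig, r, 0)
  step_in <- step_in / sum(step_in)
  step_out <- ifelse(in_sig, 0, 1 / (n - m))
  sum(cumsum(step_in) - cumsum(step_out))
}

#' Enrichment scores for a signature set across all ROIs
#'
#' @param experiment a Q3-normalized `geomx_experiment`.
#' @param signatures named list of gene signatures (e.g. top-5 cluster
#'   signatures from [top_k()]).
#' @param alpha rank weighting exponent (default 0.25).
#' @return matrix of scores, signatures by ROIs.
#' @export
enrichment_scores <- function(experiment, signatures, alpha = 0.25) {
  mat <- experiment$normalized %||% experiment$counts
  out <- vapply(seq_len(ncol(mat)), function(j) {
    profile <- stats::setNames(mat[, j], rownames(mat))
    vapply(signatures, enrichment_score, numeric(1),
           profile = profile, alpha = alpha)
  }, numeric(length(signatures)))
  out <- matrix(out, nrow = length(signatures),
                dimnames = list(names(signatures), colnames(mat)))
  out
}

#' Compare values across pathology groups within a region
#'
#' Subsets ROIs to `region` and runs [anova_posthoc()] on the pathology
#' factor (reference level `healthy` for Dunnett comparisons).
#'
#' @param values named per-ROI values (e.g. a gene's normalized counts or an
#'   enrichment score row), names matching `roi_id`.
#' @param experiment a `geomx_experiment`.
#' @param region region to analyze.
#' @param design,posthoc passed to [anova_posthoc()]; the default mirrors a
#'   two-way region-by-pathology ANOVA with Dunnett comparisons against
#'   healthy when `region = NULL`.
#' @return result of [anova_posthoc()].
#' @export
group_compare <- function(values, experiment, region = NULL,
                          design = if (is.null(region)) "two_way" else "one_way",
                          posthoc = "dunnett") {
  meta <- experiment$roi_meta
  values <- values[meta$roi_id]
  keep <- if (is.null(region)) rep(TRUE, nrow(meta)) else meta$region == region
  pathology <- factor(meta$pathology[keep], levels = GEOMX_PATHOLOGY)
  pathology <- droplevels(pathology)
  anova_posthoc(values[keep], pathology, design = design, posthoc = posthoc,
                group2 = if (design == "two_way") meta$region[keep] else NULL)
}
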