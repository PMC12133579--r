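## Synthetic GeoMx-style ROI experiment: ROI-by-target counts with negative
## probes drawn from a log-normal background noise model and a configured
## subset of targets planted above the limit of quantification.

#' Configuration for the synthetic ROI experiment
#'
#' @param targets measured target names (default: the tissue panel).
#' @param n_neg_probes number of negative probes (default 20; at least 2).
#' @param rois_per_group ROIs per region x pathology combination (default 4).
#' @param regions,pathologies controlled vocabularies (defaults: the three
#'   stained regions and the three pathology groups).
#' @param background_mean geometric mean of background counts (default 50).
#' @param background_sdlog log-normal s.d. of background noise (default 0.4).
#' @param signal_fold multiplicative separation of planted targets above
#'   background (default 8).
#' @param detect_fraction fraction of targets planted above the LOQ
#'   (default 0.5).
#' @return a `geomx_config`.
#' @export
geomx_config <- function(targets = default_panel(),
                         n_neg_probes = 20,
                         rois_per_group = 4,
                         regions = GEOMX_REGIONS,
                         pathologies = GEOMX_PATHOLOGY,
                         background_mean = 50,
                         background_sdlog = 0.4,
                         signal_fold = 8,
                         detect_fraction = 0.5) {
  if (n_neg_probes < 2) {
    abort_config("fewer than 2 negative probes (s.d. undefined)")
  }
  stopifnot(rois_per_group >= 0, background_mean > 0, background_sdlog > 0,
            signal_fold > 1, detect_fraction >= 0, detect_fraction <= 1)
  structure(list(targets = targets, n_neg_probes = n_neg_probes,
                 rois_per_group = rois_per_group, regions = regions,
                 pathologies = pathologies, background_mean = background_mean,
                 background_sdlog = background_sdlog,
                 signal_fold = signal_fold, detect_fraction = detect_fraction),
            class = "geomx_config")
}

#' Generate a synthetic GeoMx experiment with recorded truth
#'
#' Counts are log-normal: background for negative probes and undetected
#' targets, `signal_fold` above background for the planted detected subset.
#' The truth records which targets were planted above the LOQ.
#'
#' @param config a [geomx_config()].
#' @param seed integer seed.
#' @return list with `experiment` (a `geomx_experiment`) and `truth`.
#' @export
generate_geomx <- function(config, seed = 1) {
  stopifnot(inherits(config, "geomx_config"))
  withr::with_seed(as.integer(seed), {
    groups <- expand.grid(region = config$regions,
                          pathology = config$pathologies,
                          rep = seq_len(config$rois_per_group),
                          stringsAsFactors = FALSE)
    n_roi <- nrow(groups)
    roi_meta <- data.frame(
      roi_id = if (n_roi) sprintf("ROI%03d", seq_len(n_roi)) else character(),
      region = groups$region, pathology = groups$pathology,
      donor = if (n_roi) sprintf("D%d", ((groups$rep - 1L) %% 4L) + 1L) else character(),
      stringsAsFactors = FALSE)

    neg_names <- sprintf("NegProbe%02d", seq_len(config$n_neg_probes))
    all_names <- c(config$targets, neg_names)
    n_planted <- round(config$detect_fraction * length(config$targets))
    planted <- sort(sample(config$targets, n_planted))
    meanlog <- log(config$background_mean) +
      ifelse(all_names %in% planted, log(config$signal_fold), 0)

    counts <- matrix(0, nrow = length(all_names), ncol = n_roi,
                     dimnames = list(all_names, roi_meta$roi_id))
    if (n_roi > 0) {
      counts[] <- round(stats::rlnorm(length(counts),
                                      meanlog = rep(meanlog, times = n_roi),
                                      sdlog = config$background_sdlog))
      counts <- pmax(counts, 1)  # library-level floor keeps logs defined
    }
    experiment <- geomx_experiment(counts,
                                   is_negative = all_names %in% neg_names,
                                   roi_meta = roi_meta)
    truth <- structure(list(planted_above_loq = planted,
                            signal_fold = config$signal_fold,
                            seed = seed),
                       class = "synthetic_truth")
    list(experiment = experiment, truth = truth)
  })
}
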