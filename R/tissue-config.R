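## Configuration of the synthetic airway-wall tissue generator. The defaults
## describe the emulated study conditions: two transcript-rich niches
## (an epithelial band and a mucous gland) separated by a smooth-muscle band,
## ~16 spatially structured cell clusters over a 339-gene panel with
## negative-binomial counts, planted chemokine/alarmin hubs just inside the
## tissue, and disease-condition effects (reduced alarmin/chemokine
## expression, contracted cell placement around hub anchors).

#' Default niche geometry
#'
#' Three stacked bands (micrometres, y increasing downward as in the imaging
#' convention): epithelial 0-150, smooth muscle 150-250, mucous gland
#' 250-450.
#'
#' @param width_um tissue width (default 600).
#' @return a [region_set()].
#' @export
default_niche_regions <- function(width_um = 600) {
  region_set(list(
    epithelial = rect_poly(0, 0, width_um, 150),
    smooth_muscle = rect_poly(0, 150, width_um, 250),
    mucous_gland = rect_poly(0, 250, width_um, 450)
  ))
}

#' Default cluster catalogue
#'
#' 16 clusters with a spatial placement rule (one niche name, or `"any"` for
#' tissue-wide placement) and relative abundance weights.
#'
#' @return data frame with `name`, `niche`, `weight`.
#' @export
default_cluster_catalogue <- function() {
  data.frame(
    name = c("BC1", "BC2", "goblet", "ciliated", "club",
             "serous1", "serous2", "SMC",
             "EnC1", "EnC2", "fibroblast", "mast", "macrophage",
             "plasma", "Tcell", "monocyte"),
    niche = c("epithelial", "epithelial", "epithelial", "epithelial",
              "epithelial", "mucous_gland", "mucous_gland", "smooth_muscle",
              "any", "any", "any", "any", "any", "any", "any", "any"),
    weight = c(0.06, 0.10, 0.08, 0.10, 0.05,
               0.07, 0.03, 0.12,
               0.07, 0.05, 0.10, 0.05, 0.05, 0.03, 0.03, 0.01),
    stringsAsFactors = FALSE
  )
}

.marker_genes <- function() {
  list(
    BC1 = c("KRT15", "F3", "KRT5", "TP63"),
    BC2 = c("KRT14", "S100A2", "DST", "KRT17"),
    goblet = c("MUC5B", "MUC5AC", "KRT7", "TACSTD2", "CYP2F1", "KLK11"),
    ciliated = c("FOXJ1", "TPPP3", "PIFO", "DNAAF1"),
    club = c("SCGB1A1", "SCGB3A1", "BPIFB1", "CYP2B6"),
    serous1 = c("LTF", "DMBT1", "LYZ", "PIP"),
    serous2 = c("LTF", "ZG16B", "AZGP1", "DMBT1"),
    SMC = c("ACTA2", "MYH11", "TAGLN", "DES", "CNN1"),
    EnC1 = c("PECAM1", "CLDN5", "CD34", "EGFL7"),
    EnC2 = c("VWF", "PLVAP", "ACKR1", "SELE"),
    fibroblast = c("COL1A1", "COL3A1", "COL1A2", "PDGFRA", "APOD", "LUM", "DCN"),
    mast = c("CPA3", "KIT", "MS4A2", "TPSAB1", "AREG", "HPGDS"),
    macrophage = c("MARCO", "CD68", "MRC1", "MSR1", "C1QA"),
    plasma = c("JCHAIN", "MZB1", "DERL3"),
    Tcell = c("CD3E", "CD8A", "IL7R", "TRBC2"),
    monocyte = c("FCN1", "S100A8", "S100A9", "VCAN")
  )
}

#' Default 339-gene panel
#'
#' Canonical airway cell-type markers, the chemokine and alarmin sets, a few
#' drug-target genes, padded with filler probes to the panel size of 339.
#'
#' @return character vector of 339 gene symbols.
#' @export
default_panel <- function() {
  named <- unique(c(unlist(.marker_genes(), use.names = FALSE),
                    chemokine_genes(), alarmin_genes(),
                    c("EGFR", "PTGS2", "NR3C1", "MKI67", "TOP2A", "FN1")))
  filler <- sprintf("PANEL%03d", seq_len(339 - length(named)))
  c(named, filler)
}

#' Default per-cluster per-gene expression model
#'
#' Negative-binomial means per cluster and gene: a low baseline everywhere,
#' marker genes boosted per cluster, chemokines/alarmins expressed at a
#' modest rate by the stromal producer clusters (basal 1, endothelial 2,
#' goblet, fibroblast, serous), and filler genes given small round-robin
#' cluster preferences so every cluster has structure. Baselines are free
#' parameters of the simulator (the study reports no per-cluster rates) and
#' are set so the median per-cell total is of the order of 30 transcripts.
#'
#' @param cluster_names cluster names (rows).
#' @param panel gene names (columns).
#' @param baseline baseline NB mean per gene (default 0.04).
#' @param marker_mean NB mean of a cluster's marker genes (default 2).
#' @param producer_mean NB mean of chemokines/alarmins in producer clusters
#'   (default 0.3).
#' @param dispersion NB size parameter, shared (default 2).
#' @return list with `mu` (matrix clusters x genes) and `size`.
#' @export
default_expression_model <- function(cluster_names, panel,
                                     baseline = 0.04, marker_mean = 2,
                                     producer_mean = 0.3, dispersion = 2) {
  mu <- matrix(baseline, nrow = length(cluster_names), ncol = length(panel),
               dimnames = list(cluster_names, panel))
  markers <- .marker_genes()
  for (cl in intersect(cluster_names, names(markers))) {
    g <- intersect(markers[[cl]], panel)
    mu[cl, g] <- marker_mean
  }
  producers <- intersect(c("BC1", "EnC2", "goblet", "fibroblast",
                           "serous1", "serous2"), cluster_names)
  mediators <- intersect(c(chemokine_genes(), alarmin_genes()), panel)
  if (length(producers) && length(mediators)) {
    mu[producers, mediators] <- producer_mean
  }
  if ("Tcell" %in% cluster_names && "CCL5" %in% panel) mu["Tcell", "CCL5"] <- 2
  ## round-robin filler preferences keep non-marker genes cluster-structured
  filler <- grep("^PANEL", panel, value = TRUE)
  if (length(filler)) {
    owner <- rep(seq_along(cluster_names), length.out = length(filler))
    mu[cbind(owner, match(filler, panel))] <- 0.4
  }
  list(mu = mu, size = dispersion)
}

#' Hub specification
#'
#' @param n_hubs hubs planted per tissue section (default 3).
#' @param radius_um hub radius (default 40).
#' @param genes genes boosted inside hubs (default chemokines + alarmins).
#' @param multiplier expression multiplier inside the hub (default 5).
#' @param placement niche in which hub centers are drawn (default
#'   `"epithelial"`: hubs sit just inside the epithelial band).
#' @return a `hub_spec` list.
#' @export
hub_spec <- function(n_hubs = 3, radius_um = 40,
                     genes = c(chemokine_genes(), alarmin_genes()),
                     multiplier = 5, placement = "epithelial") {
  if (radius_um <= 0) abort_config("hub radius must be > 0")
  if (n_hubs < 0) abort_config("hub count must be >= 0")
  structure(list(n_hubs = n_hubs, radius_um = radius_um, genes = genes,
                 multiplier = multiplier, placement = placement),
            class = "hub_spec")
}

#' Default condition effects
#'
#' Per-gene log2 fold changes by condition plus the spatial contraction
#' factor applied to disease-condition cell placement around hub anchors.
#' The disease defaults emulate the reported directions: chemokines and
#' alarmins reduced (except CXCL12 unchanged and CXCL17 increased), MUC5B
#' strongly increased, APOD increased, CPA3 reduced, and cell displacements
#' contracted toward hub anchors by 0.7.
#'
#' @param panel gene names.
#' @param conditions condition names; the first is the reference.
#' @param contraction named contraction factors in (0, 1]; defaults to 1 for
#'   the reference and 0.7 for every other condition.
#' @return list with `log2fc` (genes x conditions matrix) and `contraction`.
#' @export
default_condition_effects <- function(panel,
                                      conditions = c("healthy", "asthma"),
                                      contraction = NULL) {
  log2fc <- matrix(0, nrow = length(panel), ncol = length(conditions),
                   dimnames = list(panel, conditions))
  if (length(conditions) > 1) {
    disease <- conditions[-1]
    down <- intersect(setdiff(c(chemokine_genes(), alarmin_genes()),
                              c("CXCL12", "CXCL17")), panel)
    log2fc[down, disease] <- -1
    if ("CXCL17" %in% panel) log2fc["CXCL17", disease] <- 1
    if ("MUC5B" %in% panel) log2fc["MUC5B", disease] <- log2(4.4)
    if ("APOD" %in% panel) log2fc["APOD", disease] <- log2(2.5)
    if ("CPA3" %in% panel) log2fc["CPA3", disease] <- log2(0.45)
  }
  if (is.null(contraction)) {
    contraction <- stats::setNames(c(1, rep(0.7, length(conditions) - 1L)),
                                   conditions)
  }
  list(log2fc = log2fc, contraction = contraction)
}

#' Tissue generator configuration
#'
#' Bundles geometry, cluster catalogue, panel, expression model, hub
#' specification, condition effects, sampling sizes and noise parameters.
#' Defaults describe the emulated study conditions; see
#' `vignette("airwayhubs-methods")` for the rationale behind each value.
#'
#' @param width_um tissue section width (default 600).
#' @param niches a [region_set()] of niche polygons (must not overlap).
#' @param clusters cluster catalogue data frame (`name`, `niche`, `weight`).
#' @param panel gene panel.
#' @param expression expression model from [default_expression_model()].
#' @param hubs a [hub_spec()].
#' @param conditions condition names (first = reference).
#' @param condition_effects from [default_condition_effects()].
#' @param n_cells_per_donor cells per donor section (default 2000).
#' @param donors_per_condition donors per condition (default 4).
#' @param qv_low_fraction fraction of transcripts drawn from the low-quality
#'   mode (default 0.05).
#' @param qv_modes,qv_sds means/s.d. of the high (>= 30) and low (< 20)
#'   quality-value modes.
#' @param transcript_jitter_um isotropic s.d. of molecule placement around
#'   the cell centroid (default 3).
#' @param donor_sigma s.d. of the per-donor log-normal factor on gene means
#'   (default 0.1).
#' @param unassigned_fraction fraction of transcripts left unassigned to any
#'   cell (default 0.02).
#' @param section_gap_um spacing between donor sections on the virtual slide
#'   (default 200; keeps sections farther apart than any neighbor window).
#' @return a validated `tissue_config`.
#' @export
tissue_config <- function(width_um = 600,
                          niches = default_niche_regions(width_um),
                          clusters = default_cluster_catalogue(),
                          panel = default_panel(),
                          expression = default_expression_model(clusters$name, panel),
                          hubs = hub_spec(),
                          conditions = c("healthy", "asthma"),
                          condition_effects = default_condition_effects(panel, conditions),
                          n_cells_per_donor = 2000,
                          donors_per_condition = 4,
                          qv_low_fraction = 0.05,
                          qv_modes = c(high = 35, low = 12),
                          qv_sds = c(high = 3, low = 3),
                          transcript_jitter_um = 3,
                          donor_sigma = 0.1,
                          unassigned_fraction = 0.02,
                          section_gap_um = 200) {
  if (!is.data.frame(clusters) || nrow(clusters) == 0) {
    abort_config("cluster catalogue is empty")
  }
  stopifnot(all(c("name", "niche", "weight") %in% names(clusters)))
  if (any(!is.finite(clusters$weight)) || any(clusters$weight <= 0)) {
    abort_config("abundance weights must be positive and finite")
  }
  stopifnot(inherits(niches, "region_set"), inherits(hubs, "hub_spec"))
  nm <- names(niches$polygons)
  if (length(nm) > 1) {
    for (i in seq_len(length(nm) - 1L)) {
      for (j in (i + 1L):length(nm)) {
        if (.polygons_overlap(niches$polygons[[i]], niches$polygons[[j]])) {
          abort_config(sprintf("niche polygons '%s' and '%s' overlap",
                               nm[i], nm[j]))
        }
      }
    }
  }
  bad_niche <- setdiff(unique(clusters$niche), c(nm, "any"))
  if (length(bad_niche)) {
    abort_config(sprintf("cluster placement niche '%s' has no polygon",
                         bad_niche[1]))
  }
  stopifnot(is.matrix(expression$mu),
            identical(rownames(expression$mu), clusters$name),
            identical(colnames(expression$mu), panel))
  if (any(expression$size <= 0)) abort_config("NB dispersion must be > 0")
  if (any(expression$mu < 0)) abort_config("NB means must be >= 0")
  cf <- condition_effects$contraction
  if (!all(conditions %in% names(cf))) {
    abort_config("contraction must be named per condition")
  }
  if (any(cf <= 0 | cf > 1)) abort_config("contraction factor must be in (0, 1]")
  stopifnot(identical(rownames(condition_effects$log2fc), panel),
            all(conditions %in% colnames(condition_effects$log2fc)))
  if (!is_count(n_cells_per_donor) || !is_count(donors_per_condition)) {
    abort_config("cell and donor counts must be non-negative integers")
  }
  stopifnot(qv_low_fraction >= 0, qv_low_fraction <= 1,
            transcript_jitter_um >= 0, donor_sigma >= 0,
            unassigned_fraction >= 0, unassigned_fraction < 1)
  structure(list(
    width_um = width_um, niches = niches, clusters = clusters, panel = panel,
    expression = expression, hubs = hubs, conditions = conditions,
    condition_effects = condition_effects,
    n_cells_per_donor = n_cells_per_donor,
    donors_per_condition = donors_per_condition,
    qv_low_fraction = qv_low_fraction, qv_modes = qv_modes, qv_sds = qv_sds,
    transcript_jitter_um = transcript_jitter_um, donor_sigma = donor_sigma,
    unassigned_fraction = unassigned_fraction,
    section_gap_um = section_gap_um
  ), class = "tissue_config")
}

#' @export
print.tissue_config <- function(x, ...) {
  cat(sprintf(
    "tissue_config: %d clusters, %d genes, %d x %d cells (donors x per-donor), conditions: %s\n",
    nrow(x$clusters), length(x$panel),
    x$donors_per_condition * length(x$conditions), x$n_cells_per_donor,
    paste(x$conditions, collapse = ", ")))
  invisible(x)
}
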