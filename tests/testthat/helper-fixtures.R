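## Shared fixtures and independent oracles. Oracles are deliberately written
## with different algorithms than the package implementations they check.

cm_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  airwayhubs:::new_count_matrix(Matrix::Matrix(m, sparse = TRUE))
}

toy_cells <- function(x, y, cluster, condition = "healthy",
                      niche = "unassigned") {
  n <- length(x)
  data.frame(cell_id = sprintf("c%04d", seq_len(n)), x_um = x, y_um = y,
             cluster_label = rep_len(cluster, n),
             donor_id = "D1", condition = rep_len(condition, n),
             niche_label = rep_len(niche, n), stringsAsFactors = FALSE)
}

## O(n^2) nearest-neighbor oracle via the full distance matrix.
nn_oracle <- function(ax, ay, bx, by, self = NULL) {
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  if (!is.null(self)) {
    for (i in seq_along(ax)) if (!is.na(self[i])) d[i, self[i]] <- Inf
  }
  apply(d, 1, min)
}

range_count_oracle <- function(ax, ay, bx, by, R, self = NULL) {
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  if (!is.null(self)) {
    for (i in seq_along(ax)) if (!is.na(self[i])) d[i, self[i]] <- Inf
  }
  apply(d, 1, function(v) sum(v <= R))
}

## Winding-number point-in-polygon oracle (angle summation), independent of
## the crossing-number implementation. Not reliable exactly on the boundary.
winding_oracle <- function(px, py, poly) {
  vapply(seq_along(px), function(i) {
    dx <- poly[, 1] - px[i]; dy <- poly[, 2] - py[i]
    a <- atan2(dy, dx)
    da <- diff(c(a, a[1]))
    da <- ifelse(da > pi, da - 2 * pi, ifelse(da < -pi, da + 2 * pi, da))
    abs(sum(da)) > pi
  }, logical(1))
}

## Exact two-sided Mann-Whitney P by enumeration of all group assignments.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

## Brute-force running-sum enrichment oracle (explicit position loop).
es_oracle <- function(profile, signature, alpha = 0.25) {
  genes <- names(profile)
  ord <- order(-profile, genes)
  n <- length(profile)
  m <- sum(genes %in% signature)
  denom <- sum(((n:1)[genes[ord] %in% signature])^alpha)
  run_in <- 0; run_out <- 0; score <- 0
  for (i in seq_len(n)) {
    g <- genes[ord][i]
    if (g %in% signature) run_in <- run_in + (n - i + 1)^alpha / denom
    else run_out <- run_out + 1 / (n - m)
    score <- score + (run_in - run_out)
  }
  score
}

## Lean generator configs used by recovery simulations. Parameters state the
## simulated study conditions for each check and are fixed up front.
single_cluster_config <- function(n_cells = 500, hub_genes = c("CXCL8", "IL33"),
                                  n_hubs = 1, multiplier = 5, radius = 40) {
  panel <- c(hub_genes, sprintf("G%02d", 1:18))
  clusters <- data.frame(name = "epi", niche = "any", weight = 1,
                         stringsAsFactors = FALSE)
  mu <- matrix(0.5, 1, length(panel), dimnames = list("epi", panel))
  tissue_config(
    width_um = 400,
    niches = region_set(list(epithelial = airwayhubs:::rect_poly(0, 0, 400, 300))),
    clusters = clusters, panel = panel,
    expression = list(mu = mu, size = 2),
    hubs = hub_spec(n_hubs = n_hubs, radius_um = radius, genes = hub_genes,
                    multiplier = multiplier, placement = "epithelial"),
    conditions = "healthy",
    condition_effects = default_condition_effects(panel, "healthy"),
    n_cells_per_donor = n_cells, donors_per_condition = 1,
    unassigned_fraction = 0, qv_low_fraction = 0)
}

contraction_config <- function(n_cells = 2000, contraction = 0.7) {
  panel <- c("G1", "G2")
  clusters <- data.frame(name = c("A", "B"), niche = "any",
                         weight = c(0.5, 0.5), stringsAsFactors = FALSE)
  mu <- matrix(0.01, 2, 2, dimnames = list(c("A", "B"), panel))
  tissue_config(
    width_um = 500,
    niches = region_set(list(epithelial = airwayhubs:::rect_poly(0, 0, 500, 500))),
    clusters = clusters, panel = panel,
    expression = list(mu = mu, size = 2),
    hubs = hub_spec(n_hubs = 1, radius_um = 40, genes = "G1",
                    multiplier = 1, placement = "epithelial"),
    conditions = c("healthy", "asthma"),
    condition_effects = default_condition_effects(
      panel, c("healthy", "asthma"),
      contraction = c(healthy = 1, asthma = contraction)),
    n_cells_per_donor = n_cells, donors_per_condition = 1,
    unassigned_fraction = 0, qv_low_fraction = 0)
}

knockdown_config <- function(n_cells = 500, knockdown = 0.2) {
  panel <- c("KIT", "PDGFRA", "VWF", sprintf("G%02d", 1:12))
  clusters <- data.frame(name = c("mast", "EnC"), niche = "any",
                         weight = c(0.3, 0.7), stringsAsFactors = FALSE)
  mu <- matrix(0.3, 2, length(panel), dimnames = list(c("mast", "EnC"), panel))
  mu["mast", c("KIT", "PDGFRA")] <- 2
  mu["EnC", "VWF"] <- 2
  eff <- default_condition_effects(panel, c("placebo", "imatinib"),
                                   contraction = c(placebo = 1, imatinib = 1))
  eff$log2fc[c("KIT", "PDGFRA"), "imatinib"] <- log2(knockdown)
  tissue_config(
    width_um = 400,
    niches = region_set(list(epithelial = airwayhubs:::rect_poly(0, 0, 400, 400))),
    clusters = clusters, panel = panel,
    expression = list(mu = mu, size = 2),
    hubs = hub_spec(n_hubs = 0, radius_um = 40, genes = "KIT", multiplier = 1),
    conditions = c("placebo", "imatinib"),
    condition_effects = eff,
    n_cells_per_donor = n_cells, donors_per_condition = 1,
    unassigned_fraction = 0, qv_low_fraction = 0)
}

## Tiny hand-built GeoMx experiment: constant negative probes fix the LOQ.
toy_geomx <- function(counts, neg_level = 100, n_roi = ncol(counts),
                      raw_floor = 5000) {
  neg <- matrix(neg_level, 2, n_roi,
                dimnames = list(c("NegProbe01", "NegProbe02"), colnames(counts)))
  all <- rbind(counts, neg)
  meta <- data.frame(roi_id = colnames(counts),
                     region = rep_len(airwayhubs:::GEOMX_REGIONS, n_roi),
                     pathology = rep_len(airwayhubs:::GEOMX_PATHOLOGY, n_roi),
                     donor = "D1", stringsAsFactors = FALSE)
  geomx_experiment(all, startsWith(rownames(all), "NegProbe"), meta,
                   raw_floor = raw_floor)
}
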