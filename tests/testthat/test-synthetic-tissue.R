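test_that("configuration invariants are enforced", {
  expect_error(tissue_config(clusters = data.frame()), "catalogue is empty")

  bad_w <- default_cluster_catalogue()
  bad_w$weight[1] <- -1
  expect_error(tissue_config(clusters = bad_w), "positive and finite")

  overlapping <- region_set(list(
    epithelial = airwayhubs:::rect_poly(0, 0, 100, 100),
    mucous_gland = airwayhubs:::rect_poly(50, 50, 150, 150)))
  expect_error(
    tissue_config(niches = overlapping,
                  clusters = data.frame(name = "a", niche = "any", weight = 1),
                  panel = c("G1"),
                  expression = list(mu = matrix(1, 1, 1, dimnames = list("a", "G1")),
                                    size = 2),
                  condition_effects = default_condition_effects("G1")),
    "'epithelial' and 'mucous_gland' overlap")

  ## adjacent bands sharing an edge are not an overlap
  expect_s3_class(tissue_config(), "tissue_config")

  expect_error(hub_spec(radius_um = 0), "radius")
  eff <- default_condition_effects(default_panel(),
                                   contraction = c(healthy = 1, asthma = 1.2))
  expect_error(tissue_config(condition_effects = eff), "\\(0, 1\\]")
  expect_error(
    tissue_config(expression = within(default_expression_model(
      default_cluster_catalogue()$name, default_panel()), size <- 0)),
    "dispersion")
})

test_that("zero cells per donor yields empty tables and truth without hubs", {
  cfg <- single_cluster_config(n_cells = 0)
  g <- generate_tissue(cfg, seed = 1)
  expect_equal(nrow(g$cells), 0)
  expect_equal(nrow(g$transcripts), 0)
  expect_equal(nrow(g$truth$hubs), 0)
})

test_that("generation is bit-reproducible for equal config and seed", {
  cfg <- single_cluster_config(n_cells = 80)
  a <- generate_tissue(cfg, seed = 123)
  b <- generate_tissue(cfg, seed = 123)
  expect_identical(a$cells, b$cells)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth$hubs, b$truth$hubs)
  c_ <- generate_tissue(cfg, seed = 124)
  expect_false(identical(a$cells, c_$cells))
})

test_that("hub multiplier is realized in within-hub expression", {
  ## mean within-hub vs outside-hub per-cell count of the hub genes over
  ## 50 seeds; the generator's own stated rate is the multiplier (5)
  cfg <- single_cluster_config(n_cells = 400, n_hubs = 1, radius = 60)
  in_tot <- 0; in_n <- 0; out_tot <- 0; out_n <- 0
  for (s in 1:50) {
    g <- generate_tissue(cfg, seed = s)
    per_cell <- table(factor(
      g$transcripts$cell_id[g$transcripts$gene %in% g$truth$hub_genes],
      levels = g$cells$cell_id))
    d2 <- (g$cells$x_um - g$truth$hubs$x_um[1])^2 +
      (g$cells$y_um - g$truth$hubs$y_um[1])^2
    inside <- d2 <= g$truth$hubs$radius_um[1]^2
    in_tot <- in_tot + sum(per_cell[inside]); in_n <- in_n + sum(inside)
    out_tot <- out_tot + sum(per_cell[!inside]); out_n <- out_n + sum(!inside)
  }
  ratio <- (in_tot / in_n) / (out_tot / out_n)
  expect_gt(ratio, 5 * 0.9)
  expect_lt(ratio, 5 * 1.1)
})

test_that("realized cluster proportions match configured weights", {
  cfg <- tissue_config(n_cells_per_donor = 1500, donors_per_condition = 1,
                       conditions = "healthy",
                       condition_effects = default_condition_effects(
                         default_panel(), "healthy"))
  g <- generate_tissue(cfg, seed = 17)
  w <- cfg$clusters$weight / sum(cfg$clusters$weight)
  names(w) <- cfg$clusters$name
  n <- nrow(g$cells)
  p_hat <- table(factor(g$cells$cluster_label, levels = names(w))) / n
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(as.vector(p_hat) - w) <= 3 * se))
})

test_that("cells respect their placement niches and sections stay apart", {
  cfg <- tissue_config(n_cells_per_donor = 400, donors_per_condition = 2)
  g <- generate_tissue(cfg, seed = 8)
  epi <- merge(g$cells, cfg$clusters, by.x = "cluster_label", by.y = "name")
  placed <- epi[epi$niche != "any", ]
  expect_true(all(placed$niche_label[placed$condition == "healthy"] ==
                    placed$niche[placed$condition == "healthy"]))
  ## sections are disjoint along x
  sec <- split(g$cells$x_um, g$cells$donor_id)
  rng <- t(vapply(sec, range, numeric(2)))
  rng <- rng[order(rng[, 1]), ]
  expect_true(all(rng[-1, 1] > rng[-nrow(rng), 2]))
})

test_that("quality values fall below threshold at the configured rate", {
  cfg <- single_cluster_config(n_cells = 400)
  cfg$qv_low_fraction <- 0.05
  g <- generate_tissue(cfg, seed = 19)
  frac_low <- mean(g$transcripts$qv < 20)
  expect_gt(frac_low, 0.03)
  expect_lt(frac_low, 0.07)
})

test_that("disease-condition contraction scales pairwise distances", {
  cfg <- contraction_config(n_cells = 2000, contraction = 0.7)
  ratios <- vapply(1:3, function(s) {
    g <- generate_tissue(cfg, seed = 200 + s)
    h <- g$cells[g$cells$condition == "healthy", ]
    a <- g$cells[g$cells$condition == "asthma", ]
    median(shortest_distances(a, "A", "B")) /
      median(shortest_distances(h, "A", "B"))
  }, numeric(1))
  expect_true(all(abs(ratios - 0.7) / 0.7 <= 0.15))
})

test_that("generated outputs survive the write/read round trip", {
  g <- generate_tissue(single_cluster_config(n_cells = 40), seed = 4)
  d <- withr::local_tempdir()
  write_cells(g$cells, file.path(d, "cells.csv"))
  write_transcripts(g$transcripts, file.path(d, "tx.csv"))
  write_truth(g$truth, file.path(d, "truth.json"))
  back_cells <- read_cells(file.path(d, "cells.csv"))
  expect_equal(back_cells$cell_id, g$cells$cell_id)
  expect_equal(back_cells$x_um, g$cells$x_um, tolerance = 1e-12)
  tj <- jsonlite::fromJSON(file.path(d, "truth.json"))
  expect_equal(nrow(tj$hubs), nrow(g$truth$hubs))
})
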