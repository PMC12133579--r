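test_that("LOQ follows the geometric closed form", {
  ## zero variance: LOQ equals the common probe level
  e1 <- toy_geomx(matrix(50, 1, 4, dimnames = list("T1", sprintf("R%d", 1:4))),
                  neg_level = 100)
  expect_equal(unname(loq(e1)), rep(100, 4))

  ## two probes at 1 and e^2: logs {0, 2}, sd = sqrt(2)
  counts <- matrix(c(1, exp(2), 10), 3, 1,
                   dimnames = list(c("NegProbe01", "NegProbe02", "T1"), "R1"))
  meta <- data.frame(roi_id = "R1", region = "epithelium",
                     pathology = "healthy", donor = "D1")
  e2 <- geomx_experiment(counts, c(TRUE, TRUE, FALSE), meta)
  expect_equal(unname(loq(e2)), exp(1 + 2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(loq(e2)), 45.99, tolerance = 1e-4)

  ## scaling all probes by 10 scales the LOQ by 10
  counts10 <- counts; counts10[1:2, ] <- counts[1:2, ] * 10
  e3 <- geomx_experiment(counts10, c(TRUE, TRUE, FALSE), meta)
  expect_equal(unname(loq(e3)), 10 * unname(loq(e2)), tolerance = 1e-12)

  ## zero probes are rejected in log space
  counts0 <- counts; counts0[1, ] <- 0
  e4 <- geomx_experiment(counts0, c(TRUE, TRUE, FALSE), meta)
  expect_error(loq(e4), "log undefined")
  expect_equal(unname(loq(e4, space = "arithmetic")),
               mean(c(0, exp(2))) + 2 * sd(c(0, exp(2))))

  expect_error(
    geomx_experiment(counts[c(1, 3), , drop = FALSE], c(TRUE, FALSE), meta),
    "2 negative probes")
})

test_that("target filtering applies the consistently-below rule", {
  ## LOQ = 100 everywhere (constant negative probes)
  counts <- rbind(
    detected_once = c(150, rep(50, 9)),     # above LOQ in 1 of 10 ROIs
    below_small   = rep(99, 10),            # below everywhere, 990 reads
    below_big     = rep(999, 10))           # below a high LOQ, 9990 reads
  colnames(counts) <- sprintf("R%02d", 1:10)
  e <- toy_geomx(counts, neg_level = 100)
  f <- filter_targets(e)
  expect_true("detected_once" %in% rownames(f$counts))
  expect_false("below_small" %in% rownames(f$counts))
  expect_true("below_big" %in% rownames(f$counts))   # above LOQ=100 everywhere
  expect_false(any(startsWith(rownames(f$counts), "NegProbe")))

  e2 <- toy_geomx(counts, neg_level = 10000)
  f2 <- filter_targets(e2)           # all targets below LOQ everywhere
  expect_equal(rownames(f2$counts), "below_big")  # 9990 reads clear the floor
  f2or <- filter_targets(e2, rule = "or")
  expect_equal(nrow(f2or$counts), 0)

  ## lowering the floor never removes a previously retained target
  e3 <- toy_geomx(counts, neg_level = 10000, raw_floor = 500)
  kept_low <- rownames(filter_targets(e3)$counts)
  expect_true(all(rownames(f2$counts) %in% kept_low))
})

test_that("Q3 normalization equalizes upper quartiles and is idempotent", {
  set.seed(21)
  base <- matrix(rlnorm(40 * 3, log(100), 0.5), 40, 3,
                 dimnames = list(sprintf("T%02d", 1:40), c("R1", "R2", "R3")))
  base[, 2] <- base[, 2] * 7
  e <- toy_geomx(base)
  f <- filter_targets(e)
  qn <- q3_normalize(f)
  q3 <- apply(qn$normalized, 2, quantile, 0.75, names = FALSE)
  expect_lt(diff(range(q3)) / mean(q3), 1e-9)
  expect_equal(mean(q3), airwayhubs:::geomean(
    apply(f$counts, 2, quantile, 0.75, names = FALSE)), tolerance = 1e-9)

  qn2 <- q3_normalize(qn)
  expect_equal(qn2$normalized, qn$normalized, tolerance = 1e-12)

  ## hand computation on two ROIs with Q3s 10 and 1000 (probes filtered out
  ## first; a low constant probe keeps every target detected)
  two <- matrix(c(rep(10, 4), rep(1000, 4)), 4, 2,
                dimnames = list(sprintf("T%d", 1:4), c("Ra", "Rb")))
  qn3 <- q3_normalize(filter_targets(toy_geomx(two, neg_level = 0.5)))
  expect_equal(unname(qn3$q3_factors), c(10, 0.1))
  expect_equal(unname(apply(qn3$normalized, 2, quantile, 0.75)), c(100, 100))

  ## single ROI: scale factor 1
  one <- matrix(1:4, 4, 1, dimnames = list(sprintf("T%d", 1:4), "R1"))
  qn1 <- q3_normalize(filter_targets(toy_geomx(one, n_roi = 1, neg_level = 0.5)))
  expect_equal(qn1$normalized[, 1], one[, 1])
})

test_that("enrichment scores match the running-sum oracle and rank logic", {
  set.seed(14)
  profile <- setNames(sample(seq(10, 100, by = 10)), sprintf("G%02d", 1:10))
  sig_top <- names(sort(profile, decreasing = TRUE))[1:3]
  sig_bot <- names(sort(profile))[1:3]

  for (sig in list(sig_top, sig_bot, sample(names(profile), 4))) {
    expect_equal(enrichment_score(profile, sig), es_oracle(profile, sig),
                 tolerance = 1e-9)
  }
  expect_gt(enrichment_score(profile, sig_top), 0)
  expect_lt(enrichment_score(profile, sig_bot), 0)

  ## the top-ranked signature dominates every other set of its size
  best <- enrichment_score(profile, sig_top)
  combos <- combn(names(profile), 3)
  others <- apply(combos, 2, function(s) enrichment_score(profile, s))
  expect_true(all(best >= others - 1e-12))

  ## rank-based: invariant under strictly monotone transforms
  expect_equal(enrichment_score(profile, sig_top),
               enrichment_score(sqrt(profile) + 2, sig_top))
  expect_error(enrichment_score(profile, "ZZZ"), "no signature gene")
})

test_that("group comparison detects planted pathology shifts", {
  e <- generate_geomx(geomx_config(targets = sprintf("T%02d", 1:30),
                                   rois_per_group = 3), seed = 2)$experiment
  f <- q3_normalize(filter_targets(e))
  vals <- setNames(f$normalized[1, ], colnames(f$normalized))
  res <- group_compare(vals, f, region = "epithelium", posthoc = "dunnett")
  expect_true(all(res$posthoc$p > 0 & res$posthoc$p <= 1))

  ## power simulation: 2x mean shift at n=8 ROIs/group, CV 20%
  hits <- 0
  for (s in 1:100) {
    set.seed(400 + s)
    y <- c(rnorm(8, 100, 20), rnorm(8, 200, 40), rnorm(8, 100, 20))
    g <- factor(rep(c("healthy", "mild", "severe"), each = 8),
                levels = c("healthy", "mild", "severe"))
    res <- anova_posthoc(y, g, posthoc = "dunnett")
    p_mild <- res$posthoc$p[grepl("^mild", res$posthoc$comparison)]
    if (p_mild < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)

  ## identical groups carry no signal
  res0 <- anova_posthoc(rep(5, 12), rep(c("healthy", "mild"), each = 6),
                        posthoc = "dunnett")
  expect_equal(res0$omnibus_p, 1)
})

test_that("synthetic GeoMx experiments are reproducible and recoverable", {
  cfg <- geomx_config(targets = sprintf("T%02d", 1:60), rois_per_group = 2)
  a <- generate_geomx(cfg, seed = 5)
  b <- generate_geomx(cfg, seed = 5)
  expect_identical(a$experiment$counts, b$experiment$counts)

  ## 0 ROIs: an empty experiment
  e0 <- generate_geomx(geomx_config(targets = c("T1", "T2"),
                                    rois_per_group = 0), seed = 1)
  expect_equal(ncol(e0$experiment$counts), 0)

  expect_error(geomx_config(n_neg_probes = 1), "negative probes")

  ## planted above-LOQ targets recovered in >= 90% of seeds
  rates <- vapply(1:100, function(s) {
    gx <- generate_geomx(cfg, seed = s)
    det <- sweep(gx$experiment$counts[!gx$experiment$is_negative, ], 2,
                 loq(gx$experiment), ">")
    rec <- rownames(det)[rowMeans(det) > 0.5]
    mean(gx$truth$planted_above_loq %in% rec)
  }, numeric(1))
  expect_gte(mean(rates >= 0.9), 0.9)

  ## TSV round trip through the reader
  gx <- generate_geomx(cfg, seed = 9)
  d <- withr::local_tempdir()
  counts_df <- data.frame(target = rownames(gx$experiment$counts),
                          gx$experiment$counts, check.names = FALSE)
  write.table(counts_df, file.path(d, "counts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(gx$experiment$roi_meta, file.path(d, "meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  back <- read_geomx(file.path(d, "counts.tsv"), file.path(d, "meta.tsv"))
  expect_equal(back$counts, gx$experiment$counts)
  expect_equal(back$is_negative, gx$experiment$is_negative)
})
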