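toy_nm <- function(vals) {
  structure(list(values = vals,
                 gene_ids = sprintf("g%03d", seq_len(nrow(vals))),
                 barcodes = sprintf("c%03d", seq_len(ncol(vals))),
                 size_factors = rep(1, ncol(vals))),
            class = "NormalizedMatrix")
}

test_that("detection fractions count strictly positive values per group", {
  v <- matrix(0, 1, 40)
  v[1, 1:4] <- 2  # 4 of 20 in-group cells
  nm <- toy_nm(v)
  df <- detection_fractions(nm, 1, 1:20, 21:40)
  expect_equal(unname(df), c(0.20, 0))
  all_on <- toy_nm(matrix(1, 1, 40))
  expect_equal(unname(detection_fractions(all_on, 1, 1:20, 21:40)), c(1, 1))
  expect_error(detection_fractions(nm, 1, 1:20, 15:40), "disjoint")
})

test_that("log2 fold change is antisymmetric and hits constructed ratios", {
  big <- matrix(log1p(c(rep(2000, 10), rep(1000, 10))), 1, 20)
  nm <- toy_nm(big)
  lfc <- log2_fold_change(nm, 1, 1:10, 11:20)
  expect_equal(lfc, 1, tolerance = 0.01)
  expect_equal(log2_fold_change(nm, 1, 11:20, 1:10), -lfc, tolerance = 1e-10)
  same <- toy_nm(matrix(log1p(5), 1, 20))
  expect_equal(log2_fold_change(same, 1, 1:10, 11:20), 0)
})

test_that("hurdle statistic matches brute-force ML fits on a 20-cell case", {
  set.seed(31)
  group <- factor(rep(c("a", "b"), each = 10))
  vals <- c(rnorm(10, 1.0, 0.5), rnorm(10, 1.6, 0.5))
  vals[sample(20, 6)] <- 0
  ht <- hurdle_test(vals, group)
  expect_equal(ht$statistic, hurdle_oracle_stat(vals, group),
               tolerance = 1e-6)
  expect_equal(ht$df, 2)
  # a detection-only gene exercises the discrete part alone
  det_only <- c(rep(1.5, 9), 0, rep(0, 9), 1.5)
  ht2 <- hurdle_test(det_only, group, min_detected = 30)
  expect_equal(ht2$continuous_stat, 0)
  # closed-form binomial LR for a 9/1 vs 1/9 detection split
  lr <- 2 * (2 * (9 * log(0.9) + log(0.1)) - 20 * log(0.5))
  expect_equal(ht2$statistic, lr, tolerance = 1e-6)
  expect_lt(ht2$p_value, 0.01)
})

test_that("a strong detection difference is overwhelmingly significant", {
  set.seed(32)
  group <- factor(rep(c("a", "b"), each = 100))
  vals <- c(ifelse(runif(100) < 0.9, rlnorm(100), 0),
            ifelse(runif(100) < 0.1, rlnorm(100), 0))
  ht <- hurdle_test(vals, group)
  expect_lt(ht$p_value, 1e-6)
})

test_that("complete separation falls back to the ridge path with a flag", {
  group <- factor(rep(c("a", "b"), each = 10))
  vals <- c(rnorm(10, 2, 0.3), rep(0, 10))  # detection perfectly separates
  ht <- hurdle_test(vals, group)
  expect_true(ht$flagged)
  expect_true(is.finite(ht$statistic))
  expect_lt(ht$p_value, 0.01)
})

test_that("identically distributed groups give near-uniform p-values", {
  set.seed(33)
  group <- factor(rep(c("a", "b"), each = 50))
  p <- replicate(200, {
    vals <- ifelse(runif(100) < 0.5, rlnorm(100), 0)
    hurdle_test(vals, group)$p_value
  })
  expect_gt(mean(p > 0.5), 0.35)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("marker screen applies the detection and fold-change gates", {
  set.seed(34)
  n <- 40  # 20 cells per cluster
  labels <- rep(c("k1", "k2"), each = 20)
  vals <- matrix(ifelse(runif(5 * n) < 0.5, rlnorm(5 * n), 0), 5, n)
  # gene 1: real marker of k1
  vals[1, ] <- c(ifelse(runif(20) < 0.9, rlnorm(20, 2), 0),
                 ifelse(runif(20) < 0.1, rlnorm(20), 0))
  # gene 2: huge fold change but pct_in 0.15 < 0.20 -> excluded
  vals[2, ] <- 0
  vals[2, 1:3] <- 50
  # gene 3: pct_out exactly 0.60 -> excluded (strict "less than")
  vals[3, ] <- 0
  vals[3, 1:20] <- rlnorm(20, 3)
  vals[3, 21:32] <- 0.01  # 12/20 = 0.60 detected outside
  res <- marker_screen(toy_nm(vals), labels)
  k1 <- res[res$cluster == "k1", ]
  expect_true("g001" %in% k1$gene)
  expect_false("g002" %in% k1$gene)
  expect_false("g003" %in% k1$gene)
  expect_error(marker_screen(toy_nm(vals), rep("k1", n)), "2 clusters")
})

test_that("marker screen recovers simulated markers", {
  ti <- small_transfer_inputs()
  sp <- small_domain_pair()
  labels <- sp$ref$truth$cells$label[match(ti$nm_s$barcodes,
                                           sp$ref$truth$cells$barcode)]
  res <- marker_screen(ti$nm_s, labels)
  hits <- unique(res$gene[res$adj_p < 0.05])
  markers <- sp$ref$truth$markers$gene_id
  markers <- markers[markers %in% ti$nm_s$gene_ids]
  expect_gte(mean(markers %in% hits), 0.95)
})

test_that("condition contrast bookkeeping swaps sign with the coding", {
  cfg <- simulation_config(n_genes = 500, cells_per_class = 300,
                           frac_de_genes = 0.1, effect_log2fc = 1,
                           seed = 35)
  tg <- simulate_two_group(cfg)
  nm <- normalize_counts(filter_genes(tg$counts, 5))
  cond <- factor(tg$cells$condition, c("vehicle", "treated"))
  res <- condition_contrast(nm, cond)
  flipped <- condition_contrast(nm, stats::relevel(cond, "treated"))
  expect_setequal(res$up, flipped$down)
  expect_setequal(res$down, flipped$up)
  # recovery of planted DE genes
  true_de <- tg$truth$genes$gene_id[tg$truth$genes$is_de]
  found <- c(res$up, res$down)
  jac <- length(intersect(found, true_de)) / length(union(found, true_de))
  expect_gte(jac, 0.7)
})

test_that("a full null contrast yields essentially no survivors", {
  cfg <- simulation_config(n_genes = 2000, cells_per_class = 60,
                           frac_de_genes = 0, seed = 36)
  tg <- simulate_two_group(cfg)
  nm <- normalize_counts(filter_genes(tg$counts, 5))
  cond <- factor(tg$cells$condition, c("vehicle", "treated"))
  res <- condition_contrast(nm, cond)
  expect_lte(length(res$up) + length(res$down), 1)
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(37)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone non-decreasing in sorted order, bounded by 1
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
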