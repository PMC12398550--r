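make_counts <- function(mat, prefix = "g") {
  count_matrix(mat, sprintf("%s%03d", prefix, seq_len(nrow(mat))),
               sprintf("c%03d", seq_len(ncol(mat))))
}

test_that("gene filter keeps genes detected in strictly more than the cut", {
  # gene 1 detected in exactly 10 cells, gene 2 in 11, gene 3 in all 20
  m <- matrix(0, 3, 20)
  m[1, 1:10] <- 1
  m[2, 1:11] <- 1
  m[3, ] <- 2
  f <- filter_genes(make_counts(m), 10)
  expect_identical(f$gene_ids, c("g002", "g003"))
  # threshold 0 keeps everything with any detection
  f0 <- filter_genes(make_counts(m), 0)
  expect_equal(nrow(f0$values), 3)
  expect_error(filter_genes(make_counts(m), 100), "every gene")
})

test_that("cell QC removes by the right criterion and spares clean cells", {
  set.seed(1)
  base <- matrix(rpois(50 * 60, 5), 50, 60)
  ids <- sprintf("g%03d", 1:50)
  ids[1] <- "MT-CO1"
  clean <- count_matrix(base, ids, sprintf("c%03d", 1:60))
  res <- filter_cells(clean, mad_multiplier = 3, max_mito_fraction = 0.2)
  expect_lte(mean(res$report$removed), 0.01)
  # one cell with 90% mito counts is removed, attributed to the mito rule
  dirty <- base
  dirty[, 1] <- 0
  dirty[1, 1] <- round(sum(base[, 2]) * 3)  # mito-dominated, similar depth
  dirty[2:10, 1] <- 5
  m2 <- count_matrix(dirty, ids, sprintf("c%03d", 1:60))
  res2 <- filter_cells(m2, mad_multiplier = 6, max_mito_fraction = 0.2)
  expect_true(res2$report$removed_mito[1])
  expect_false(res2$report$barcode[1] %in% res2$counts$barcodes)
  # huge MAD multiplier leaves only the mito criterion active
  res3 <- filter_cells(m2, mad_multiplier = 1e6, max_mito_fraction = 0.2)
  expect_true(all(!res3$report$removed_umi & !res3$report$removed_gene_count))
  expect_true(any(res3$report$removed_mito))
})

test_that("combined gene+cell QC is idempotent on its own output", {
  sp <- small_domain_pair()
  q1 <- qc_filter(sp$ref$counts, 10)
  q2 <- qc_filter(q1$counts, 10)
  expect_identical(q2$counts$gene_ids, q1$counts$gene_ids)
  expect_identical(q2$counts$barcodes, q1$counts$barcodes)
  expect_equal(q2$iterations, 1)
})

test_that("size factors are scale-equivariant with geometric mean 1", {
  base <- matrix(rpois(40 * 3, 10) + 1, 40, 3)
  same <- make_counts(cbind(base[, 1], base[, 1], base[, 1]))
  nm <- normalize_counts(same, min_ratio_genes = 5)
  expect_equal(nm$size_factors, rep(1, 3), tolerance = 1e-12)
  # doubling every count doubles the size factor
  doubled <- make_counts(cbind(base, base[, 1] * 2))
  nm2 <- normalize_counts(doubled, min_ratio_genes = 5)
  expect_equal(nm2$size_factors[4] / nm2$size_factors[1], 2,
               tolerance = 1e-10)
  expect_equal(exp(mean(log(nm2$size_factors))), 1, tolerance = 1e-12)
  # zero-count cell is an error
  z <- make_counts(cbind(base[, 1], 0))
  expect_error(normalize_counts(z), "zero-count")
})

test_that("normalisation shrinks the across-cell total variation", {
  sp <- small_domain_pair()
  m <- filter_genes(sp$ref$counts, 10)
  nm <- normalize_counts(m)
  raw_tot <- Matrix::colSums(m$values)
  norm_tot <- colSums(sweep(as.matrix(m$values), 2, nm$size_factors, "/"))
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(norm_tot), cv(raw_tot))
})

test_that("variable-gene ranking surfaces markers and honours n_top", {
  ti <- small_transfer_inputs()
  sp <- small_domain_pair()
  hvg <- select_variable_genes(ti$nm_s, 60)
  markers <- sp$ref$truth$markers$gene_id
  markers <- markers[markers %in% ti$nm_s$gene_ids]
  expect_gte(mean(markers %in% hvg), 0.9)
  # constant gene never selected
  vals <- rbind(ti$nm_s$values, 1)
  nm2 <- structure(list(values = vals,
                        gene_ids = c(ti$nm_s$gene_ids, "constant"),
                        barcodes = ti$nm_s$barcodes,
                        size_factors = ti$nm_s$size_factors),
                   class = "NormalizedMatrix")
  expect_false("constant" %in% select_variable_genes(nm2, nrow(vals) - 1))
  # n_top = gene count returns the identity set
  all_g <- select_variable_genes(ti$nm_s, length(ti$nm_s$gene_ids))
  expect_setequal(all_g, ti$nm_s$gene_ids)
})

test_that("PCA matches a dense eigendecomposition oracle and is stable", {
  set.seed(33)
  x <- matrix(rnorm(20 * 10), 10, 20)  # 10 genes x 20 cells
  nm <- structure(list(values = x, gene_ids = sprintf("g%02d", 1:10),
                       barcodes = sprintf("c%02d", 1:20),
                       size_factors = rep(1, 20)),
                  class = "NormalizedMatrix")
  emb <- run_pca(nm, nm$gene_ids, max_pcs = 10, min_pcs = 1)
  z <- scale(t(x))
  ev_oracle <- sort(eigen(stats::cov(z))$values, decreasing = TRUE)
  expect_equal(emb$explained_variance, ev_oracle[1:10], tolerance = 1e-8)
  # scores reproduce the centred data in the fitted basis
  expect_equal(emb$scores %*% t(emb$loadings), unclass(z)[, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated cell gets an identical embedding row
  x2 <- cbind(x, x[, 1])
  nm2 <- structure(list(values = x2, gene_ids = nm$gene_ids,
                        barcodes = c(nm$barcodes, "dup"),
                        size_factors = rep(1, 21)),
                   class = "NormalizedMatrix")
  emb2 <- run_pca(nm2, nm$gene_ids, max_pcs = 5, min_pcs = 1)
  expect_equal(emb2$scores[21, ], emb2$scores[1, ], tolerance = 1e-10)
  # rank-3 data has ~zero variance beyond PC3
  lowr <- matrix(rnorm(3 * 15), 15, 3) %*% matrix(rnorm(3 * 12), 3, 12)
  nm3 <- structure(list(values = t(lowr), gene_ids = sprintf("g%02d", 1:12),
                        barcodes = sprintf("c%02d", 1:15),
                        size_factors = rep(1, 15)),
                   class = "NormalizedMatrix")
  expect_warning(emb3 <- run_pca(nm3, nm3$gene_ids, max_pcs = 20,
                                 min_pcs = 1), "clipped")
  expect_lt(sum(emb3$explained_variance[4:10]),
            1e-10 * sum(emb3$explained_variance))
})

test_that("elbow rule matches its worked example and degenerate cases", {
  expect_equal(choose_elbow(c(10, 5, 1, 0.01, 0.009), min_pcs = 1), 3)
  expect_equal(choose_elbow(rep(1, 40), min_pcs = 1, max_pcs = 20), 20)
  expect_warning(k1 <- choose_elbow(5, min_pcs = 5), "shorter")
  expect_equal(k1, 1)
  expect_error(choose_elbow(c(1, 2, 3)), "non-increasing")
  # floor of 5 applies when the spectrum collapses early
  expect_equal(choose_elbow(c(10, 5, 1, 1e-9, 1e-9, 1e-9, 1e-9)), 5)
})

test_that("Louvain clustering recovers planted blobs and beats singletons", {
  set.seed(44)
  blobs <- rbind(matrix(rnorm(60 * 2, 0, 1), 60, 2),
                 matrix(rnorm(60 * 2, 10, 1), 60, 2))
  truth <- rep(1:2, each = 60)
  cl <- cluster_cells(blobs, k_neighbors = 30, resolution = 1, seed = 7)
  expect_equal(ari(cl$labels, truth), 1)
  expect_equal(length(unique(cl$labels)), 2)
  # modularity of the returned partition beats all-singletons
  g <- cl$graph
  singleton_mod <- igraph::modularity(g, seq_len(igraph::vcount(g)),
                                      weights = igraph::E(g)$weight)
  expect_gte(cl$modularity, singleton_mod)
  # resolution -> 0 collapses a connected cloud to one cluster
  one <- matrix(rnorm(80 * 2), 80, 2)
  cl0 <- cluster_cells(one, k_neighbors = 15, resolution = 1e-4, seed = 7)
  expect_equal(length(unique(cl0$labels)), 1)
  expect_gt(length(unique(cluster_cells(one, k_neighbors = 15,
                                        resolution = 1,
                                        seed = 7)$labels)), 1)
  # reproducible under a fixed seed
  cl2 <- cluster_cells(blobs, k_neighbors = 30, resolution = 1, seed = 7)
  expect_identical(cl$labels, cl2$labels)
})
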