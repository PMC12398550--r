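#' Remove genes detected in too few cells
#'
#' Retains exactly the genes detected (count > 0) in strictly more than
#' `min_cells_exclusive` cells; the default of 10 removes genes expressed in
#' ten or fewer cells.
#'
#' @param m a `CountMatrix`.
#' @param min_cells_exclusive exclusive lower bound on detecting cells.
#' @return Filtered `CountMatrix`.
#' @export
filter_genes <- function(m, min_cells_exclusive = 10L) {
  stopifnot(inherits(m, "CountMatrix"))
  n_detect <- Matrix::rowSums(m$values > 0)
  keep <- n_detect > min_cells_exclusive
  if (!any(keep)) stop("gene filter removed every gene")
  subset_count_matrix(m, genes = keep)
}

#' Remove outlier cells
#'
#' Cells are dropped when their log total UMI count or log detected-gene
#' count lies outside median +/- `mad_multiplier` * MAD (two-sided), or their
#' mitochondrial count fraction exceeds `max_mito_fraction` (one-sided).
#' Mitochondrial genes are identified by `mito_prefix` on the gene id (after
#' any species prefix).
#'
#' @param m a `CountMatrix`.
#' @param mad_multiplier MAD multiplier for the two-sided rules.
#' @param max_mito_fraction upper bound on the mitochondrial fraction.
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @param force proceed even if more than 90% of cells would be removed.
#' @return A list with `counts` (filtered `CountMatrix`) and `report`
#'   (data.frame: barcode, metrics, per-criterion removal flags).
#' @export
filter_cells <- function(m, mad_multiplier = 3, max_mito_fraction = 1,
                         mito_prefix = "MT-", force = FALSE) {
  stopifnot(inherits(m, "CountMatrix"))
  total <- Matrix::colSums(m$values)
  n_genes <- Matrix::colSums(m$values > 0)
  stripped <- sub("^(GRCh38_|mm10_)", "", m$gene_ids)
  mito <- startsWith(stripped, mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(m$values[mito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(m$values))
  out_mad <- function(x) {
    med <- stats::median(x); dev <- stats::mad(x)
    if (dev == 0) rep(FALSE, length(x))
    else x < med - mad_multiplier * dev | x > med + mad_multiplier * dev
  }
  rm_umi <- out_mad(log1p(total))
  rm_gene <- out_mad(log1p(n_genes))
  rm_mito <- mito_frac > max_mito_fraction
  removed <- rm_umi | rm_gene | rm_mito
  report <- data.frame(barcode = m$barcodes, total_umi = total,
                       n_genes = n_genes, mito_fraction = mito_frac,
                       removed_umi = rm_umi, removed_gene_count = rm_gene,
                       removed_mito = rm_mito, removed = removed,
                       stringsAsFactors = FALSE)
  if (mean(removed) > 0.9 && !force)
    stop("cell QC would remove ", round(100 * mean(removed)),
         "% of cells; pass force = TRUE to override")
  list(counts = subset_count_matrix(m, cells = !removed), report = report)
}

#' Combined gene/cell QC to a fixed point
#'
#' Alternates [filter_genes()] and [filter_cells()] until neither removes
#' anything (cell removal can push a gene below the detection cut and vice
#' versa), so the result is idempotent: re-applying the QC removes nothing.
#'
#' @inheritParams filter_genes
#' @inheritParams filter_cells
#' @param max_iter safety bound on the alternation.
#' @return A list with `counts` (QC'd `CountMatrix`), `report` (the final
#'   cell-QC report) and `iterations`.
#' @export
qc_filter <- function(m, min_cells_exclusive = 10L, mad_multiplier = 3,
                      max_mito_fraction = 1, mito_prefix = "MT-",
                      force = FALSE, max_iter = 10L) {
  report <- NULL
  for (it in seq_len(max_iter)) {
    before <- dim(m$values)
    m <- filter_genes(m, min_cells_exclusive)
    res <- filter_cells(m, mad_multiplier, max_mito_fraction, mito_prefix,
                        force)
    m <- res$counts
    report <- res$report
    if (identical(dim(m$values), before)) break
  }
  list(counts = m, report = report, iterations = it)
}

#' Size-factor normalisation to log expression
#'
#' Per-cell size factors by the median-ratio rule against the arithmetic mean
#' expression profile (ratios taken over genes detected in the cell), rescaled
#' to geometric mean 1; cells with too few usable genes fall back to
#' library-size factors. Values are `ln(count / size_factor + 1)`.
#'
#' @param m a `CountMatrix` that passed QC.
#' @param min_ratio_genes minimum detected genes for the median-ratio rule.
#' @return A list of class `NormalizedMatrix`: `values` (dense genes x cells
#'   log-expression matrix), `size_factors`, `gene_ids`, `barcodes`.
#' @export
normalize_counts <- function(m, min_ratio_genes = 50L) {
  stopifnot(inherits(m, "CountMatrix"))
  total <- Matrix::colSums(m$values)
  if (any(total == 0))
    stop("zero-count cell present (barcode ",
         m$barcodes[which(total == 0)[1]], "); run cell QC first")
  ref <- Matrix::rowMeans(m$values)
  dense <- as.matrix(m$values)
  sf <- vapply(seq_len(ncol(dense)), function(j) {
    x <- dense[, j]
    use <- x > 0 & ref > 0
    if (sum(use) >= min_ratio_genes) stats::median(x[use] / ref[use])
    else total[j] / mean(total)
  }, numeric(1))
  sf <- sf / exp(mean(log(sf)))
  values <- log(sweep(dense, 2, sf, "/") + 1)
  structure(list(values = values, size_factors = sf,
                 gene_ids = m$gene_ids, barcodes = m$barcodes),
            class = "NormalizedMatrix")
}

#' Rank genes by standardized variance and keep the top set
#'
#' Fits a quadratic mean-variance trend on log scale across genes, z-scores
#' each gene by its trend-predicted standard deviation and ranks genes by the
#' variance of those z-scores (vst-style standardized variance).
#'
#' @param nm a `NormalizedMatrix`.
#' @param n_top number of genes to return.
#' @return Character vector of the `n_top` most variable gene ids.
#' @export
select_variable_genes <- function(nm, n_top = 2000L) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  n_top <- min(n_top, length(nm$gene_ids))
  mu <- rowMeans(nm$values)
  v <- apply(nm$values, 1, stats::var)
  if (all(v == 0)) stop("constant matrix: no variable genes")
  pos <- v > 0 & mu > 0
  fit <- stats::lm(log(v[pos]) ~ stats::poly(log(mu[pos]), 2))
  trend <- rep(NA_real_, length(v))
  trend[pos] <- exp(stats::fitted(fit))
  std_var <- rep(-Inf, length(v))
  for (i in which(pos)) {
    z <- (nm$values[i, ] - mu[i]) / sqrt(trend[i])
    z <- pmin(z, sqrt(ncol(nm$values)))  # clip extreme cells, vst convention
    std_var[i] <- stats::var(z)
  }
  nm$gene_ids[order(std_var, decreasing = TRUE)[seq_len(n_top)]]
}

#' Principal component analysis of selected genes
#'
#' Centers and unit-scales the selected genes' expression across cells and
#' projects onto the top components. Sign convention: each component's
#' largest-magnitude gene loading is made positive, so results are fully
#' deterministic.
#'
#' @param nm a `NormalizedMatrix`.
#' @param genes character vector of genes to use (subset of `nm$gene_ids`).
#' @param max_pcs number of components (clipped to the data rank with a
#'   warning if too large).
#' @param elbow_frac,min_pcs elbow-rule parameters passed to [choose_elbow()].
#' @return A list of class `Embedding`: `scores` (cells x components),
#'   `loadings`, `explained_variance`, `n_pcs_selected`, `barcodes`.
#' @export
run_pca <- function(nm, genes, max_pcs = 30L, elbow_frac = 0.001,
                    min_pcs = 5L) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  idx <- match(genes, nm$gene_ids)
  if (anyNA(idx)) stop("genes not present in the matrix: ",
                       genes[is.na(idx)][1])
  x <- t(nm$values[idx, , drop = FALSE])  # cells x genes
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE])
  cap <- min(nrow(x) - 1L, ncol(x))
  if (max_pcs > cap) {
    warning("max_pcs clipped from ", max_pcs, " to ", cap)
    max_pcs <- cap
  }
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = max_pcs)
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    l <- p$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  ev <- p$sdev[seq_len(max_pcs)]^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev,
                 n_pcs_selected = choose_elbow(ev, frac = elbow_frac,
                                               min_pcs = min_pcs,
                                               max_pcs = max_pcs),
                 barcodes = nm$barcodes),
            class = "Embedding")
}

#' Elbow rule for the number of principal components
#'
#' Keeps every component whose explained variance is at least `frac` of the
#' total (default 0.1%): the elbow is where the spectrum falls below that
#' floor. The result is clamped to `[min_pcs, max_pcs]` (and to the vector
#' length).
#'
#' @param explained_variance non-increasing variance vector.
#' @param frac variance floor as a fraction of total.
#' @param min_pcs lower clamp on the returned count.
#' @param max_pcs upper clamp.
#' @return Integer number of components.
#' @export
choose_elbow <- function(explained_variance, frac = 0.001, min_pcs = 5L,
                         max_pcs = length(explained_variance)) {
  ev <- explained_variance
  if (length(ev) == 0) stop("empty variance vector")
  if (any(diff(ev) > 1e-8 * max(ev)))
    stop("explained variance must be non-increasing")
  if (length(ev) < min_pcs) {
    warning("variance vector shorter than the floor of ", min_pcs,
            " components; returning full length")
    return(length(ev))
  }
  k <- sum(ev >= frac * sum(ev))
  max(min(k, max_pcs, length(ev)), min(min_pcs, length(ev)), 1L)
}

# k-nearest-neighbour indices by Euclidean distance (brute force)
knn_indices <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' KNN-graph Louvain clustering of an embedding
#'
#' Builds a k-nearest-neighbour graph in PC space (Euclidean), weights edges
#' by the Jaccard overlap of the two cells' neighbour sets (shared-nearest-
#' neighbour weighting), and maximises modularity with the Louvain algorithm.
#' Labels are contiguous integers ordered by decreasing cluster size.
#'
#' @param emb an `Embedding` (the first `n_pcs_selected` components are used)
#'   or a plain cells x dims matrix.
#' @param k_neighbors neighbours per cell (must be < number of cells).
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed for the (order-dependent) Louvain heuristic.
#' @param min_snn Jaccard weight below which an edge is pruned.
#' @return A list with `labels` (integer vector), `cells` (data.frame
#'   barcode/label if barcodes known), `modularity`, and `graph` (igraph).
#' @export
cluster_cells <- function(emb, k_neighbors = 20L, resolution = 1, seed = 1L,
                          min_snn = 1 / 15) {
  x <- if (inherits(emb, "Embedding"))
    emb$scores[, seq_len(emb$n_pcs_selected), drop = FALSE]
  else as.matrix(emb)
  n <- nrow(x)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the cell count")
  nn <- knn_indices(x, k_neighbors)
  # SNN: Jaccard similarity of neighbour sets over the kNN edge list
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  memb <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                               dims = c(n, n))
  shared <- as.matrix(Matrix::tcrossprod(memb))
  w <- apply(edges, 1, function(e) {
    s <- shared[e[1], e[2]]
    s / (2 * k_neighbors - s)
  })
  keep <- w >= min_snn & edges[, 1] < edges[, 2]
  # keep each undirected pair once with its Jaccard weight
  pair_id <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  first <- !duplicated(pair_id)
  use <- (w >= min_snn) & first
  g <- igraph::graph_from_edgelist(
    cbind(pmin(edges[use, 1], edges[use, 2]),
          pmax(edges[use, 1], edges[use, 2])), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[use]
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(comm)
  if (any(igraph::degree(g) == 0))
    warning(sum(igraph::degree(g) == 0), " isolated cells form singleton clusters")
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relabel[as.character(raw)])
  cells <- if (inherits(emb, "Embedding"))
    data.frame(barcode = emb$barcodes, label = labels, stringsAsFactors = FALSE)
  else data.frame(barcode = seq_len(n), label = labels)
  list(labels = labels, cells = cells,
       modularity = igraph::modularity(g, raw, weights = igraph::E(g)$weight),
       graph = g)
}
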