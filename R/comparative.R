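#' Per-cluster expression centroids
#'
#' Mean expression per cluster, restricted to a shared feature space. The
#' default profile for cross-dataset cosine comparison is mean log-normalised
#' expression over the classifier's feature space; detection-frequency
#' profiles (`profile = "detection"`) are available as an alternative.
#'
#' @param nm a `NormalizedMatrix` (or genes x cells matrix with rownames).
#' @param labels cluster label per cell.
#' @param fs `FeatureSpace` (or character vector) of genes to profile over;
#'   genes absent from `nm` contribute 0.
#' @param profile `"expression"` (mean log-normalised values) or
#'   `"detection"` (fraction of cells with value > 0).
#' @param min_size clusters smaller than this are flagged in the
#'   `"flagged_small"` attribute.
#' @return clusters x features centroid matrix (rownames = cluster labels).
#' @export
cluster_centroids <- function(nm, labels, fs,
                              profile = c("expression", "detection"),
                              min_size = 10L) {
  profile <- match.arg(profile)
  vals <- if (inherits(nm, "NormalizedMatrix")) nm$values else as.matrix(nm)
  ids <- if (inherits(nm, "NormalizedMatrix")) nm$gene_ids else rownames(nm)
  if (length(labels) != ncol(vals))
    stop("labels must cover all cells (", length(labels), " vs ",
         ncol(vals), ")")
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  fs <- as.character(fs)
  idx <- match(fs, ids)
  cen <- matrix(0, length(cls), length(fs), dimnames = list(cls, fs))
  for (k in seq_along(cls)) {
    cells <- labels == cls[k]
    if (!any(cells)) stop("empty cluster: ", cls[k])
    sub <- vals[idx[!is.na(idx)], cells, drop = FALSE]
    prof <- if (profile == "expression") rowMeans(sub) else rowMeans(sub > 0)
    cen[k, !is.na(idx)] <- prof
  }
  attr(cen, "flagged_small") <- cls[table(factor(labels, cls)) < min_size]
  cen
}

#' Cosine similarity between two profile sets
#'
#' `S[i, j] = a_i . b_j / (||a_i|| ||b_j||)`, in [-1, 1]. Zero-norm profiles
#' yield `NA` entries and a warning.
#'
#' @param a,b profiles x features matrices over the same feature dimension.
#' @return `nrow(a)` x `nrow(b)` similarity matrix.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("feature dimension mismatch: ", ncol(a), " vs ", ncol(b))
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  s <- (a %*% t(b)) / outer(na, nb)
  if (any(na == 0) || any(nb == 0)) {
    warning("zero-norm profile(s); similarity undefined (NA) for those rows")
    s[na == 0, ] <- NA_real_
    s[, nb == 0] <- NA_real_
  }
  s
}

#' Cluster-composition comparison between conditions
#'
#' Tabulates per-condition cell fractions over clusters (each condition's
#' fractions sum to 1) and tests each cluster's abundance difference between
#' the two conditions with a two-proportion z-test, Benjamini-Hochberg
#' adjusted across clusters.
#'
#' @param cells data.frame with `label` (cluster) and `condition` columns.
#' @param conditions the two condition levels to contrast (default: first two
#'   observed).
#' @return A list with `composition` (cluster x condition fraction matrix)
#'   and `tests` (data.frame: cluster, per-condition fractions, difference,
#'   p, adj_p).
#' @export
composition_compare <- function(cells, conditions = NULL) {
  stopifnot(all(c("label", "condition") %in% names(cells)))
  if (is.null(conditions)) conditions <- unique(as.character(cells$condition))
  if (length(conditions) < 2) stop("need at least two conditions")
  conditions <- conditions[1:2]
  sub <- cells[cells$condition %in% conditions, ]
  n_by <- table(factor(sub$condition, conditions))
  if (any(n_by == 0)) stop("condition with zero cells: ",
                           conditions[n_by == 0][1])
  tab <- table(factor(sub$label), factor(sub$condition, conditions))
  comp <- sweep(tab, 2, colSums(tab), "/")
  p <- vapply(rownames(tab), function(cl) {
    x <- tab[cl, ]
    n <- colSums(tab)
    ph <- sum(x) / sum(n)
    se <- sqrt(ph * (1 - ph) * (1 / n[1] + 1 / n[2]))
    if (se == 0) return(1)
    z <- (x[1] / n[1] - x[2] / n[2]) / se
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  tests <- data.frame(cluster = rownames(tab),
                      frac_1 = as.numeric(comp[, 1]),
                      frac_2 = as.numeric(comp[, 2]),
                      difference = as.numeric(comp[, 1] - comp[, 2]),
                      p_value = as.numeric(p),
                      adj_p = bh_adjust(as.numeric(p)),
                      stringsAsFactors = FALSE)
  names(tests)[2:3] <- paste0("frac_", conditions)
  list(composition = unclass(as.matrix(comp)), tests = tests)
}
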