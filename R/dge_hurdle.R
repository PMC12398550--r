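#' Marker-screen and condition-contrast thresholds
#'
#' `marker_filter()` holds the pre-filter applied before testing cluster
#' markers: minimum positive log2 fold change 0.25, detection in at least 20%
#' of cells inside the cluster and strictly less than 60% outside.
#' `dge_thresholds()` holds the additional condition-contrast cut-offs:
#' absolute log2FC >= 0.5 and adjusted p < 0.05.
#'
#' @param min_log2fc minimum positive log2FC for marker screening.
#' @param min_pct_in minimum in-group detection fraction.
#' @param max_pct_out exclusive upper bound on out-group detection.
#' @return Named list.
#' @export
marker_filter <- function(min_log2fc = 0.25, min_pct_in = 0.20,
                          max_pct_out = 0.60) {
  list(min_log2fc = min_log2fc, min_pct_in = min_pct_in,
       max_pct_out = max_pct_out)
}

#' @rdname marker_filter
#' @param min_abs_log2fc minimum absolute log2FC for contrast survivors.
#' @param max_adj_p adjusted-p cut-off (exclusive).
#' @export
dge_thresholds <- function(min_abs_log2fc = 0.5, max_adj_p = 0.05) {
  list(min_abs_log2fc = min_abs_log2fc, max_adj_p = max_adj_p)
}

#' Detection fractions of a gene in two groups
#'
#' @param nm a `NormalizedMatrix`.
#' @param gene gene id or row index.
#' @param in_group,out_group disjoint cell index/logical vectors.
#' @return Named numeric: `pct_in`, `pct_out` (fractions of cells with the
#'   gene detected, i.e. count > 0).
#' @export
detection_fractions <- function(nm, gene, in_group, out_group) {
  v <- gene_values(nm, gene)
  i <- resolve_cells(in_group, length(v))
  o <- resolve_cells(out_group, length(v))
  if (length(i) == 0 || length(o) == 0) stop("empty group")
  if (length(intersect(i, o))) stop("groups must be disjoint")
  c(pct_in = mean(v[i] > 0), pct_out = mean(v[o] > 0))
}

#' Log2 fold change between groups
#'
#' Computed on back-transformed normalised expression:
#' `log2((mean(expm1(x_in)) + pseudocount) / (mean(expm1(x_out)) + pseudocount))`
#' — the dominant single-cell convention. Antisymmetric under swapping the
#' groups.
#'
#' @inheritParams detection_fractions
#' @param pseudocount added to both back-transformed means.
#' @return Scalar log2 fold change.
#' @export
log2_fold_change <- function(nm, gene, in_group, out_group, pseudocount = 1) {
  v <- gene_values(nm, gene)
  i <- resolve_cells(in_group, length(v))
  o <- resolve_cells(out_group, length(v))
  log2((mean(expm1(v[i])) + pseudocount) / (mean(expm1(v[o])) + pseudocount))
}

gene_values <- function(nm, gene) {
  if (inherits(nm, "NormalizedMatrix")) {
    if (is.character(gene)) gene <- match(gene, nm$gene_ids)
    if (is.na(gene)) stop("unknown gene")
    nm$values[gene, ]
  } else if (is.matrix(nm)) {
    nm[gene, ]
  } else as.numeric(nm)
}

resolve_cells <- function(idx, n) {
  if (is.logical(idx)) which(idx) else as.integer(idx)
}

# penalised logistic log-likelihood fit (ridge fallback for separation)
ridge_logit_dev <- function(x, y, ridge = 1e-3) {
  nll <- function(beta) {
    eta <- drop(x %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      ridge * sum(beta[-1]^2)
  }
  fit <- stats::optim(rep(0, ncol(x)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  2 * fit$value
}

#' Two-part hurdle differential-expression test
#'
#' The MAST model class: a logistic regression of detection (count > 0) on
#' group (plus covariates), and a Gaussian regression of log-normalised
#' expression among detected cells on the same design. The likelihood-ratio
#' statistics of the group term are summed across the two parts and compared
#' to a chi-square with the summed degrees of freedom. Parts with no usable
#' data (constant detection; fewer than `min_detected` detected cells; a
#' group absent among detected cells) contribute 0 df. Complete separation in
#' the logistic part falls back to a small ridge stabiliser and is flagged.
#'
#' @param values per-cell log-normalised expression of one gene (or a
#'   `NormalizedMatrix` plus `gene`).
#' @param group factor with >= 2 levels (>= 2 cells per group).
#' @param covariates optional data.frame of per-cell covariates.
#' @param gene gene id/index when `values` is a `NormalizedMatrix`.
#' @param min_detected minimum detected cells for the continuous part.
#' @return List: `statistic` (summed LR), `df`, `p_value`,
#'   `discrete_stat`, `continuous_stat`, `flagged`.
#' @export
hurdle_test <- function(values, group, covariates = NULL, gene = NULL,
                        min_detected = 3L) {
  if (inherits(values, "NormalizedMatrix")) values <- gene_values(values, gene)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("need >= 2 cells per group")
  det <- as.integer(values > 0)
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  df_all <- data.frame(det = det, y = values, group = group)
  if (has_cov) df_all <- cbind(df_all, as.data.frame(covariates))
  cov_terms <- if (has_cov)
    paste(colnames(as.data.frame(covariates)), collapse = " + ") else "1"
  flagged <- FALSE
  # discrete part
  d_stat <- 0; d_df <- 0L
  if (length(unique(det)) > 1) {
    ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
    full <- suppressWarnings(stats::glm(
      stats::as.formula(paste("det ~ group +", cov_terms)),
      family = stats::binomial(), data = df_all, control = ctl))
    null <- suppressWarnings(stats::glm(
      stats::as.formula(paste("det ~", cov_terms)),
      family = stats::binomial(), data = df_all, control = ctl))
    sep <- any(abs(stats::coef(full)[-1]) > 15, na.rm = TRUE) ||
      !full$converged
    if (sep) {
      flagged <- TRUE
      xf <- stats::model.matrix(full)
      xn <- stats::model.matrix(null)
      d_stat <- max(0, ridge_logit_dev(xn, det) - ridge_logit_dev(xf, det))
    } else {
      d_stat <- max(0, null$deviance - full$deviance)
    }
    d_df <- null$df.residual - full$df.residual
  }
  # continuous part, detected cells only
  c_stat <- 0; c_df <- 0L
  di <- det == 1
  if (sum(di) >= min_detected &&
      length(unique(group[di])) == nlevels(group)) {
    sub <- df_all[di, , drop = FALSE]
    sub$group <- droplevels(sub$group)
    full <- stats::lm(stats::as.formula(paste("y ~ group +", cov_terms)),
                      data = sub)
    null <- stats::lm(stats::as.formula(paste("y ~", cov_terms)), data = sub)
    if (full$df.residual > 0 && null$df.residual > full$df.residual) {
      rss1 <- sum(stats::residuals(full)^2)
      rss0 <- sum(stats::residuals(null)^2)
      if (rss1 > 0) {
        c_stat <- sum(di) * log(rss0 / rss1)
        c_df <- null$df.residual - full$df.residual
      }
    }
  }
  stat <- d_stat + c_stat
  df <- d_df + c_df
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p_value = p,
       discrete_stat = d_stat, continuous_stat = c_stat, flagged = flagged)
}

# vectorised per-gene pct/lfc against a two-group split
group_summaries <- function(vals, in_cells, out_cells, pseudocount = 1) {
  pct_in <- rowMeans(vals[, in_cells, drop = FALSE] > 0)
  pct_out <- rowMeans(vals[, out_cells, drop = FALSE] > 0)
  m_in <- rowMeans(expm1(vals[, in_cells, drop = FALSE]))
  m_out <- rowMeans(expm1(vals[, out_cells, drop = FALSE]))
  data.frame(pct_in = pct_in, pct_out = pct_out,
             log2fc = log2((m_in + pseudocount) / (m_out + pseudocount)))
}

#' Screen cluster markers with the hurdle test
#'
#' For every cluster, genes are pre-filtered by positive log2FC > 0.25,
#' detection in >= 20% of cluster cells and < 60% of the remaining cells
#' (strict), then hurdle-tested cluster-vs-rest; Benjamini-Hochberg
#' adjustment is applied within each cluster's tested set.
#'
#' @param nm a `NormalizedMatrix`.
#' @param labels cluster label per cell (>= 2 clusters).
#' @param filter a [marker_filter()].
#' @param covariates optional per-cell covariate data.frame.
#' @return data.frame with columns `cluster`, `gene`, `pct_in`, `pct_out`,
#'   `log2fc`, `p_value`, `adj_p`, `direction`.
#' @export
marker_screen <- function(nm, labels, filter = marker_filter(),
                          covariates = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need >= 2 clusters")
  out <- list()
  for (cl in cls) {
    in_cells <- labels == cl
    gs <- group_summaries(nm$values, in_cells, !in_cells)
    pass <- gs$log2fc > filter$min_log2fc &
      gs$pct_in >= filter$min_pct_in &
      gs$pct_out < filter$max_pct_out
    idx <- which(pass)
    if (!length(idx)) next
    grp <- factor(ifelse(in_cells, "in", "out"), c("out", "in"))
    p <- vapply(idx, function(i)
      hurdle_test(nm$values[i, ], grp, covariates)$p_value, numeric(1))
    out[[cl]] <- data.frame(cluster = cl, gene = nm$gene_ids[idx],
                            pct_in = gs$pct_in[idx], pct_out = gs$pct_out[idx],
                            log2fc = gs$log2fc[idx], p_value = p,
                            adj_p = bh_adjust(p), direction = "up",
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      pct_in = numeric(), pct_out = numeric(),
                      log2fc = numeric(), p_value = numeric(),
                      adj_p = numeric(), direction = character()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Two-condition differential expression with the hurdle test
#'
#' Genes pass a direction-symmetric pre-filter (|log2FC| >= `min_log2fc` and
#' detection >= `min_pct_in` in at least one condition), are hurdle-tested
#' between conditions, BH-adjusted over the tested set, and split into up-
#' and downregulated survivor lists at |log2FC| >= 0.5 and adjusted p < 0.05.
#'
#' @param nm a `NormalizedMatrix`.
#' @param condition two-level factor per cell; the first level is the
#'   baseline (log2FC > 0 means higher in the second level).
#' @param covariates optional per-cell covariate data.frame (e.g. sample).
#' @param thresholds a [dge_thresholds()].
#' @param filter a [marker_filter()] supplying the pre-filter cut-offs.
#' @return List: `up`, `down` (gene id vectors), `table` (all tested genes
#'   with `pct_in` = detection in the non-baseline condition, `pct_out` =
#'   baseline, `log2fc`, `p_value`, `adj_p`, `direction`, `significant`).
#' @export
condition_contrast <- function(nm, condition, covariates = NULL,
                               thresholds = dge_thresholds(),
                               filter = marker_filter()) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2) stop("need exactly two conditions")
  trt <- condition == levels(condition)[2]
  gs <- group_summaries(nm$values, trt, !trt)
  pass <- abs(gs$log2fc) >= filter$min_log2fc &
    pmax(gs$pct_in, gs$pct_out) >= filter$min_pct_in
  idx <- which(pass)
  p <- vapply(idx, function(i)
    hurdle_test(nm$values[i, ], condition, covariates)$p_value, numeric(1))
  adj <- bh_adjust(p)
  tab <- data.frame(gene = nm$gene_ids[idx], pct_in = gs$pct_in[idx],
                    pct_out = gs$pct_out[idx], log2fc = gs$log2fc[idx],
                    p_value = p, adj_p = adj,
                    direction = ifelse(gs$log2fc[idx] >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  tab$significant <- abs(tab$log2fc) >= thresholds$min_abs_log2fc &
    tab$adj_p < thresholds$max_adj_p
  list(up = tab$gene[tab$significant & tab$direction == "up"],
       down = tab$gene[tab$significant & tab$direction == "down"],
       table = tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (order-preserving under ties); input must lie in [0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
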