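# shared fixtures, built in code and memoised per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# tiny hand-checkable count matrix: 3 genes x 2 cells
tiny_counts <- function() {
  count_matrix(matrix(c(5, 0, 0, 0, 0, 2), 3, 2),
               c("GRCh38_MBP", "gA", "mm10_Mbp"), c("bc1", "bc2"))
}

# small labelled source + shifted target pair (4 classes)
small_domain_pair <- function() {
  memo("small_pair", function() {
    cfg <- simulation_config(n_classes = 4, n_genes = 200,
                             cells_per_class = 60, markers_per_class = 8,
                             domain_shift_sd = 0.3, seed = 101)
    ref <- simulate_reference(cfg)
    tgt <- simulate_target(cfg, ref$truth)
    list(cfg = cfg, ref = ref, tgt = tgt)
  })
}

# normalized matrices + feature space for the small pair
small_transfer_inputs <- function() {
  memo("small_transfer", function() {
    sp <- small_domain_pair()
    ref_f <- filter_genes(sp$ref$counts, 5)
    tgt_f <- filter_genes(sp$tgt$counts, 5)
    nm_s <- normalize_counts(ref_f)
    nm_t <- normalize_counts(tgt_f)
    fs <- build_feature_space(select_variable_genes(nm_s, 150),
                              select_variable_genes(nm_t, 150))
    list(ref = ref_f, tgt = tgt_f, nm_s = nm_s, nm_t = nm_t, fs = fs,
         labels = sp$ref$truth$cells$label,
         tgt_truth = sp$tgt$truth$cells$label)
  })
}

# brute-force BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force maximum-likelihood hurdle LR statistic (optim-based)
hurdle_oracle_stat <- function(values, group) {
  det <- as.integer(values > 0)
  gi <- as.integer(as.factor(group)) - 1L
  nll_logit <- function(b, X) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - det * eta)
  }
  fit_logit <- function(X)
    stats::optim(rep(0, ncol(X)), nll_logit, X = X, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 1000))$value
  d_stat <- if (length(unique(det)) > 1)
    2 * (fit_logit(cbind(rep(1, length(det)))) - fit_logit(cbind(1, gi)))
  else 0
  nll_norm <- function(X, y) {
    b <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% b)^2)
    n <- length(y)
    n / 2 * log(rss / n) + n / 2 * (1 + log(2 * pi))
  }
  di <- det == 1
  c_stat <- if (sum(di) >= 3 && length(unique(gi[di])) == 2)
    2 * (nll_norm(cbind(rep(1, sum(di))), values[di]) -
           nll_norm(cbind(1, gi[di]), values[di]))
  else 0
  d_stat + c_stat
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
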