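#' Build the binarized classifier's feature space
#'
#' The feature space is the sorted, deduplicated union of the variable genes
#' of the source (atlas) and target datasets. Genes absent from one dataset
#' simply contribute an "undetected" (0) column there. The feature order is
#' stable and persisted with trained models.
#'
#' @param source_hvg,target_hvg character vectors of variable genes.
#' @return Character vector of class `FeatureSpace`.
#' @export
build_feature_space <- function(source_hvg, target_hvg) {
  fs <- sort(unique(c(as.character(source_hvg), as.character(target_hvg))))
  if (length(fs) == 0) stop("empty feature-space union")
  structure(fs, class = "FeatureSpace")
}

#' Binarize expression over a feature space
#'
#' Encodes each gene/cell as detected (UMI count > 0) or undetected
#' (count = 0) — the entire feature representation of the classifier.
#' Features missing from the input yield all-zero columns. Binarization is
#' idempotent.
#'
#' @param m a `CountMatrix`, a genes x cells matrix with gene-id rownames, or
#'   an existing `BinarizedMatrix` (cells x features).
#' @param fs a [build_feature_space()] result.
#' @return cells x features 0/1 matrix of class `BinarizedMatrix`, with the
#'   feature space as column names.
#' @export
binarize <- function(m, fs) {
  stopifnot(inherits(fs, "FeatureSpace"))
  f <- length(fs)
  if (inherits(m, "BinarizedMatrix")) {
    x <- matrix(0, nrow(m), f, dimnames = list(rownames(m), as.character(fs)))
    idx <- match(as.character(fs), colnames(m))
    ok <- !is.na(idx)
    x[, ok] <- (unclass(m)[, idx[ok], drop = FALSE] > 0) + 0
    return(structure(x, class = "BinarizedMatrix"))
  }
  if (inherits(m, "CountMatrix")) {
    vals <- m$values; ids <- m$gene_ids; bcs <- m$barcodes
  } else {
    vals <- as(methods::as(as.matrix(m), "dMatrix"), "CsparseMatrix")
    ids <- rownames(m); bcs <- colnames(m)
    if (is.null(ids)) stop("matrix input needs gene-id rownames")
  }
  x <- matrix(0, ncol(vals), f, dimnames = list(bcs, as.character(fs)))
  idx <- match(as.character(fs), ids)
  ok <- !is.na(idx)
  if (any(ok))
    x[, ok] <- t(as.matrix(vals[idx[ok], , drop = FALSE] > 0)) + 0
  structure(x, class = "BinarizedMatrix")
}

#' Network and training hyper-parameters
#'
#' Defaults follow the published architecture: two ReLU hidden layers of 64
#' and 32 units with L1 regularisation (lambda 0.001) on their weights, and a
#' softmax output over the label set. Training uses cross-entropy loss,
#' RMSprop (step size 0.001, decay 0.9, stabiliser 1e-7) and a balanced
#' sample generator drawing `per_class_per_step` examples per class per
#' gradient step. The published schedule is 1000 epochs of 256 steps; the
#' package default is a scaled-down 100 x 64 schedule for desk-scale runs.
#'
#' @param hidden1,hidden2 hidden layer widths.
#' @param l1_lambda L1 penalty on the two hidden layers' weight matrices
#'   (biases and the output layer are unpenalised).
#' @return Named list (`ANNConfig`).
#' @export
ann_config <- function(hidden1 = 64L, hidden2 = 32L, l1_lambda = 0.001) {
  structure(list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
                 l1_lambda = l1_lambda), class = c("ANNConfig", "list"))
}

#' @rdname ann_config
#' @param n_folds stratified folds / ensemble size (the published analyses
#'   use 5 or 3).
#' @param epochs,steps_per_epoch training schedule.
#' @param per_class_per_step examples drawn per class per gradient step.
#' @param learning_rate,rho,epsilon RMSprop parameters.
#' @param seed integer seed for fold assignment, initialisation and batches.
#' @export
training_config <- function(n_folds = 5L, epochs = 100L,
                            steps_per_epoch = 64L, per_class_per_step = 16L,
                            learning_rate = 0.001, rho = 0.9, epsilon = 1e-7,
                            seed = 1L) {
  structure(list(n_folds = as.integer(n_folds), epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 per_class_per_step = as.integer(per_class_per_step),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = c("TrainingConfig", "list"))
}

# Glorot-uniform initialisation, seeded by the caller's RNG state
init_ann <- function(n_features, n_labels, cfg) {
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  structure(list(W1 = glorot(n_features, cfg$hidden1), b1 = rep(0, cfg$hidden1),
                 W2 = glorot(cfg$hidden1, cfg$hidden2), b2 = rep(0, cfg$hidden2),
                 W3 = glorot(cfg$hidden2, n_labels), b3 = rep(0, n_labels),
                 n_features = n_features, n_labels = n_labels,
                 config = cfg, history = NULL, levels = NULL,
                 feature_space = NULL),
            class = "ANNModel")
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

#' Forward pass of the classifier
#'
#' `h1 = relu(X W1 + b1)`, `h2 = relu(h1 W2 + b2)`,
#' `p = softmax(h2 W3 + b3)`; every output row sums to 1.
#'
#' @param model an `ANNModel`.
#' @param x cells x features matrix (binarized expression).
#' @param cache return intermediate activations (for backprop).
#' @return Probability matrix (cells x labels), or a list with `p`, `h1`,
#'   `h2`, `z1`, `z2` when `cache = TRUE`.
#' @export
ann_forward <- function(model, x, cache = FALSE) {
  x <- unclass(x)
  if (ncol(x) != model$n_features)
    stop("feature dimension mismatch: got ", ncol(x), ", expected ",
         model$n_features)
  z1 <- add_bias(x %*% model$W1, model$b1)
  h1 <- pmax(z1, 0)
  z2 <- add_bias(h1 %*% model$W2, model$b2)
  h2 <- pmax(z2, 0)
  z3 <- add_bias(h2 %*% model$W3, model$b3)
  z3 <- z3 - apply(z3, 1, max)
  e <- exp(z3)
  p <- e / rowSums(e)
  if (cache) list(p = p, h1 = h1, h2 = h2, z1 = z1, z2 = z2) else p
}

#' Cross-entropy loss with L1 regularisation
#'
#' Mean categorical cross-entropy (probabilities clipped at 1e-12 before the
#' log) plus `l1_lambda * (||W1||_1 + ||W2||_1)`; biases and the output layer
#' are not penalised.
#'
#' @param model an `ANNModel`.
#' @param x cells x features matrix.
#' @param y_idx integer label index per cell (1..K).
#' @return Scalar loss.
#' @export
ann_loss <- function(model, x, y_idx) {
  p <- ann_forward(model, x)
  ce <- -mean(log(pmax(p[cbind(seq_len(nrow(p)), y_idx)], 1e-12)))
  ce + model$config$l1_lambda * (sum(abs(model$W1)) + sum(abs(model$W2)))
}

# analytic gradient of ann_loss w.r.t. all parameters
ann_gradient <- function(model, x, y_idx) {
  x <- unclass(x)
  n <- nrow(x)
  fw <- ann_forward(model, x, cache = TRUE)
  y <- matrix(0, n, model$n_labels)
  y[cbind(seq_len(n), y_idx)] <- 1
  g3 <- (fw$p - y) / n
  lam <- model$config$l1_lambda
  g2 <- (g3 %*% t(model$W3)) * (fw$z2 > 0)
  g1 <- (g2 %*% t(model$W2)) * (fw$z1 > 0)
  list(W1 = crossprod(x, g1) + lam * sign(model$W1), b1 = colSums(g1),
       W2 = crossprod(fw$h1, g2) + lam * sign(model$W2), b2 = colSums(g2),
       W3 = crossprod(fw$h2, g3), b3 = colSums(g3))
}

#' Stratified fold assignment
#'
#' Distributes the cells of every class as evenly as possible across
#' `n_folds` folds (shuffled within class), so each fold preserves the class
#' proportions within one cell.
#'
#' @param labels factor or character label per cell.
#' @param n_folds number of folds.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return Integer fold id (1..n_folds) per cell.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  small <- names(counts)[counts < n_folds]
  if (length(small))
    stop("class '", small[1], "' has ", counts[small[1]],
         " members, fewer than n_folds = ", n_folds)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Class-balanced minibatch index stream
#'
#' Every batch holds exactly `per_class` examples of every class, sampled
#' with replacement — the sample generator that re-balances skewed training
#' sets. Uses (and advances) the caller's RNG stream; seed it for
#' reproducibility.
#'
#' @param labels factor/character label per training cell.
#' @param per_class examples per class per batch.
#' @param n_batches number of batches to emit.
#' @param class_levels label universe (defaults to observed levels; every
#'   level must be present in `labels`).
#' @return List of integer index vectors, each of length
#'   `per_class * n_classes`.
#' @export
balanced_batches <- function(labels, per_class, n_batches,
                             class_levels = NULL) {
  labels <- as.character(labels)
  if (is.null(class_levels)) class_levels <- sort(unique(labels))
  by_class <- lapply(class_levels, function(cl) which(labels == cl))
  empty <- lengths(by_class) == 0
  if (any(empty))
    stop("class '", class_levels[empty][1], "' absent from the training fold")
  lapply(seq_len(n_batches), function(b)
    unlist(lapply(by_class, function(idx)
      idx[sample.int(length(idx), per_class, replace = TRUE)])))
}

rmsprop_update <- function(model, vel, grad, tc) {
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    vel[[nm]] <- tc$rho * vel[[nm]] + (1 - tc$rho) * grad[[nm]]^2
    model[[nm]] <- model[[nm]] -
      tc$learning_rate * grad[[nm]] / (sqrt(vel[[nm]]) + tc$epsilon)
  }
  list(model = model, vel = vel)
}

#' Train one classifier
#'
#' RMSprop on the L1-regularised cross-entropy, over `steps_per_epoch`
#' class-balanced batches per epoch. History records the mean training-batch
#' loss and the validation balanced accuracy per epoch. Fully deterministic
#' given `seed`.
#'
#' @param x_train,y_train training binarized matrix and labels (factor levels
#'   define the output layer).
#' @param x_val,y_val held-out validation fold (may be `NULL`).
#' @param cfg an [ann_config()].
#' @param tc a [training_config()].
#' @param seed integer seed (defaults to `tc$seed`).
#' @return A trained `ANNModel` with `$history` and `$levels`.
#' @export
train_ann <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                      cfg = ann_config(), tc = training_config(),
                      seed = tc$seed) {
  y_train <- as.factor(y_train)
  lev <- levels(y_train)
  set.seed(seed)
  model <- init_ann(ncol(x_train), length(lev), cfg)
  model$levels <- lev
  vel <- lapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                function(p) p * 0)
  y_idx <- as.integer(y_train)
  hist <- data.frame(epoch = seq_len(tc$epochs), train_loss = NA_real_,
                     val_balanced_accuracy = NA_real_, val_loss = NA_real_)
  for (ep in seq_len(tc$epochs)) {
    batches <- balanced_batches(y_train, tc$per_class_per_step,
                                tc$steps_per_epoch, class_levels = lev)
    losses <- numeric(length(batches))
    for (s in seq_along(batches)) {
      bi <- batches[[s]]
      xb <- unclass(x_train)[bi, , drop = FALSE]
      yb <- y_idx[bi]
      grad <- ann_gradient(model, xb, yb)
      losses[s] <- ann_loss(model, xb, yb)
      if (!is.finite(losses[s]))
        stop("non-finite training loss at epoch ", ep, ", step ", s,
             " (lr ", tc$learning_rate, ")")
      up <- rmsprop_update(model, vel, grad, tc)
      model <- up$model; vel <- up$vel
    }
    hist$train_loss[ep] <- mean(losses)
    if (!is.null(x_val) && length(y_val)) {
      p <- ann_forward(model, x_val)
      pred <- lev[max.col(p, ties.method = "first")]
      hist$val_balanced_accuracy[ep] <-
        balanced_accuracy(pred, as.character(y_val), lev)
      hist$val_loss[ep] <- ann_loss(model, x_val,
                                    match(as.character(y_val), lev))
    }
  }
  model$history <- hist
  model
}

#' Train the cross-validated ensemble
#'
#' Splits the labelled source data into `n_folds` stratified parts and trains
#' one network per fold, each on all parts minus one with the held-out part
#' as validation — yielding the 3- or 5-member ensemble used for label
#' transfer.
#'
#' @param x source-domain `BinarizedMatrix`.
#' @param labels source labels.
#' @param cfg an [ann_config()].
#' @param tc a [training_config()].
#' @param fs optional `FeatureSpace` persisted with each model.
#' @return List of class `ANNEnsemble`: `models`, `folds`,
#'   `validation` (per-fold balanced accuracy / precision / recall and their
#'   averages), `levels`, `feature_space`.
#' @export
train_ensemble <- function(x, labels, cfg = ann_config(),
                           tc = training_config(), fs = NULL) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  folds <- stratified_folds(labels, tc$n_folds, seed = tc$seed)
  models <- vector("list", tc$n_folds)
  val <- data.frame(fold = seq_len(tc$n_folds), balanced_accuracy = NA_real_,
                    macro_precision = NA_real_, macro_recall = NA_real_)
  for (k in seq_len(tc$n_folds)) {
    tr <- folds != k
    m <- train_ann(unclass(x)[tr, , drop = FALSE],
                   factor(labels[tr], levels = lev),
                   unclass(x)[!tr, , drop = FALSE], labels[!tr],
                   cfg, tc, seed = derive_seed(tc$seed, paste0("fold", k)))
    m$feature_space <- fs
    p <- ann_forward(m, unclass(x)[!tr, , drop = FALSE])
    pred <- lev[max.col(p, ties.method = "first")]
    ev <- evaluate_transfer(pred, as.character(labels[!tr]), lev)
    val$balanced_accuracy[k] <- ev$balanced_accuracy
    val$macro_precision[k] <- ev$macro_precision
    val$macro_recall[k] <- ev$macro_recall
    models[[k]] <- m
  }
  structure(list(models = models, folds = folds, validation = val,
                 mean_validation = colMeans(val[, -1]),
                 levels = lev, feature_space = fs),
            class = "ANNEnsemble")
}

#' Plurality-vote ensemble prediction
#'
#' Each member votes its argmax label per cell; the final label is the
#' plurality winner. Vote ties are broken by the highest ensemble-mean
#' softmax probability among the tied labels and flagged.
#'
#' @param ensemble an `ANNEnsemble` (or plain list of `ANNModel`s sharing one
#'   feature space).
#' @param x_target target-domain `BinarizedMatrix`.
#' @return A list with `table` (data.frame: `barcode`, `label`, `mean_max_p`,
#'   `tie_broken`), `votes` (cells x labels count matrix, rows summing to the
#'   ensemble size) and `mean_probs`.
#' @export
ensemble_predict <- function(ensemble, x_target) {
  models <- if (inherits(ensemble, "ANNEnsemble")) ensemble$models
  else ensemble
  if (length(models) == 0) stop("empty model list")
  lev <- models[[1]]$levels
  n <- nrow(x_target)
  votes <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  psum <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (m in models) {
    p <- ann_forward(m, x_target)
    psum <- psum + p
    am <- max.col(p, ties.method = "first")
    votes[cbind(seq_len(n), am)] <- votes[cbind(seq_len(n), am)] + 1L
  }
  pmean <- psum / length(models)
  top <- apply(votes, 1, max)
  label <- character(n); tie <- logical(n)
  for (i in seq_len(n)) {
    cand <- which(votes[i, ] == top[i])
    if (length(cand) > 1) {
      tie[i] <- TRUE
      cand <- cand[which.max(pmean[i, cand])]
    }
    label[i] <- lev[cand]
  }
  bcs <- rownames(x_target)
  if (is.null(bcs)) bcs <- as.character(seq_len(n))
  list(table = data.frame(barcode = bcs, label = label,
                          mean_max_p = pmean[cbind(seq_len(n),
                                                   match(label, lev))],
                          tie_broken = tie, stringsAsFactors = FALSE),
       votes = votes, mean_probs = pmean)
}

balanced_accuracy <- function(pred, truth, levels) {
  recalls <- vapply(levels, function(cl) {
    in_cl <- truth == cl
    if (!any(in_cl)) return(NA_real_)
    mean(pred[in_cl] == cl)
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}

#' Transfer/classification metrics
#'
#' Balanced accuracy (unweighted mean per-class recall), macro precision and
#' macro recall (unweighted class means), and the confusion matrix. Classes
#' never predicted receive precision 0 with a warning.
#'
#' @param pred_labels,true_labels character/factor label vectors.
#' @param levels label universe (default: union of both).
#' @return List: `balanced_accuracy`, `macro_precision`, `macro_recall`,
#'   `confusion` (truth x prediction table).
#' @export
evaluate_transfer <- function(pred_labels, true_labels, levels = NULL) {
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(pred_labels) == 0) stop("empty input")
  if (length(pred_labels) != length(true_labels))
    stop("label vectors differ in length")
  if (is.null(levels)) levels <- sort(unique(c(pred_labels, true_labels)))
  conf <- table(truth = factor(true_labels, levels),
                prediction = factor(pred_labels, levels))
  recall <- diag(conf) / rowSums(conf)        # NaN for absent truth classes
  prec_den <- colSums(conf)
  precision <- ifelse(prec_den > 0, diag(conf) / prec_den, 0)
  if (any(prec_den == 0 & rowSums(conf) > 0))
    warning("classes never predicted get precision 0: ",
            paste(levels[prec_den == 0 & rowSums(conf) > 0], collapse = ", "))
  present <- rowSums(conf) > 0
  list(balanced_accuracy = mean(recall[present]),
       macro_precision = mean(precision[present]),
       macro_recall = mean(recall[present]),
       confusion = conf)
}

#' Save / load a trained ensemble as a portable text archive
#'
#' Weights, feature space, label set and configs are serialised to a single
#' JSON file (text only, no binary formats), so models round-trip exactly.
#'
#' @param ensemble an `ANNEnsemble`.
#' @param path output `.json` path.
#' @return `save_ensemble()` returns `path` invisibly; `load_ensemble()` the
#'   restored `ANNEnsemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ANNEnsemble"))
  ser_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  ser <- list(levels = as.list(ensemble$levels),
              feature_space = as.list(as.character(ensemble$feature_space)),
              folds = ensemble$folds,
              models = lapply(ensemble$models, function(m)
                list(W1 = ser_mat(m$W1), b1 = m$b1,
                     W2 = ser_mat(m$W2), b2 = m$b2,
                     W3 = ser_mat(m$W3), b3 = m$b3,
                     hidden1 = m$config$hidden1, hidden2 = m$config$hidden2,
                     l1_lambda = m$config$l1_lambda)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_mat <- function(s)
    matrix(unlist(s$data), unlist(s$dim)[1], unlist(s$dim)[2])
  lev <- unlist(ser$levels)
  fs <- if (length(ser$feature_space))
    structure(unlist(ser$feature_space), class = "FeatureSpace") else NULL
  models <- lapply(ser$models, function(raw) {
    w1 <- de_mat(raw$W1); w3 <- de_mat(raw$W3)
    structure(list(W1 = w1, b1 = unlist(raw$b1),
                   W2 = de_mat(raw$W2), b2 = unlist(raw$b2),
                   W3 = w3, b3 = unlist(raw$b3),
                   n_features = nrow(w1), n_labels = ncol(w3),
                   config = ann_config(raw$hidden1, raw$hidden2,
                                       raw$l1_lambda),
                   history = NULL, levels = lev, feature_space = fs),
              class = "ANNModel")
  })
  structure(list(models = models, folds = unlist(ser$folds),
                 validation = NULL, levels = lev, feature_space = fs),
            class = "ANNEnsemble")
}
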