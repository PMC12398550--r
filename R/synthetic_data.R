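#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-data generators.
#' The generators emulate the statistical structure the pipeline assumes:
#' cell classes distinguished by marker detection (negative-binomial counts
#' thinned by logistic dropout), a multiplicative gene-wise batch shift
#' between a labelled source atlas and an unlabelled target domain,
#' human/mouse chimera mixtures with cross-species count leakage, and
#' two-group treatment contrasts.
#'
#' @param n_classes number of cell classes (the reference atlas analogue).
#' @param n_genes number of genes.
#' @param cells_per_class cells simulated per class (and per group for the
#'   two-group generator).
#' @param markers_per_class genes upregulated in exactly one class.
#' @param base_mean negative-binomial mean of a background gene.
#' @param marker_fold fold elevation of a marker in its own class (> 1).
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param dropout_midpoint,dropout_slope logistic dropout on the log mean:
#'   an entry is zeroed with probability
#'   `plogis(dropout_slope * (dropout_midpoint - log(mu)))`.
#' @param domain_shift_sd sd of the log-normal gene-wise factor applied to
#'   target-domain means.
#' @param contamination_fraction fraction of a chimera cell's counts leaking
#'   to the other species' genes (must be < 0.3).
#' @param effect_log2fc log2 fold change of differentially expressed genes in
#'   the two-group generator.
#' @param frac_de_genes fraction of genes differentially expressed.
#' @param n_chimera_cells,human_fraction chimera size and true human share.
#' @param seed integer seed; the generators are pure functions of their
#'   configuration, seed included.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_classes = 8L, n_genes = 500L,
                              cells_per_class = 200L, markers_per_class = 10L,
                              base_mean = 0.2, marker_fold = 8,
                              dispersion = 2, dropout_midpoint = -1.5,
                              dropout_slope = 1.5, domain_shift_sd = 0.3,
                              contamination_fraction = 0.05,
                              effect_log2fc = 1, frac_de_genes = 0.1,
                              n_chimera_cells = 2000L, human_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes), n_genes = as.integer(n_genes),
              cells_per_class = as.integer(cells_per_class),
              markers_per_class = as.integer(markers_per_class),
              base_mean = base_mean, marker_fold = marker_fold,
              dispersion = dispersion, dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope, domain_shift_sd = domain_shift_sd,
              contamination_fraction = contamination_fraction,
              effect_log2fc = effect_log2fc, frac_de_genes = frac_de_genes,
              n_chimera_cells = as.integer(n_chimera_cells),
              human_fraction = human_fraction, seed = as.integer(seed))
  with(cfg, {
    if (n_classes < 1 || n_genes < 1 || cells_per_class < 1)
      stop("config error: sizes must be positive")
    if (markers_per_class * n_classes > n_genes)
      stop("config error: markers_per_class * n_classes (",
           markers_per_class * n_classes, ") exceeds n_genes (", n_genes, ")")
    if (base_mean <= 0 || dispersion <= 0)
      stop("config error: base_mean and dispersion must be positive")
    if (marker_fold <= 0) stop("config error: marker_fold must be positive")
    if (domain_shift_sd < 0) stop("config error: domain_shift_sd must be >= 0")
    if (contamination_fraction < 0 || contamination_fraction >= 0.3)
      stop("config error: contamination_fraction must lie in [0, 0.3)")
    if (frac_de_genes < 0 || frac_de_genes > 1)
      stop("config error: frac_de_genes must lie in [0, 1]")
    if (human_fraction < 0 || human_fraction > 1)
      stop("config error: human_fraction must lie in [0, 1]")
  })
  structure(cfg, class = c("SimulationConfig", "list"))
}

# logistic dropout probability for mean mu
dropout_prob <- function(mu, cfg) {
  stats::plogis(cfg$dropout_slope * (cfg$dropout_midpoint - log(pmax(mu, 1e-12))))
}

# genes x classes matrix of negative-binomial means; baseline means are
# drawn log-normally around base_mean (real transcriptomes span orders of
# magnitude, and the variable-gene trend fit needs that spread), markers are
# elevated marker_fold over their own baseline in their class only.
# Uses the caller's seeded RNG stream.
class_mean_matrix <- function(cfg, base_sdlog = 0.5) {
  baseline <- stats::rlnorm(cfg$n_genes, log(cfg$base_mean), base_sdlog)
  means <- matrix(baseline, cfg$n_genes, cfg$n_classes)
  markers <- data.frame(gene = integer(), class = integer())
  if (cfg$markers_per_class > 0) {
    idx <- seq_len(cfg$markers_per_class * cfg$n_classes)
    cls <- rep(seq_len(cfg$n_classes), each = cfg$markers_per_class)
    means[cbind(idx, cls)] <- baseline[idx] * cfg$marker_fold
    markers <- data.frame(gene = idx, class = cls)
  }
  list(means = means, markers = markers)
}

# draw a sparse genes x cells count matrix from per-cell mean columns,
# thinned entry-wise by logistic dropout on the gene/class log-mean
draw_nb_counts <- function(means, class_of_cell, cfg) {
  n_genes <- nrow(means)
  n_cells <- length(class_of_cell)
  drop_p <- dropout_prob(means, cfg)  # genes x classes
  tl <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    cl <- class_of_cell[j]
    x <- stats::rnbinom(n_genes, mu = means[, cl], size = cfg$dispersion)
    keep <- stats::runif(n_genes) >= drop_p[, cl]
    x[!keep] <- 0L
    nz <- which(x > 0)
    if (length(nz))
      tl[[j]] <- cbind(i = nz, j = rep.int(j, length(nz)), x = x[nz])
  }
  tr <- do.call(rbind, tl)
  if (is.null(tr)) tr <- matrix(0, 0, 3, dimnames = list(NULL, c("i", "j", "x")))
  Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                       dims = c(n_genes, n_cells))
}

#' Simulate a labelled reference (source atlas) dataset
#'
#' Counts are negative binomial with class-specific means (each class's
#' markers at `base_mean * marker_fold`, everything else at `base_mean`),
#' thinned entry-wise by logistic dropout on the log mean. Labels are
#' balanced across classes.
#'
#' @param cfg a [simulation_config()].
#' @return A list with `counts` (a `CountMatrix`), `cells` (annotation
#'   data.frame with `barcode`, `label`, `sample`, `condition`) and `truth`
#'   (ground-truth list: per-cell labels, marker table, class mean matrix).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "reference"))
  mm <- class_mean_matrix(cfg)
  n_cells <- cfg$n_classes * cfg$cells_per_class
  class_of_cell <- rep(seq_len(cfg$n_classes), each = cfg$cells_per_class)
  vals <- draw_nb_counts(mm$means, class_of_cell, cfg)
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  barcodes <- sprintf("src_%05d", seq_len(n_cells))
  labels <- sprintf("class_%02d", class_of_cell)
  counts <- count_matrix(vals, gene_ids, barcodes)
  cells <- data.frame(barcode = barcodes, label = labels,
                      sample = "source", condition = "none",
                      stringsAsFactors = FALSE)
  truth <- list(cells = data.frame(barcode = barcodes, label = labels,
                                   class = class_of_cell,
                                   stringsAsFactors = FALSE),
                markers = transform(mm$markers,
                                    gene_id = gene_ids[mm$markers$gene]),
                class_means = mm$means, gene_ids = gene_ids)
  list(counts = counts, cells = cells, truth = truth)
}

#' Simulate a domain-shifted, unlabelled target dataset
#'
#' Shares the reference's gene set and class structure; every gene's mean is
#' multiplied by a fixed log-normal(0, `domain_shift_sd`) factor, emulating a
#' batch/platform shift between an in vitro dataset and the atlas. True labels
#' are returned only in the ground truth. Classes absent from
#' `classes_present` can emulate a target containing a subset of source
#' classes; the closed label set means such cells must still receive some
#' source label downstream.
#'
#' @param cfg a [simulation_config()].
#' @param reference_truth the `truth` element returned by
#'   [simulate_reference()] under the same config.
#' @param classes_present integer vector of class indices present in the
#'   target (default: all).
#' @return A list with `counts` (a `CountMatrix`, labels withheld), `truth`
#'   (per-cell true labels plus the per-gene shift factors).
#' @export
simulate_target <- function(cfg, reference_truth,
                            classes_present = seq_len(cfg$n_classes)) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!identical(reference_truth$gene_ids,
                 sprintf("gene_%04d", seq_len(cfg$n_genes))))
    stop("validation error: reference gene set does not match config")
  set.seed(derive_seed(cfg$seed, "target"))
  shift <- exp(stats::rnorm(cfg$n_genes, 0, cfg$domain_shift_sd))
  means <- reference_truth$class_means * shift
  class_of_cell <- rep(classes_present, each = cfg$cells_per_class)
  vals <- draw_nb_counts(means, class_of_cell, cfg)
  barcodes <- sprintf("tgt_%05d", seq_along(class_of_cell))
  counts <- count_matrix(vals, reference_truth$gene_ids, barcodes)
  truth <- list(cells = data.frame(barcode = barcodes,
                                   label = sprintf("class_%02d", class_of_cell),
                                   class = class_of_cell,
                                   stringsAsFactors = FALSE),
                shift_factors = shift)
  list(counts = counts, truth = truth)
}

#' Simulate a mixed-species chimera count matrix
#'
#' Each cell's counts are drawn over its true species' genes (multinomial with
#' fixed gene weights), then a `contamination_fraction` of its total counts is
#' reassigned to random genes of the other species, emulating ambient
#' cross-species leakage in a dissociated chimera.
#'
#' @param cfg a [simulation_config()]; requires
#'   `contamination_fraction < 0.3`.
#' @return A list with `counts` (a `CountMatrix` over both species' genes,
#'   ids prefixed `GRCh38_` / `mm10_`) and `truth` (per-cell true species).
#' @export
simulate_chimera <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "chimera"))
  ng <- cfg$n_genes
  gene_ids <- c(sprintf("GRCh38_gene_%04d", seq_len(ng)),
                sprintf("mm10_gene_%04d", seq_len(ng)))
  w_h <- stats::rexp(ng); w_h <- w_h / sum(w_h)
  w_m <- stats::rexp(ng); w_m <- w_m / sum(w_m)
  n <- cfg$n_chimera_cells
  is_human <- stats::runif(n) < cfg$human_fraction
  tl <- vector("list", n)
  for (j in seq_len(n)) {
    total <- stats::rnbinom(1, mu = 1500, size = 10) + 200L
    n_cont <- stats::rbinom(1, total, cfg$contamination_fraction)
    own <- stats::rmultinom(1, total - n_cont,
                            if (is_human[j]) w_h else w_m)[, 1]
    other <- stats::rmultinom(1, n_cont, if (is_human[j]) w_m else w_h)[, 1]
    x <- if (is_human[j]) c(own, other) else c(other, own)
    nz <- which(x > 0)
    tl[[j]] <- cbind(i = nz, j = rep.int(j, length(nz)), x = x[nz])
  }
  tr <- do.call(rbind, tl)
  vals <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                               dims = c(2L * ng, n))
  barcodes <- sprintf("chi_%05d", seq_len(n))
  counts <- count_matrix(vals, gene_ids, barcodes)
  truth <- list(cells = data.frame(barcode = barcodes,
                                   species = ifelse(is_human, "human", "mouse"),
                                   stringsAsFactors = FALSE))
  list(counts = counts, truth = truth)
}

#' Simulate a two-group (treatment vs vehicle) expression dataset
#'
#' Two equal groups; a fraction `frac_de_genes` of genes has its group-2 mean
#' shifted by `effect_log2fc` (direction alternating), all other genes are
#' exactly null — the substrate for hurdle-test calibration and power checks.
#'
#' @param cfg a [simulation_config()]; `cells_per_class` is the per-group
#'   cell count.
#' @return A list with `counts`, `cells` (with a `condition` column in
#'   `c("vehicle","treated")`) and `truth` (per-gene DE status and true
#'   log2FC).
#' @export
simulate_two_group <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "two_group"))
  ng <- cfg$n_genes
  n_per <- cfg$cells_per_class
  # baseline means around 2 UMIs: typical of genes surviving expression QC
  base <- stats::rlnorm(ng, meanlog = log(2), sdlog = 0.8)
  n_de <- round(cfg$frac_de_genes * ng)
  is_de <- rep(FALSE, ng); is_de[seq_len(n_de)] <- TRUE
  sign <- rep(0, ng)
  if (n_de > 0) sign[seq_len(n_de)] <- rep_len(c(1, -1), n_de)
  true_lfc <- sign * cfg$effect_log2fc
  mean1 <- base
  mean2 <- base * 2^true_lfc
  draw_group <- function(means, n_cells) {
    tl <- vector("list", n_cells)
    for (j in seq_len(n_cells)) {
      x <- stats::rnbinom(ng, mu = means, size = cfg$dispersion)
      nz <- which(x > 0)
      tl[[j]] <- cbind(i = nz, j = rep.int(j, length(nz)), x = x[nz])
    }
    do.call(rbind, tl)
  }
  t1 <- draw_group(mean1, n_per)
  t2 <- draw_group(mean2, n_per)
  t2[, 2] <- t2[, 2] + n_per
  tr <- rbind(t1, t2)
  vals <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                               dims = c(ng, 2L * n_per))
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  barcodes <- sprintf("grp_%05d", seq_len(2L * n_per))
  condition <- rep(c("vehicle", "treated"), each = n_per)
  counts <- count_matrix(vals, gene_ids, barcodes)
  cells <- data.frame(barcode = barcodes, label = "bulk",
                      sample = rep(c("s1", "s2"), times = n_per),
                      condition = condition, stringsAsFactors = FALSE)
  truth <- list(genes = data.frame(gene_id = gene_ids, is_de = is_de,
                                   true_log2fc = true_lfc,
                                   stringsAsFactors = FALSE))
  list(counts = counts, cells = cells, truth = truth)
}

#' Simulate an electron-microscopy morphometry table
#'
#' Draws axon diameters from a log-normal, assigns each myelinated axon a true
#' g-ratio from a (truncated) normal, and derives areas assuming circular
#' cross-sections, so the true g-ratio is recoverable exactly from the areas.
#' Mitochondrial areas per axon sum, on average, to `mito_fraction` times the
#' axon area.
#'
#' @param n_axons number of axon profiles.
#' @param g_mean,g_sd mean and sd of the true g-ratio; requires
#'   `0 < g_mean - 3*g_sd` and `g_mean + 3*g_sd < 1`.
#' @param mito_fraction expected mitochondrial area fraction of the axon.
#' @param seed integer seed.
#' @param n_animals animals the axons are split over (balanced).
#' @param myelinated_prob probability an axon carries compact myelin.
#' @param diameter_meanlog,diameter_sdlog log-normal diameter parameters (um).
#' @param conditions condition labels assigned to animals (recycled).
#' @return A list with `profiles` (AxonProfile data.frame: `axon_id`,
#'   `animal_id`, `condition`, `axon_area`, `outer_area`, `mito_areas`
#'   (semicolon-joined um^2), `myelinated`, `compartment`) and `truth`
#'   (per-axon true g-ratio, diameter and mitochondrial fraction).
#' @export
simulate_morphometry <- function(n_axons = 500L, g_mean = 0.8, g_sd = 0.05,
                                 mito_fraction = 0.1, seed = 1L,
                                 n_animals = 6L, myelinated_prob = 0.7,
                                 diameter_meanlog = log(0.8),
                                 diameter_sdlog = 0.35,
                                 conditions = c("vehicle", "treated")) {
  if (g_mean - 3 * g_sd <= 0 || g_mean + 3 * g_sd >= 1)
    stop("config error: need 0 < g_mean +/- 3*g_sd < 1")
  set.seed(derive_seed(seed, "morphometry"))
  d <- stats::rlnorm(n_axons, diameter_meanlog, diameter_sdlog)
  g <- if (g_sd == 0) rep(g_mean, n_axons) else
    pmin(pmax(stats::rnorm(n_axons, g_mean, g_sd), g_mean - 3 * g_sd),
         g_mean + 3 * g_sd)
  myelinated <- stats::runif(n_axons) < myelinated_prob
  axon_area <- pi * (d / 2)^2
  outer_area <- ifelse(myelinated, pi * (d / (2 * g))^2, axon_area)
  frac <- stats::rgamma(n_axons, shape = 4, rate = 4 / mito_fraction)
  frac <- pmin(frac, 0.9)
  n_mito <- 1L + stats::rpois(n_axons, 1)
  mito_areas <- vapply(seq_len(n_axons), function(i) {
    parts <- stats::rgamma(n_mito[i], 1)
    parts <- parts / sum(parts) * frac[i] * axon_area[i]
    paste(formatC(parts, digits = 10, format = "g"), collapse = ";")
  }, character(1))
  animal <- rep_len(seq_len(n_animals), n_axons)
  cond <- rep_len(conditions, n_animals)[animal]
  profiles <- data.frame(
    axon_id = sprintf("axon_%04d", seq_len(n_axons)),
    animal_id = sprintf("animal_%02d", animal),
    condition = cond,
    axon_area = axon_area, outer_area = outer_area,
    mito_areas = mito_areas,
    myelinated = myelinated, compartment = "axon",
    stringsAsFactors = FALSE)
  truth <- data.frame(axon_id = profiles$axon_id,
                      true_diameter = d,
                      true_g = ifelse(myelinated, g, NA_real_),
                      true_mito_fraction = frac,
                      stringsAsFactors = FALSE)
  list(profiles = profiles, truth = truth)
}

#' Parse a semicolon-joined area list
#'
#' @param x character vector of `;`-separated areas (um^2); empty string or
#'   `NA` means no mitochondria.
#' @return A list of numeric vectors.
#' @export
parse_areas <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}
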