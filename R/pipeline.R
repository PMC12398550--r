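#' @keywords internal
stage_simulate <- function(cfg, out_dir) {
  sc <- do.call(simulation_config, c(cfg$simulate, list(seed = cfg$seed)))
  ref <- simulate_reference(sc)
  tgt <- simulate_target(sc, ref$truth)
  chi <- simulate_chimera(sc)
  tg <- simulate_two_group(sc)
  mo <- do.call(simulate_morphometry,
                c(cfg$morphometry[c("n_axons", "g_mean", "g_sd",
                                    "mito_fraction")],
                  list(seed = cfg$seed)))
  sim <- file.path(out_dir, "simulate")
  write_count_matrix(ref$counts, file.path(sim, "reference"))
  write_tsv(ref$cells, file.path(sim, "reference_cells.tsv"))
  write_tsv(ref$truth$cells, file.path(sim, "reference_truth.tsv"))
  write_count_matrix(tgt$counts, file.path(sim, "target"))
  write_tsv(tgt$truth$cells, file.path(sim, "target_truth.tsv"))
  write_count_matrix(chi$counts, file.path(sim, "chimera"))
  write_tsv(chi$truth$cells, file.path(sim, "chimera_truth.tsv"))
  write_count_matrix(tg$counts, file.path(sim, "two_group"))
  write_tsv(tg$cells, file.path(sim, "two_group_cells.tsv"))
  write_tsv(tg$truth$genes, file.path(sim, "two_group_truth.tsv"))
  write_tsv(mo$profiles, file.path(sim, "morphometry_profiles.tsv"))
  write_tsv(mo$truth, file.path(sim, "morphometry_truth.tsv"))
  invisible(sim)
}

read_triplet <- function(dir)
  read_count_matrix(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                    file.path(dir, "barcodes.tsv"))

#' @keywords internal
stage_demux <- function(cfg, out_dir) {
  sim <- file.path(out_dir, "simulate")
  chi <- read_triplet(file.path(sim, "chimera"))
  truth <- read_tsv(file.path(sim, "chimera_truth.tsv"))
  calls <- assign_species(chi, min_fraction = cfg$demux$min_fraction,
                          basis = cfg$demux$basis)
  split <- split_by_species(chi, calls)
  dd <- file.path(out_dir, "demux")
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(calls), file.path(dd, "species_calls.tsv"))
  write_count_matrix(split$human, file.path(dd, "human"))
  write_count_matrix(split$mouse, file.path(dd, "mouse"))
  writeLines(split$ambiguous, file.path(dd, "ambiguous_barcodes.txt"))
  called <- calls$call != "ambiguous"
  acc <- mean(calls$call[called] ==
                truth$species[match(calls$barcode, truth$barcode)][called])
  write_tsv(data.frame(n_cells = nrow(calls),
                       n_ambiguous = sum(!called),
                       accuracy_called = acc),
            file.path(dd, "demux_summary.tsv"))
  invisible(dd)
}

preprocess_counts <- function(m, pp) {
  qc <- qc_filter(m, pp$min_cells_per_gene_exclusive, pp$mad_multiplier,
                  pp$max_mito_fraction, pp$mito_gene_prefix)
  nm <- normalize_counts(qc$counts)
  hvg <- select_variable_genes(nm, pp$n_top_genes)
  list(counts = qc$counts, report = qc$report, nm = nm, hvg = hvg)
}

#' @keywords internal
stage_preprocess <- function(cfg, out_dir) {
  sim <- file.path(out_dir, "simulate")
  pp <- cfg$preprocess
  tgt <- preprocess_counts(read_triplet(file.path(sim, "target")), pp)
  emb <- run_pca(tgt$nm, tgt$hvg, pp$max_pcs, pp$elbow_frac, pp$min_pcs)
  cl <- cluster_cells(emb, pp$k_neighbors, pp$resolution,
                      seed = derive_seed(cfg$seed, "louvain"))
  pd <- file.path(out_dir, "preprocess")
  dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  write_tsv(tgt$report, file.path(pd, "target_qc_report.tsv"))
  writeLines(tgt$hvg, file.path(pd, "hvg_target.txt"))
  write_tsv(cl$cells, file.path(pd, "target_clusters.tsv"))
  write_tsv(data.frame(component = seq_along(emb$explained_variance),
                       explained_variance = emb$explained_variance,
                       selected = seq_along(emb$explained_variance) <=
                         emb$n_pcs_selected),
            file.path(pd, "target_pca_variance.tsv"))
  src <- preprocess_counts(read_triplet(file.path(sim, "reference")), pp)
  writeLines(src$hvg, file.path(pd, "hvg_source.txt"))
  invisible(pd)
}

#' @keywords internal
stage_transfer <- function(cfg, out_dir) {
  sim <- file.path(out_dir, "simulate")
  pd <- file.path(out_dir, "preprocess")
  pp <- cfg$preprocess
  src <- preprocess_counts(read_triplet(file.path(sim, "reference")), pp)
  tgt <- preprocess_counts(read_triplet(file.path(sim, "target")), pp)
  fs <- build_feature_space(readLines(file.path(pd, "hvg_source.txt")),
                            readLines(file.path(pd, "hvg_target.txt")))
  src_cells <- read_tsv(file.path(sim, "reference_cells.tsv"))
  labels <- src_cells$label[match(src$counts$barcodes, src_cells$barcode)]
  x_src <- binarize(src$counts, fs)
  x_tgt <- binarize(tgt$counts, fs)
  acfg <- ann_config(cfg$ann$hidden1, cfg$ann$hidden2, cfg$ann$l1_lambda)
  tc <- training_config(cfg$ann$n_folds, cfg$ann$epochs,
                        cfg$ann$steps_per_epoch, cfg$ann$per_class_per_step,
                        cfg$ann$learning_rate, cfg$ann$rho, cfg$ann$epsilon,
                        seed = derive_seed(cfg$seed, "ann"))
  ens <- train_ensemble(x_src, labels, acfg, tc, fs = fs)
  pred <- ensemble_predict(ens, x_tgt)
  td <- file.path(out_dir, "transfer")
  dir.create(td, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cbind(pred$table, as.data.frame(pred$votes)),
            file.path(td, "predictions.tsv"))
  write_tsv(ens$validation, file.path(td, "fold_validation.tsv"))
  truth <- read_tsv(file.path(sim, "target_truth.tsv"))
  ev <- evaluate_transfer(pred$table$label,
                          truth$label[match(pred$table$barcode,
                                            truth$barcode)], ens$levels)
  write_tsv(data.frame(balanced_accuracy = ev$balanced_accuracy,
                       macro_precision = ev$macro_precision,
                       macro_recall = ev$macro_recall,
                       n_features = length(fs)),
            file.path(td, "target_metrics.tsv"))
  invisible(td)
}

#' @keywords internal
stage_compare <- function(cfg, out_dir) {
  sim <- file.path(out_dir, "simulate")
  pd <- file.path(out_dir, "preprocess")
  pp <- cfg$preprocess
  src <- preprocess_counts(read_triplet(file.path(sim, "reference")), pp)
  tgt <- preprocess_counts(read_triplet(file.path(sim, "target")), pp)
  fs <- build_feature_space(readLines(file.path(pd, "hvg_source.txt")),
                            readLines(file.path(pd, "hvg_target.txt")))
  src_cells <- read_tsv(file.path(sim, "reference_cells.tsv"))
  src_lab <- src_cells$label[match(src$counts$barcodes, src_cells$barcode)]
  pred <- read_tsv(file.path(out_dir, "transfer", "predictions.tsv"))
  tgt_lab <- pred$label[match(tgt$counts$barcodes, pred$barcode)]
  cen_s <- cluster_centroids(src$nm, src_lab, fs)
  cen_t <- cluster_centroids(tgt$nm, tgt_lab, fs)
  s <- cosine_similarity(cen_t, cen_s)
  cd <- file.path(out_dir, "compare")
  dir.create(cd, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(target_cluster = rownames(s),
                       as.data.frame(unclass(s)), check.names = FALSE),
            file.path(cd, "cosine_similarity.tsv"))
  comp <- composition_compare(
    data.frame(label = tgt_lab,
               condition = rep_len(c("groupA", "groupB"), length(tgt_lab))))
  write_tsv(comp$tests, file.path(cd, "composition_tests.tsv"))
  invisible(cd)
}

#' @keywords internal
stage_dge <- function(cfg, out_dir) {
  sim <- file.path(out_dir, "simulate")
  m <- read_triplet(file.path(sim, "two_group"))
  cells <- read_tsv(file.path(sim, "two_group_cells.tsv"))
  m <- filter_genes(m, cfg$preprocess$min_cells_per_gene_exclusive)
  nm <- normalize_counts(m)
  cond <- factor(cells$condition[match(m$barcodes, cells$barcode)],
                 c("vehicle", "treated"))
  res <- condition_contrast(
    nm, cond,
    covariates = data.frame(sample = cells$sample[match(m$barcodes,
                                                        cells$barcode)]),
    thresholds = dge_thresholds(cfg$dge$min_abs_log2fc, cfg$dge$max_adj_p),
    filter = marker_filter(cfg$dge$min_log2fc, cfg$dge$min_pct_in,
                           cfg$dge$max_pct_out))
  dd <- file.path(out_dir, "dge")
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$table, file.path(dd, "contrast_table.tsv"))
  writeLines(res$up, file.path(dd, "upregulated.txt"))
  writeLines(res$down, file.path(dd, "downregulated.txt"))
  invisible(dd)
}

# deterministic in situ puncta table for the composite-score demonstration
simulate_puncta <- function(seed, n_animals = 6L, rois_per_animal = 2L,
                            cells_per_roi = 30L, effect = 1.5) {
  set.seed(derive_seed(seed, "puncta"))
  rows <- list()
  for (a in seq_len(n_animals)) {
    cond <- if (a %% 2 == 0) "treated" else "vehicle"
    lam <- if (cond == "treated") 3 * effect else 3
    for (r in seq_len(rois_per_animal)) {
      n <- cells_per_roi
      rows[[length(rows) + 1]] <- data.frame(
        roi_id = sprintf("a%02d_roi%d", a, r),
        animal_id = sprintf("animal_%02d", a), condition = cond,
        probe = "probeA", olig2_positive = stats::runif(n) < 0.6,
        puncta = stats::rpois(n, lam), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @keywords internal
stage_morphometry <- function(cfg, out_dir) {
  sim <- file.path(out_dir, "simulate")
  prof <- read_tsv(file.path(sim, "morphometry_profiles.tsv"))
  prof$myelinated <- as.logical(prof$myelinated)
  filt <- exclude_small_axons(prof, cfg$morphometry$min_axon_diameter)
  kept <- filt$kept
  md <- file.path(out_dir, "morphometry")
  dir.create(md, recursive = TRUE, showWarnings = FALSE)
  my <- kept[kept$myelinated, ]
  g <- data.frame(axon_id = my$axon_id, animal_id = my$animal_id,
                  condition = my$condition,
                  g_ratio = g_ratio(my$axon_area, my$outer_area),
                  stringsAsFactors = FALSE)
  write_tsv(g, file.path(md, "g_ratios.tsv"))
  g_animal <- do.call(rbind, lapply(split(g, g$animal_id), function(d)
    data.frame(animal_id = d$animal_id[1], condition = d$condition[1],
               mean_g = mean(d$g_ratio), n_axons = nrow(d))))
  write_tsv(g_animal, file.path(md, "g_ratio_per_animal.tsv"))
  mf <- myelinated_fraction(kept)
  write_tsv(mf$per_animal, file.path(md, "myelinated_per_animal.tsv"))
  write_tsv(mf$summary, file.path(md, "myelinated_summary.tsv"))
  mito <- mito_area_fraction(kept)
  write_tsv(mito$per_animal, file.path(md, "mito_per_animal.tsv"))
  cmp_my <- group_compare(mf$per_animal$percent_myelinated,
                          mf$per_animal$condition)
  cmp_g <- group_compare(g_animal$mean_g, g_animal$condition)
  cmp_mito <- group_compare(mito$per_animal$mean_fraction,
                            mito$per_animal$condition)
  punc <- simulate_puncta(cfg$seed)
  cs <- composite_score(punc)
  write_tsv(cs$per_roi, file.path(md, "composite_per_roi.tsv"))
  write_tsv(cs$per_condition, file.path(md, "composite_per_condition.tsv"))
  cmp_cs <- group_compare(cs$per_animal$mean_score, cs$per_animal$condition)
  write_tsv(data.frame(
    measure = c("percent_myelinated", "mean_g_ratio", "mito_fraction",
                "composite_score"),
    test = c(cmp_my$test, cmp_g$test, cmp_mito$test, cmp_cs$test),
    p_value = c(cmp_my$p_value, cmp_g$p_value, cmp_mito$p_value,
                cmp_cs$p_value)),
    file.path(md, "group_tests.tsv"))
  invisible(md)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates every input with known ground truth, then runs species
#' demultiplexing, preprocessing/clustering, ensemble label transfer, cosine
#' cluster comparison, hurdle differential expression and morphometry,
#' writing all declared outputs (TSV / Matrix Market) under `out_dir`. With
#' a fixed config (seed included) all outputs are byte-identical across
#' runs.
#'
#' @param config a [load_config()] result, or path to a YAML/JSON config, or
#'   `NULL` for defaults.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param seed optional seed override.
#' @param stages subset of stages to run, in pipeline order.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL,
                         stages = c("simulate", "demux", "preprocess",
                                    "transfer", "compare", "dge",
                                    "morphometry")) {
  cfg <- if (inherits(config, "RunConfig")) config else load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("oligomatch ", as.character(utils::packageVersion("oligomatch")),
      "\nseed: ", cfg$seed, "\nstages: ", paste(stages, collapse = ", "),
      "\nconfig:\n", yaml::as.yaml(unclass(cfg)), sep = "", file = log_path)
  runners <- list(simulate = stage_simulate, demux = stage_demux,
                  preprocess = stage_preprocess, transfer = stage_transfer,
                  compare = stage_compare, dge = stage_dge,
                  morphometry = stage_morphometry)
  for (st in stages) {
    if (!st %in% names(runners)) stop("unknown stage: ", st)
    runners[[st]](cfg, out_dir)
    log_line(log_path, "completed stage: ", st)
  }
  invisible(out_dir)
}

cli_usage <- function() {
  paste0(
    "usage: oligomatch <subcommand> [--config FILE] [--seed N] ",
    "[--out-dir DIR]\n",
    "subcommands: simulate preprocess demux transfer compare dge ",
    "morphometry run-all\n")
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()]; see `inst/cli/oligomatch.R`
#' for the Rscript wrapper. Unknown subcommands print usage and return a
#' nonzero status.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
omx_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage())
    return(invisible(0L))
  }
  cmd <- argv[1]
  known <- c("simulate", "preprocess", "demux", "transfer", "compare",
             "dge", "morphometry", "run-all")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", cli_usage())
    return(invisible(2L))
  }
  opts <- list(config = NULL, seed = NULL, out_dir = NULL)
  keymap <- c("--config" = "config", "--seed" = "seed",
              "--out-dir" = "out_dir")
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!key %in% names(keymap) || i == length(argv)) {
      message("bad argument: ", key, "\n", cli_usage())
      return(invisible(2L))
    }
    opts[[keymap[[key]]]] <- argv[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    stages <- if (cmd == "run-all")
      c("simulate", "demux", "preprocess", "transfer", "compare", "dge",
        "morphometry")
    else cmd
    run_pipeline(config = opts$config, out_dir = opts$out_dir,
                 seed = if (!is.null(opts$seed)) as.integer(opts$seed),
                 stages = stages)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
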