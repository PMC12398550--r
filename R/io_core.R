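#' Read a 10x-style Matrix Market triplet into a CountMatrix
#'
#' Expects the standard trio: a Matrix Market coordinate file (1-based on
#' disk), a genes table (TSV, first column = gene id) and a barcodes table
#' (TSV, first column = barcode). Species tags are parsed from the gene-id
#' prefix convention (`GRCh38_` / `mm10_`).
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path path to `genes.tsv`.
#' @param barcodes_path path to `barcodes.tsv`.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  if (file.size(matrix_path) == 0) stop("format error: empty matrix file ",
                                        matrix_path)
  vals <- tryCatch(Matrix::readMM(matrix_path),
                   error = function(e) stop("format error reading ",
                                            matrix_path, ": ",
                                            conditionMessage(e)))
  read_ids <- function(p) {
    if (file.size(p) == 0) return(character(0))
    utils::read.table(p, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "")[[1]]
  }
  genes <- read_ids(genes_path)
  bcs <- read_ids(barcodes_path)
  if (length(genes) != nrow(vals))
    stop("format error: matrix has ", nrow(vals), " rows but genes table has ",
         length(genes))
  if (length(bcs) != ncol(vals))
    stop("format error: matrix has ", ncol(vals),
         " columns but barcodes table has ", length(bcs))
  count_matrix(vals, genes, bcs)
}

#' Write a CountMatrix as a Matrix Market triplet
#'
#' Inverse of [read_count_matrix()]: `read(write(m))` is the identity.
#'
#' @param m a `CountMatrix`.
#' @param out_dir output directory (created if absent). Files written:
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_count_matrix <- function(m, out_dir) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "genes.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"))
  v <- m$values
  dimnames(v) <- NULL
  Matrix::writeMM(v, paths[["matrix"]])
  writeLines(m$gene_ids, paths[["genes"]])
  writeLines(m$barcodes, paths[["barcodes"]])
  invisible(paths)
}

#' Write/read a TSV results table with a header row
#'
#' Plain, locale-independent TSV used for every annotation and results table
#' the pipeline emits; numeric formatting is deterministic (15 significant
#' digits) so identical tables hash identically.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` a data.frame.
#' @export
write_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) {
    out <- formatC(col, digits = 15, format = "g")
    out[is.na(col)] <- "NA"
    out
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# --- run configuration ------------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "oligomatch_out",
    simulate = list(n_classes = 8L, n_genes = 500L, cells_per_class = 200L,
                    markers_per_class = 10L, base_mean = 0.2,
                    marker_fold = 8, dispersion = 2,
                    dropout_midpoint = -1.5, dropout_slope = 1.5,
                    domain_shift_sd = 0.3, contamination_fraction = 0.05,
                    effect_log2fc = 1, frac_de_genes = 0.1,
                    n_chimera_cells = 2000L, human_fraction = 0.5),
    preprocess = list(min_cells_per_gene_exclusive = 10L, mad_multiplier = 3,
                      max_mito_fraction = 1, mito_gene_prefix = "MT-",
                      n_top_genes = 2000L, max_pcs = 30L,
                      elbow_frac = 0.001, min_pcs = 5L,
                      k_neighbors = 20L, resolution = 1),
    demux = list(min_fraction = 0.70, basis = "umi_counts"),
    ann = list(hidden1 = 64L, hidden2 = 32L, l1_lambda = 0.001,
               n_folds = 5L, epochs = 100L, steps_per_epoch = 64L,
               per_class_per_step = 16L, learning_rate = 0.001,
               rho = 0.9, epsilon = 1e-7),
    dge = list(min_log2fc = 0.25, min_pct_in = 0.20, max_pct_out = 0.60,
               min_abs_log2fc = 0.5, max_adj_p = 0.05),
    morphometry = list(min_axon_diameter = 0.4, n_axons = 500L,
                       g_mean = 0.8, g_sd = 0.05, mito_fraction = 0.1)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(defaults))
      stop("config error: unknown key '", paste(here, collapse = "."), "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config error: '", paste(here, collapse = "."),
             "' must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON document, rejects unknown keys (reporting the full key
#' path), fills defaults for everything unspecified and coerces the seed to
#' integer. The same config (seed included) always reproduces the same
#' pipeline outputs.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) config file, or `NULL`
#'   for pure defaults.
#' @return A named list of validated parameters (class `RunConfig`).
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(config_defaults(), user)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("config error: seed must be an integer")
  structure(cfg, class = c("RunConfig", "list"))
}

#' Derive a per-stage RNG seed from the global seed
#'
#' Each stochastic stage draws from its own substream so that reordering or
#' skipping stages never perturbs another stage's stream. The derivation is a
#' fixed integer hash of the stage name folded into the global seed, kept
#' below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name (character scalar).
#' @return An integer seed for `set.seed()`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# append a structured line to the run log
log_line <- function(log_path, ...) {
  if (is.null(log_path)) return(invisible())
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
  invisible()
}
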