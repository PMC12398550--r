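#' Construct a CountMatrix
#'
#' A `CountMatrix` bundles a sparse genes x cells matrix of UMI counts with
#' gene identifiers, per-gene species tags and cell barcodes. Species tags
#' follow the barnyard-reference convention for concatenated genomes: gene ids
#' prefixed `GRCh38_` are human, `mm10_` are mouse, anything else is `none`.
#'
#' @param values genes x cells matrix of non-negative integer counts (dense or
#'   any `Matrix` sparse class; stored as `dgCMatrix`).
#' @param gene_ids character vector of unique gene identifiers (length = rows).
#' @param barcodes character vector of unique cell barcodes (length = cols).
#' @param gene_species optional character vector in `c("human","mouse","none")`;
#'   when `NULL`, tags are parsed from the gene-id prefixes.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(values, gene_ids, barcodes, gene_species = NULL) {
  if (is.matrix(values)) values <- Matrix::Matrix(values, sparse = TRUE)
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != rows (", nrow(values), ")")
  if (length(barcodes) != ncol(values))
    stop("barcodes length (", length(barcodes), ") != columns (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", gene_ids[duplicated(gene_ids)][1])
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes: ", barcodes[duplicated(barcodes)][1])
  x <- values@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (is.null(gene_species)) {
    gene_species <- species_from_prefix(gene_ids)
  } else {
    gene_species <- as.character(gene_species)
    if (length(gene_species) != length(gene_ids))
      stop("gene_species length mismatch")
    if (!all(gene_species %in% c("human", "mouse", "none")))
      stop("gene_species must be 'human', 'mouse' or 'none'")
  }
  dimnames(values) <- list(gene_ids, barcodes)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 gene_species = gene_species,
                 barcodes = as.character(barcodes)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  sp <- table(factor(x$gene_species, c("human", "mouse", "none")))
  cat("CountMatrix: ", nrow(x$values), " genes x ", ncol(x$values), " cells (",
      format(Matrix::nnzero(x$values), big.mark = ","), " non-zero)\n",
      "  species tags: human ", sp[["human"]], ", mouse ", sp[["mouse"]],
      ", none ", sp[["none"]], "\n", sep = "")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

# species tag from the concatenated-genome id prefix
species_from_prefix <- function(gene_ids) {
  out <- rep("none", length(gene_ids))
  out[startsWith(gene_ids, "GRCh38_")] <- "human"
  out[startsWith(gene_ids, "mm10_")] <- "mouse"
  out
}

#' Subset a CountMatrix
#'
#' @param m a `CountMatrix`.
#' @param genes,cells indices, logical masks or names; `NULL` keeps all.
#' @return A `CountMatrix` restricted to the requested genes/cells.
#' @export
subset_count_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(m$values)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(m$values)) else cells
  if (is.character(gi)) gi <- match(gi, m$gene_ids)
  if (is.character(ci)) ci <- match(ci, m$barcodes)
  if (is.logical(gi)) gi <- which(gi)
  if (is.logical(ci)) ci <- which(ci)
  if (anyNA(gi) || anyNA(ci)) stop("unknown gene id or barcode in subset")
  count_matrix(m$values[gi, ci, drop = FALSE],
               m$gene_ids[gi], m$barcodes[ci], m$gene_species[gi])
}

#' Validate a cell annotation table against a CountMatrix
#'
#' @param cells data.frame with at least a `barcode` column; optional `label`,
#'   `sample`, `condition`, `species`.
#' @param m companion `CountMatrix`, or `NULL` to skip the membership check.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_cell_table <- function(cells, m = NULL) {
  if (!is.data.frame(cells) || !"barcode" %in% names(cells))
    stop("cell table must be a data.frame with a 'barcode' column")
  if (anyDuplicated(cells$barcode))
    stop("duplicate barcode in cell table: ",
         cells$barcode[duplicated(cells$barcode)][1])
  if (!is.null(m) && !all(cells$barcode %in% m$barcodes))
    stop("cell table contains barcodes absent from the count matrix")
  invisible(cells)
}
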