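#' Allocate chimera cells to a species
#'
#' Computes, per cell, the fraction of species-assignable signal that maps to
#' the human genome — over UMI counts (default) or over detected genes — and
#' calls the cell `human` when that fraction is at least `min_fraction`,
#' `mouse` when the mouse fraction is at least `min_fraction` (the 70%
#' boundary is inclusive on both sides), and `ambiguous` otherwise. Genes
#' without a species tag are ignored; a cell with no species-tagged counts is
#' called ambiguous and flagged.
#'
#' @param m a `CountMatrix` with genes tagged for both species.
#' @param min_fraction call threshold in (0.5, 1]; above 0.5 at most one
#'   species can pass.
#' @param basis `"umi_counts"` (fraction of UMIs) or `"detected_genes"`
#'   (fraction of detected genes).
#' @return data.frame (class `SpeciesCall`): `barcode`, `human_fraction`,
#'   `call`, `no_signal`.
#' @export
assign_species <- function(m, min_fraction = 0.70,
                           basis = c("umi_counts", "detected_genes")) {
  stopifnot(inherits(m, "CountMatrix"))
  basis <- match.arg(basis)
  if (min_fraction <= 0.5 || min_fraction > 1)
    stop("min_fraction must lie in (0.5, 1]")
  hu <- m$gene_species == "human"
  mo <- m$gene_species == "mouse"
  if (!any(hu) || !any(mo))
    stop("matrix must contain genes tagged for both species")
  v <- if (basis == "umi_counts") m$values else m$values > 0
  h <- Matrix::colSums(v[hu, , drop = FALSE])
  mm <- Matrix::colSums(v[mo, , drop = FALSE])
  tot <- h + mm
  frac <- ifelse(tot > 0, h / tot, NA_real_)
  call <- rep("ambiguous", length(frac))
  call[!is.na(frac) & frac >= min_fraction] <- "human"
  call[!is.na(frac) & (1 - frac) >= min_fraction] <- "mouse"
  out <- data.frame(barcode = m$barcodes,
                    human_fraction = ifelse(is.na(frac), 0, frac),
                    call = call, no_signal = tot == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("SpeciesCall", "data.frame")
  out
}

#' Split a chimera matrix by species call
#'
#' Produces one matrix per species containing only that species' genes and
#' its confidently called cells; ambiguous cells are excluded from both and
#' returned as an audit list (the pipeline drops them, mirroring retention of
#' only confidently assigned cells for per-species reanalysis).
#'
#' @param m the chimera `CountMatrix`.
#' @param calls a `SpeciesCall` table covering all barcodes of `m`.
#' @return A list with `human` and `mouse` (`CountMatrix`, possibly with zero
#'   cells, warned) and `ambiguous` (character vector of barcodes).
#' @export
split_by_species <- function(m, calls) {
  stopifnot(inherits(m, "CountMatrix"))
  if (!all(m$barcodes %in% calls$barcode))
    stop("species calls do not cover all barcodes")
  call <- calls$call[match(m$barcodes, calls$barcode)]
  out <- list()
  for (sp in c("human", "mouse")) {
    cells <- call == sp
    if (!any(cells))
      warning("no cells called ", sp, "; returning an empty matrix")
    out[[sp]] <- subset_count_matrix(m, genes = m$gene_species == sp,
                                     cells = cells)
  }
  out$ambiguous <- m$barcodes[call == "ambiguous"]
  out
}
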