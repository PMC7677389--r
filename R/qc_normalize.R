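# Barcode filtering, log normalization, PCA variance accounting, and
# hepatocyte-score-based cell filtering.

#' QC parameters
#'
#' @param min_genes minimum detected genes per barcode (barcodes with fewer
#'   are discarded as non-cells); default 400
#' @param hep_sd_cut cells scoring more than this many standard deviations
#'   below the mean hepatocyte signature score are removed; default 3
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes
#' @return a list of class `qc_params`
#' @export
qc_params <- function(min_genes = 400, hep_sd_cut = 3, mito_prefix = "mt-") {
  if (min_genes < 0) stopf("min_genes must be >= 0")
  if (hep_sd_cut <= 0) stopf("hep_sd_cut must be > 0")
  structure(list(min_genes = min_genes, hep_sd_cut = hep_sd_cut,
                 mito_prefix = mito_prefix), class = "qc_params")
}

#' Discard barcodes with too few detected genes
#'
#' Retains exactly the cells with `nGene >= min_genes`; the gene axis is
#' unchanged and metadata rows are subset accordingly.
#'
#' @param m a `hep_counts` object
#' @param params a `qc_params` object
#' @return a filtered `hep_counts`
#' @export
filter_barcodes <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "hep_counts"))
  keep <- m$cell_meta$nGene >= params$min_genes
  hep_counts(m$counts[, keep, drop = FALSE],
             m$cell_meta[keep, , drop = FALSE])
}

#' Log-normalize counts
#'
#' Per-cell library-size normalization to a fixed scale followed by a
#' natural-log transform: `value = ln(1 + scale * count / nUMI)`. Zero counts
#' stay exactly zero, so sparsity is preserved.
#'
#' @param m a `hep_counts` object; every cell must have `nUMI > 0`
#' @param scale library-size scale factor (default 1e4, a TPM-like per-10k
#'   convention)
#' @return a `hep_norm` object: sparse matrix `values` plus the cell metadata
#' @export
normalize_counts <- function(m, scale = 10000) {
  stopifnot(inherits(m, "hep_counts"))
  tot <- m$cell_meta$nUMI
  if (any(tot == 0)) {
    stopf("cell(s) with zero total counts: %s",
          paste(utils::head(m$cell_meta$barcode[tot == 0], 5), collapse = ", "))
  }
  v <- m$counts
  if (length(v@x)) {
    cell_of <- rep(seq_len(ncol(v)), diff(v@p))
    v@x <- log1p(scale * v@x / tot[cell_of])
  }
  structure(list(values = v, cell_meta = m$cell_meta), class = "hep_norm")
}

#' @export
print.hep_norm <- function(x, ...) {
  cat(sprintf("hep_norm: %d genes x %d cells (log-normalized)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' PCA with per-component variance accounting
#'
#' PCA on gene-standardized normalized expression (each gene centered and
#' scaled to unit variance; zero-variance genes dropped). Component signs are
#' fixed by making the largest-magnitude loading of each component positive,
#' so results are fully deterministic.
#'
#' @param nm a `hep_norm` object
#' @param n_pcs number of components to return (default 13)
#' @return list of class `hep_pca`: `n_pcs`, `variance_fraction` (each
#'   eigenvalue over the total across all components), `loadings`
#'   (gene x PC, unit-norm columns), `scores` (cell x PC), `genes_used`
#' @export
pca_variance <- function(nm, n_pcs = 13) {
  stopifnot(inherits(nm, "hep_norm"))
  n_cells <- ncol(nm$values)
  if (n_cells < 2) stopf("PCA requires at least 2 cells")
  x <- t(as.matrix(nm$values))      # cells x genes
  vs <- apply(x, 2, stats::var)
  keep <- vs > 0
  if (!any(keep)) stopf("no gene with nonzero variance")
  x <- scale(x[, keep, drop = FALSE])
  if (n_pcs > min(dim(x))) {
    stopf("n_pcs = %d exceeds min(cells, usable genes) = %d", n_pcs, min(dim(x)))
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  loadings <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(nm$values)
  structure(list(n_pcs = n_pcs,
                 variance_fraction = ev[seq_len(n_pcs)] / sum(ev),
                 all_variance_fraction = ev / sum(ev),
                 loadings = loadings,
                 scores = scores,
                 genes_used = rownames(nm$values)[keep]),
            class = "hep_pca")
}

#' Remove non-hepatocytes by signature score
#'
#' Cells whose hepatocyte signature score falls more than `hep_sd_cut`
#' standard deviations below the mean (both over all input cells) are
#' removed as non-hepatocytes.
#'
#' @param nm a `hep_norm` object
#' @param hep_score a `module_score_vector` aligned to the cells of `nm`
#' @param params a `qc_params` object
#' @return a filtered `hep_norm`; attribute `n_removed` records how many
#'   cells were dropped
#' @export
filter_hepatocytes <- function(nm, hep_score, params = qc_params()) {
  stopifnot(inherits(nm, "hep_norm"))
  s <- as.numeric(if (is.list(hep_score)) hep_score$score else hep_score)
  if (length(s) != ncol(nm$values)) stopf("score not aligned to cells")
  if (length(s) < 2) stopf("need at least 2 cells to estimate score spread")
  mu <- mean(s)
  sdv <- stats::sd(s)
  if (sdv == 0) {
    warnf("hepatocyte score is constant; no cells filtered")
    keep <- rep(TRUE, length(s))
  } else {
    keep <- s >= mu - params$hep_sd_cut * sdv
  }
  out <- structure(list(values = nm$values[, keep, drop = FALSE],
                        cell_meta = nm$cell_meta[keep, , drop = FALSE]),
                   class = "hep_norm")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-barcode QC report
#'
#' @param m a `hep_counts` object
#' @param params a `qc_params` object
#' @return data.frame with barcode, nGene, nUMI, pct_mito and whether the
#'   barcode passes the gene-count filter
#' @export
qc_report <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "hep_counts"))
  data.frame(barcode = m$cell_meta$barcode,
             nGene = m$cell_meta$nGene,
             nUMI = m$cell_meta$nUMI,
             pct_mito = m$cell_meta$pct_mito,
             retained = m$cell_meta$nGene >= params$min_genes,
             stringsAsFactors = FALSE)
}
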