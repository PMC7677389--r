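# Gene-signature machinery: bin-matched-control module scores, the
# Cyp2e1-anchored correlation screen that derives pericentral/periportal
# signatures, zonation-table-derived signatures, the composite
# periportal-minus-pericentral score, the percent-positive statistic, and
# score agreement.

#' Define a gene signature
#'
#' @param name signature name
#' @param genes character vector of gene symbols (case-sensitive, exact)
#' @param provenance one of "fixed", "correlation_derived", "zonation_table"
#' @return a list of class `signature_definition`
#' @export
signature_definition <- function(name, genes,
                                 provenance = c("fixed", "correlation_derived",
                                                "zonation_table")) {
  provenance <- match.arg(provenance)
  genes <- unique(as.character(genes))
  if (!length(genes)) stopf("signature '%s' has no genes", name)
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "signature_definition")
}

#' The fixed hepatocyte signature
#'
#' Highly expressed hepatocyte genes spanning the whole lobule, used to score
#' how "hepatocyte-like" each cell is and to filter non-hepatocytes.
#'
#' @return a `signature_definition`
#' @export
hepatocyte_signature <- function() {
  signature_definition(
    "Hepatocyte",
    c("Apoa1", "Glul", "Acly", "Asl", "Cyp2e1", "Cyp2f2",
      "Ass1", "Alb", "Mup3", "Pck1", "G6pc", "Fabp1"),
    provenance = "fixed")
}

#' Bin-matched-control module score
#'
#' Scores each cell on a gene program as the mean normalized expression of
#' the program genes minus the mean expression of control genes matched on
#' overall expression level. All genes are binned into `n_bins` quantile bins
#' by their mean expression across cells; for each program gene, `n_ctrl`
#' control genes are drawn from the same bin (excluding program genes; with
#' replacement when the bin has fewer candidates). The subtraction removes
#' the component of the program mean explained by expression level alone.
#'
#' @param nm a `hep_norm` object
#' @param sig a `signature_definition`; genes missing from the matrix are
#'   dropped with a warning, at least one must remain
#' @param n_bins number of expression bins (default 25)
#' @param n_ctrl control genes drawn per program gene (default 100)
#' @param seed RNG seed for the control draw
#' @return a list of class `module_score_vector`: per-cell `score`,
#'   `signature`, and the scoring parameters
#' @export
module_score <- function(nm, sig, n_bins = 25, n_ctrl = 100, seed = 1) {
  stopifnot(inherits(nm, "hep_norm"))
  if (n_bins < 1) stopf("n_bins must be >= 1")
  genes <- rownames(nm$values)
  present <- intersect(sig$genes, genes)
  if (length(present) < length(sig$genes)) {
    warnf("signature '%s': %d of %d genes absent from matrix",
          sig$name, length(sig$genes) - length(present), length(sig$genes))
  }
  if (!length(present)) stopf("signature '%s' empty after intersecting with matrix", sig$name)
  gmeans <- Matrix::rowMeans(nm$values)
  # quantile bins with equal gene counts; ties broken by stable order
  bin <- as.integer(cut(rank(gmeans, ties.method = "first"),
                        breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  names(bin) <- genes
  ctrl_pool_by_bin <- split(setdiff(genes, present), bin[setdiff(genes, present)])
  bin_members <- split(genes, bin)
  ctrl_genes <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- ctrl_pool_by_bin[[as.character(bin[[g]])]]
      if (is.null(pool) || !length(pool)) {
        # the whole bin is signature genes: fall back to excluding only the
        # gene itself so scoring remains defined
        pool <- setdiff(bin_members[[as.character(bin[[g]])]], g)
        if (!length(pool)) stopf("no control candidates in expression bin of gene %s", g)
        warnf("expression bin of gene %s holds only signature genes; controls drawn from the bin excluding %s", g, g)
      }
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })
  prog_mean <- Matrix::colMeans(nm$values[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(nm$values[ctrl_genes, , drop = FALSE])
  structure(list(score = as.numeric(prog_mean - ctrl_mean),
                 cells = colnames(nm$values),
                 signature = sig$name,
                 genes_used = present,
                 n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = "module_score_vector")
}

#' @export
print.module_score_vector <- function(x, ...) {
  cat(sprintf("module score '%s' over %d cells (%d genes): mean %.4f, sd %.4f\n",
              x$signature, length(x$score), length(x$genes_used),
              mean(x$score), stats::sd(x$score)))
  invisible(x)
}

#' Gene-by-gene correlation screen against an anchor gene
#'
#' Pearson correlation of every gene with a zonation anchor (default Cyp2e1,
#' the canonical pericentral gene) across all cells, plus the summary used to
#' place signature cutoffs relative to the correlation distribution.
#'
#' @param nm a `hep_norm` object
#' @param anchor anchor gene symbol
#' @param method "pearson" (default) or "spearman"
#' @return list of class `correlation_screen`: per-gene `r`, logical
#'   `zero_variance` flag, and `summary` with mean, sd, mean+3sd, mean-3sd
#' @export
anchor_correlation_screen <- function(nm, anchor = "Cyp2e1",
                                      method = c("pearson", "spearman")) {
  stopifnot(inherits(nm, "hep_norm"))
  method <- match.arg(method)
  genes <- rownames(nm$values)
  if (!anchor %in% genes) stopf("anchor gene %s not in matrix", anchor)
  x <- as.matrix(nm$values)
  a <- x[anchor, ]
  if (stats::sd(a) == 0) stopf("anchor gene %s has zero variance", anchor)
  if (method == "spearman") {
    a <- rank(a)
    x <- t(apply(x, 1, rank))
  }
  vs <- apply(x, 1, stats::sd)
  r <- rep(0, length(genes))
  names(r) <- genes
  ok <- vs > 0
  r[ok] <- suppressWarnings(as.numeric(stats::cor(t(x[ok, , drop = FALSE]), a)))
  r[anchor] <- 1
  mu <- mean(r)
  sdv <- stats::sd(r)
  structure(list(anchor = anchor, r = r, zero_variance = !ok,
                 method = method,
                 summary = c(mean = mu, sd = sdv,
                             mean_plus_3sd = mu + 3 * sdv,
                             mean_minus_3sd = mu - 3 * sdv)),
            class = "correlation_screen")
}

#' Derive pericentral and periportal signatures from the anchor screen
#'
#' Genes correlated with the anchor above `r_cut` seed the pericentral
#' signature; genes below `-r_cut` seed the periportal signature. Both lists
#' are then restricted to moderately expressed, variable genes: detected in
#' at least `min_frac_cells` of cells, mean expression at or above the
#' `min_mean_quantile` quantile of gene means, and variance/mean dispersion
#' at or above the `min_dispersion_quantile` quantile of that ratio. The
#' anchor is always part of the pericentral signature.
#'
#' @param screen a `correlation_screen`
#' @param nm the `hep_norm` the screen was computed on
#' @param r_cut absolute correlation cutoff (default 0.3)
#' @param min_frac_cells minimum detection fraction (default 0.05)
#' @param min_mean_quantile quantile of gene means below which genes are
#'   considered lowly expressed (default 0.40)
#' @param min_dispersion_quantile quantile of the variance/mean ratio below
#'   which genes are considered invariant (default 0.50)
#' @return list with `signature_definition` elements `pch` and `pph`
#' @export
derive_zonal_signatures <- function(screen, nm, r_cut = 0.3,
                                    min_frac_cells = 0.05,
                                    min_mean_quantile = 0.40,
                                    min_dispersion_quantile = 0.50) {
  stopifnot(inherits(screen, "correlation_screen"), inherits(nm, "hep_norm"))
  genes <- rownames(nm$values)
  if (!identical(names(screen$r), genes)) stopf("screen and matrix not aligned")
  x <- nm$values
  n <- ncol(x)
  frac_det <- Matrix::rowSums(x > 0) / n
  gmean <- Matrix::rowMeans(x)
  gvar <- Matrix::rowMeans(x^2) - gmean^2
  gvar <- gvar * n / max(1, n - 1)
  disp <- ifelse(gmean > 0, gvar / gmean, 0)
  expr_ok <- frac_det >= min_frac_cells &
    gmean >= stats::quantile(gmean, min_mean_quantile) &
    disp >= stats::quantile(disp, min_dispersion_quantile)
  pch <- genes[screen$r > r_cut & expr_ok]
  pph <- genes[screen$r < -r_cut & expr_ok]
  pch <- union(screen$anchor, pch)
  if (!length(pph)) stopf("no periportal genes survive the screen and expression filters")
  list(pch = signature_definition("PCHSig", pch, "correlation_derived"),
       pph = signature_definition("PPHSig", pph, "correlation_derived"))
}

#' Composite periportal-minus-pericentral score
#'
#' Subtracting the pericentral score from the periportal score gives a single
#' axis on which pericentral hepatocytes score negatively and periportal
#' hepatocytes positively.
#'
#' @param pph,pch `module_score_vector`s over the same cells
#' @return a `module_score_vector` named "PPH-PCH"
#' @export
composite_zonation_score <- function(pph, pch) {
  if (!identical(pph$cells, pch$cells)) stopf("score vectors not over the same cells")
  structure(list(score = pph$score - pch$score, cells = pph$cells,
                 signature = "PPH-PCH", genes_used = union(pph$genes_used, pch$genes_used),
                 n_bins = pph$n_bins, n_ctrl = pph$n_ctrl, seed = pph$seed),
            class = "module_score_vector")
}

#' Zonal signatures from a reference zonation table
#'
#' Builds pericentral/periportal signatures from a published zonation table
#' (per-gene layer-mean profiles with a zonation q-value, layers ordered
#' pericentral to periportal). Keeps non-randomly zonated genes
#' (`q < q_cut`) whose mean expression in the scored dataset is at least the
#' average over gene means, then assigns each gene to the lobule half holding
#' more of its profile mass; exact ties are dropped.
#'
#' @param z data.frame: column `gene`, column `q`, remaining numeric columns
#'   the per-layer mean profile ordered pericentral to periportal
#' @param nm the `hep_norm` the signatures will score
#' @param q_cut zonation q-value cutoff (default 0.01)
#' @return list with `signature_definition` elements `pch` and `pph`
#' @export
halpern_signatures <- function(z, nm, q_cut = 0.01) {
  stopifnot(is.data.frame(z), inherits(nm, "hep_norm"))
  if (!all(c("gene", "q") %in% names(z))) stopf("table needs 'gene' and 'q' columns")
  layer_cols <- setdiff(names(z), c("gene", "q"))
  if (length(layer_cols) < 2) stopf("table needs at least 2 layer columns")
  prof <- as.matrix(z[, layer_cols, drop = FALSE])
  gmean <- Matrix::rowMeans(nm$values)
  keep <- z$q < q_cut & z$gene %in% rownames(nm$values)
  keep[keep] <- gmean[z$gene[keep]] >= mean(gmean)
  if (!any(keep)) stopf("no genes pass the q-value and expression filters")
  L <- length(layer_cols)
  half <- floor(L / 2)
  pc_mass <- rowSums(prof[, seq_len(half), drop = FALSE])
  pp_mass <- rowSums(prof[, (L - half + 1):L, drop = FALSE])
  pch <- z$gene[keep & pc_mass > pp_mass]
  pph <- z$gene[keep & pp_mass > pc_mass]
  if (!length(pch) || !length(pph)) stopf("a zonal half is empty after filtering")
  list(pch = signature_definition("PCH_Halpern", pch, "zonation_table"),
       pph = signature_definition("PPH_Halpern", pph, "zonation_table"))
}

#' Percent-positive statistic per condition
#'
#' The positivity threshold is the gene's mean normalized expression over all
#' cells pooled across conditions (one global threshold); a cell is positive
#' when strictly above it. Returns, per condition, 100 times the fraction of
#' positive cells.
#'
#' @param nm a `hep_norm` object
#' @param gene gene symbol
#' @param condition_labels per-cell condition labels; defaults to the
#'   `condition` metadata column
#' @return named numeric vector of percentages, one per condition present
#' @export
percent_positive <- function(nm, gene, condition_labels = NULL) {
  stopifnot(inherits(nm, "hep_norm"))
  if (!gene %in% rownames(nm$values)) stopf("gene %s not in matrix", gene)
  labels <- condition_labels %||% nm$cell_meta$condition
  if (length(labels) != ncol(nm$values)) stopf("labels not aligned to cells")
  v <- as.numeric(nm$values[gene, ])
  thr <- mean(v)
  conds <- unique(as.character(labels))
  out <- vapply(conds, function(cc) {
    idx <- labels == cc
    100 * sum(v[idx] > thr) / sum(idx)
  }, numeric(1))
  names(out) <- conds
  out
}

#' Agreement between two score vectors
#'
#' Squared Pearson correlation with a two-sided p-value from the t transform
#' of r.
#'
#' @param a,b `module_score_vector`s (or plain numeric vectors) over the same
#'   cells, n >= 3
#' @return list with `r2` and `p`
#' @export
score_agreement <- function(a, b) {
  av <- as.numeric(if (is.list(a)) a$score else a)
  bv <- as.numeric(if (is.list(b)) b$score else b)
  if (length(av) != length(bv)) stopf("score vectors differ in length")
  n <- length(av)
  if (n < 3) stopf("need at least 3 cells")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) stopf("zero variance in a score vector")
  r <- stats::cor(av, bv)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r2 = r^2, p = 2 * stats::pt(-abs(tt), df = n - 2))
}
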