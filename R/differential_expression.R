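# Wilcoxon rank-sum differential expression with detection-fraction and
# log-fold-change pre-filters, Bonferroni adjustment over all genes in the
# matrix, cross-time-point pooling with a max-|logFC| conflict rule, the
# shared/unique partition between injury models, and Cohen's d.

# Exact two-sided rank-sum p by enumeration of all group-label assignments
# (used when both groups are small; handles ties because it permutes the
# observed ranks themselves).
exact_ranksum_p <- function(xa, xb) {
  na <- length(xa)
  pooled <- c(xa, xb)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  ws <- colSums(matrix(rk[combos], nrow = na))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction.
approx_ranksum_p <- function(xa, xb) {
  na <- length(xa); nb <- length(xb); n <- na + nb
  rk <- rank(c(xa, xb))
  w <- sum(rk[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U for group a
  mu <- na * nb / 2
  ties <- table(rk)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' A gene is tested only if it is detected in at least `min_pct` of cells in
#' at least one group and its average log fold-change magnitude is at least
#' `logfc_thresh`. The fold change is computed on the expression scale:
#' `avg_logFC = ln(mean_a(exp(x) - 1) + 1) - ln(mean_b(exp(x) - 1) + 1)` on
#' normalized values `x`. Two-sided p-values come from exact enumeration when
#' both groups have at most `exact_max` cells, otherwise from the normal
#' approximation with tie and continuity correction. Adjustment is
#' Bonferroni over all genes in the matrix (tested or not).
#'
#' @param nm a `hep_norm` object
#' @param group_a,group_b disjoint character vectors of barcodes, each with
#'   at least 3 cells
#' @param min_pct minimum detection fraction (default 0.10)
#' @param logfc_thresh minimum |avg_logFC| to test (default 0.25)
#' @param exact_max exact-enumeration group-size bound (default 8)
#' @return data.frame (class `de_result`): gene, avg_logFC, pct_1, pct_2,
#'   p, p_adj, direction; one row per tested gene, sorted by p
#' @export
wilcoxon_de <- function(nm, group_a, group_b, min_pct = 0.10,
                        logfc_thresh = 0.25, exact_max = 8) {
  stopifnot(inherits(nm, "hep_norm"))
  cells <- colnames(nm$values)
  ia <- match(group_a, cells); ib <- match(group_b, cells)
  if (anyNA(ia) || anyNA(ib)) stopf("unknown barcode in group")
  if (length(intersect(ia, ib))) stopf("groups overlap")
  if (length(ia) < 3 || length(ib) < 3) stopf("each group needs >= 3 cells")
  xa <- nm$values[, ia, drop = FALSE]
  xb <- nm$values[, ib, drop = FALSE]
  pct1 <- Matrix::rowSums(xa > 0) / length(ia)
  pct2 <- Matrix::rowSums(xb > 0) / length(ib)
  lfc <- log(Matrix::rowMeans(expm1(xa)) + 1) - log(Matrix::rowMeans(expm1(xb)) + 1)
  test <- (pmax(pct1, pct2) >= min_pct) & (abs(lfc) >= logfc_thresh)
  genes <- rownames(nm$values)[test]
  n_genes_total <- nrow(nm$values)
  use_exact <- length(ia) <= exact_max && length(ib) <= exact_max
  pv <- vapply(genes, function(g) {
    va <- as.numeric(xa[g, ]); vb <- as.numeric(xb[g, ])
    if (use_exact) exact_ranksum_p(va, vb) else approx_ranksum_p(va, vb)
  }, numeric(1))
  out <- data.frame(gene = genes,
                    avg_logFC = lfc[test],
                    pct_1 = pct1[test],
                    pct_2 = pct2[test],
                    p = unname(pv),
                    p_adj = pmin(1, unname(pv) * n_genes_total),
                    direction = ifelse(lfc[test] >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  attr(out, "n_genes_total") <- n_genes_total
  out
}

#' Pool differential-expression results across time points
#'
#' Takes the union of significant genes over the per-time-point tables of
#' one injury model. A gene significant at several time points keeps the
#' record with the largest |avg_logFC| (so a gene up at one time and down at
#' another is retained once, in the direction of its strongest change);
#' exactly tied magnitudes fall to the earliest time point.
#'
#' @param results named list of `de_result` tables; names are time-point
#'   labels, in chronological order
#' @param sig_cut significance cutoff on `p_adj` (default 0.05)
#' @param model injury-model label stored on the output
#' @return data.frame (class `pooled_de`): per retained gene the winning
#'   record plus `time_point` and `n_time_points_significant`
#' @export
pool_time_points <- function(results, sig_cut = 0.05, model = "injury") {
  if (!length(results)) stopf("no DE tables supplied")
  if (is.null(names(results))) names(results) <- paste0("t", seq_along(results))
  rows <- list()
  for (tp_i in seq_along(results)) {
    tab <- results[[tp_i]]
    sig <- tab[tab$p_adj < sig_cut, , drop = FALSE]
    if (!nrow(sig)) next
    sig$time_point <- names(results)[tp_i]
    sig$.tp_order <- tp_i
    rows[[length(rows) + 1L]] <- sig
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(0), avg_logFC = numeric(0),
                      pct_1 = numeric(0), pct_2 = numeric(0), p = numeric(0),
                      p_adj = numeric(0), direction = character(0),
                      time_point = character(0),
                      n_time_points_significant = integer(0))
    class(out) <- c("pooled_de", "data.frame")
    attr(out, "model") <- model
    return(out)
  }
  all_sig <- do.call(rbind, rows)
  keep <- do.call(rbind, lapply(split(all_sig, all_sig$gene), function(d) {
    # largest |logFC| wins; earliest time point breaks exact ties
    d <- d[order(-abs(d$avg_logFC), d$.tp_order), , drop = FALSE]
    r <- d[1L, , drop = FALSE]
    r$n_time_points_significant <- nrow(d)
    r
  }))
  keep$.tp_order <- NULL
  keep <- keep[order(keep$gene), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("pooled_de", "data.frame")
  attr(keep, "model") <- model
  keep
}

#' Partition pooled DE genes into shared and model-unique sets
#'
#' @param apap,ph `pooled_de` tables (or anything with a `gene` column)
#' @return list of character vectors: `shared`, `apap_only`, `ph_only`
#' @export
venn_partition <- function(apap, ph) {
  ga <- unique(as.character(if (is.data.frame(apap)) apap$gene else apap))
  gp <- unique(as.character(if (is.data.frame(ph)) ph$gene else ph))
  list(shared = sort(intersect(ga, gp)),
       apap_only = sort(setdiff(ga, gp)),
       ph_only = sort(setdiff(gp, ga)))
}

#' Cohen's d with star-threshold annotation
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled (n-1-weighted) standard deviation, plus the number of the effect
#' thresholds 0.2, 0.5, 0.8 that |d| exceeds.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2
#' @return list with `d` and `stars` (0-3)
#' @export
cohens_d <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 values")
  s2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (s2 == 0) stopf("pooled standard deviation is zero; effect size undefined")
  d <- (mean(values_a) - mean(values_b)) / sqrt(s2)
  list(d = d, stars = sum(abs(d) > c(0.2, 0.5, 0.8)))
}
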