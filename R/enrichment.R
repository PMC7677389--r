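# Gene-set analysis: Fisher combination of gene-level p-values, empirical
# significance by gene sampling, Benjamini-Hochberg adjustment, and the
# shared/unique gene-set parsing across injury models.

P_FLOOR <- 1e-300

#' Fisher combined statistic for a gene set
#'
#' `stat = -2 * sum(ln p_g)` over the set genes carrying a p-value. Under
#' independent uniform p-values the statistic is chi-squared with 2k degrees
#' of freedom; significance here is instead assessed empirically by gene
#' sampling, which makes no independence assumption.
#'
#' @param gene_p named numeric vector of gene-level p-values in (0, 1]
#' @param set_genes character vector of set gene symbols
#' @return the statistic (0 when no set gene is tested)
#' @export
fisher_set_stat <- function(gene_p, set_genes) {
  p <- gene_p[intersect(set_genes, names(gene_p))]
  if (!length(p)) stopf("no set gene carries a p-value")
  if (any(p <= 0)) stopf("p-value of 0 encountered; floor p-values before combining")
  if (any(p > 1)) stopf("p-values must be in (0, 1]")
  -2 * sum(log(p))
}

#' Empirical gene-sampling p-value for a set statistic
#'
#' Draws `n_perm` random gene subsets of the set's size (without
#' replacement, from all tested genes), recomputes the Fisher statistic for
#' each, and returns `(1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param stat observed statistic
#' @param gene_p named numeric vector of gene-level p-values (the universe)
#' @param set_size number of genes to draw per permutation
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed
#' @return empirical p-value in `(1/(n_perm+1), 1]`
#' @export
gene_sampling_p <- function(stat, gene_p, set_size, n_perm = 10000, seed = 1) {
  n <- length(gene_p)
  if (set_size > n) stopf("set_size %d exceeds universe of %d genes", set_size, n)
  neg2logp <- -2 * log(pmax(gene_p, P_FLOOR))
  perm <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n, set_size))
    if (set_size == 1L) neg2logp[idx] else colSums(matrix(neg2logp[idx], nrow = set_size))
  })
  (1 + sum(perm >= stat)) / (n_perm + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return vector of q-values in the input order
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set analysis over a collection
#'
#' Runs the Fisher statistic + gene-sampling significance + BH adjustment
#' for every set in a collection against gene-level p-values. Genes in the
#' matrix that were filtered before testing should enter the universe with
#' p = 1 (they carry no evidence); p-values are floored at 1e-300 before
#' taking logs.
#'
#' @param gene_p named numeric vector: gene-level p-values over the tested
#'   universe
#' @param sets a `gene_set_collection` (see [read_gmt()])
#' @param n_perm permutations per set (default 10000)
#' @param seed RNG seed; each set uses a sub-seed derived from its name
#' @param min_set_genes sets with fewer scored genes are skipped (default 2)
#' @return data.frame (class `enrichment_result`): set, n_genes_in_set,
#'   stat, p_empirical, q
#' @export
gene_set_analysis <- function(gene_p, sets, n_perm = 10000, seed = 1,
                              min_set_genes = 2) {
  gene_p <- pmax(gene_p, P_FLOOR)
  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]]$genes, names(gene_p))
    if (length(genes) < min_set_genes) return(NULL)
    stat <- fisher_set_stat(gene_p, genes)
    p_emp <- gene_sampling_p(stat, gene_p, length(genes), n_perm = n_perm,
                             seed = derive_seed(seed, nm))
    data.frame(set = nm, n_genes_in_set = length(genes), stat = stat,
               p_empirical = p_emp, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stopf("no gene set overlaps the tested universe")
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p_empirical)
  out <- out[order(out$p_empirical, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Shared and model-unique significant gene sets
#'
#' A set is shared when significant (`q < q_sig`) in both injury models. A
#' set is unique to one model when significant there and showing no trend in
#' the other (`q >= q_excl` in the other model); the exclusion band keeps
#' near-significant sets out of the unique lists.
#'
#' @param apap,ph `enrichment_result` tables over the same set universe
#' @param q_sig significance cutoff (default 0.05)
#' @param q_excl exclusion cutoff for unique calls (default 0.2)
#' @return list of character vectors: `shared`, `apap_unique`, `ph_unique`
#' @export
shared_unique_sets <- function(apap, ph, q_sig = 0.05, q_excl = 0.2) {
  qa <- stats::setNames(apap$q, apap$set)
  qp <- stats::setNames(ph$q, ph$set)
  common <- intersect(names(qa), names(qp))
  qa <- qa[common]; qp <- qp[common]
  list(shared = sort(common[qa < q_sig & qp < q_sig]),
       apap_unique = sort(common[qa < q_sig & qp >= q_excl]),
       ph_unique = sort(common[qp < q_sig & qa >= q_excl]))
}
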