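# Cell-cycle scoring and cycling-cell classification: a module score over
# S/G2M marker genes, a pooled mean + k*SD threshold, and matched
# non-cycling subsampling for paired comparisons.

#' Cell-cycle module score
#'
#' A bin-matched-control module score (see [module_score()]) over a cell
#' cycle marker gene list. A GMT with a standard S + G2M marker panel ships
#' with the package (`system.file("extdata", "cell_cycle_genes.gmt",
#' package = "hepcompass")`) and can be replaced by any user list.
#'
#' @param nm a `hep_norm` object
#' @param cc_genes a `signature_definition` of cell-cycle markers; default
#'   loads the shipped panel
#' @param seed RNG seed for the control draw
#' @param ... passed to [module_score()]
#' @return a `module_score_vector`
#' @export
cell_cycle_score <- function(nm, cc_genes = NULL, seed = 1, ...) {
  if (is.null(cc_genes)) {
    path <- system.file("extdata", "cell_cycle_genes.gmt", package = "hepcompass")
    gmt <- read_gmt(path)
    cc_genes <- signature_definition("CellCycle",
                                     unique(unlist(lapply(gmt, `[[`, "genes"))),
                                     provenance = "fixed")
  }
  out <- module_score(nm, cc_genes, seed = seed, ...)
  out$signature <- "CellCycle"
  out
}

#' Classify cycling cells by a pooled score threshold
#'
#' Cells scoring more than `k_sd` standard deviations above the mean
#' cell-cycle score (mean and SD over all cells pooled across conditions)
#' are called cycling. With a constant score no cell is called cycling.
#'
#' @param score a `module_score_vector`
#' @param k_sd threshold in standard deviations (default 2)
#' @param condition_labels per-cell condition labels (optional; enables the
#'   per-condition cycling fractions)
#' @return list of class `cycling_call`: `threshold`, logical `is_cycling`,
#'   `cells`, and `fraction_cycling` per condition
#' @export
classify_cycling <- function(score, k_sd = 2, condition_labels = NULL) {
  s <- as.numeric(if (is.list(score)) score$score else score)
  if (length(s) < 2) stopf("need at least 2 cells")
  mu <- mean(s); sdv <- stats::sd(s)
  if (sdv == 0) {
    warnf("cell-cycle score is constant; no cell classified as cycling")
    thr <- Inf
  } else {
    thr <- mu + k_sd * sdv
  }
  cyc <- s > thr
  frac <- if (!is.null(condition_labels)) {
    vapply(split(cyc, as.character(condition_labels)), mean, numeric(1))
  } else {
    c(all = mean(cyc))
  }
  structure(list(threshold = thr, is_cycling = cyc,
                 cells = if (is.list(score)) score$cells else NULL,
                 k_sd = k_sd, fraction_cycling = frac),
            class = "cycling_call")
}

#' Subsample a matched set of non-cycling cells
#'
#' Uniform sample without replacement from the non-cycling pool, sized to
#' match the cycling set it will be compared against.
#'
#' @param cells character vector: the non-cycling pool
#' @param n sample size (must not exceed the pool)
#' @param seed RNG seed
#' @return character vector of `n` barcodes
#' @export
matched_subsample <- function(cells, n, seed = 1) {
  if (n > length(cells)) stopf("pool of %d smaller than requested n = %d", length(cells), n)
  if (n == 0) return(character(0))
  if (n == length(cells)) return(cells)
  with_seed(seed, sample(cells, n, replace = FALSE))
}
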