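# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# hep_counts from a dense integer matrix (genes x cells)
toy_counts <- function(m, conditions = NULL, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  meta <- data.frame(barcode = cells,
                     condition = conditions %||% rep("UT", ncol(m)),
                     stringsAsFactors = FALSE)
  hep_counts(Matrix::Matrix(m, sparse = TRUE), meta)
}

# hep_norm directly from a dense value matrix (for analytic score tests)
toy_norm <- function(m, conditions = NULL, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  meta <- data.frame(barcode = cells,
                     condition = conditions %||% rep("UT", ncol(m)),
                     stringsAsFactors = FALSE)
  structure(list(values = Matrix::Matrix(m, sparse = TRUE), cell_meta = meta),
            class = "hep_norm")
}

random_counts <- function(n_genes, n_cells, seed, lambda = 2) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
    toy_counts(m)
  })
}

# a square image with a regular-polygon "circular" vein at the centre
toy_image <- function(half = 200, vein_r = 40, n_vertices = 64,
                      spots = list(), cells = list()) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  lobule_image(image_bounds = c(0, 0, 2 * half, 2 * half),
               pixel_size = 1,
               vein_polygon = cbind(half + vein_r * cos(ang),
                                    half + vein_r * sin(ang)),
               cells = cells, spots = spots)
}

square_cell <- function(id, cx, cy, r = 5, labels = list()) {
  list(id = id, centroid = c(cx, cy),
       outline = rbind(c(cx - r, cy - r), c(cx + r, cy - r),
                       c(cx + r, cy + r), c(cx - r, cy + r)),
       labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
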