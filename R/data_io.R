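# Reading and writing the external formats the pipeline consumes:
# triplet count matrices with TSV sidecars, GMT gene sets, lobule-geometry
# JSON, and TSV result tables.

#' Construct a validated count matrix container
#'
#' A `hep_counts` object bundles a sparse gene-by-cell integer count matrix
#' with per-cell metadata. `nGene` (genes detected) and `nUMI` (total counts)
#' are always recomputed from the counts, never trusted from the caller.
#'
#' @param counts sparse or dense nonnegative integer matrix, genes in rows,
#'   cells in columns; `dimnames` give gene symbols and cell barcodes.
#' @param cell_meta data.frame with one row per cell. Columns `condition`,
#'   `mouse` and `injury_model` are kept (missing ones are filled with
#'   `"unknown"`); a `barcode` column, if present, must match the matrix
#'   column names.
#' @return an object of class `hep_counts` with elements `counts`
#'   (a `dgCMatrix`) and `cell_meta` (with recomputed `nGene`, `nUMI`,
#'   `pct_mito`).
#' @export
hep_counts <- function(counts, cell_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  genes <- rownames(counts)
  cells <- colnames(counts)
  if (is.null(genes) && nrow(counts) == 0L) genes <- character(0)
  if (is.null(cells) && ncol(counts) == 0L) cells <- character(0)
  if (is.null(genes) || is.null(cells)) {
    stopf("counts must carry gene symbols as rownames and barcodes as colnames")
  }
  dimnames(counts) <- list(genes, cells)
  if (anyDuplicated(genes)) stopf("gene symbols must be unique")
  if (anyDuplicated(cells)) stopf("cell barcodes must be unique")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stopf("counts must be nonnegative integers")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = cells %||% character(0),
                            stringsAsFactors = FALSE)
  }
  if (!is.null(cell_meta$barcode)) {
    if (!identical(as.character(cell_meta$barcode), as.character(cells))) {
      stopf("cell_meta barcodes do not align with matrix columns")
    }
  }
  if (nrow(cell_meta) != ncol(counts)) {
    stopf("cell_meta has %d rows but matrix has %d cells",
          nrow(cell_meta), ncol(counts))
  }
  meta <- data.frame(barcode = as.character(cells %||% character(0)),
                     stringsAsFactors = FALSE)
  for (col in c("condition", "mouse", "injury_model")) {
    meta[[col]] <- if (!is.null(cell_meta[[col]])) as.character(cell_meta[[col]]) else rep("unknown", ncol(counts))
  }
  meta$nGene <- Matrix::colSums(counts > 0)
  meta$nUMI <- Matrix::colSums(counts)
  mito <- startsWith(genes, "mt-")
  meta$pct_mito <- if (any(mito) && ncol(counts)) {
    tot <- meta$nUMI
    frac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1)
    ifelse(tot > 0, frac, 0)
  } else {
    rep(0, ncol(counts))
  }
  rownames(meta) <- NULL
  # keep any extra caller-supplied columns (e.g. ground-truth labels)
  extra <- setdiff(names(cell_meta), c(names(meta)))
  for (col in extra) meta[[col]] <- cell_meta[[col]]
  structure(list(counts = counts, cell_meta = meta), class = "hep_counts")
}

#' @export
print.hep_counts <- function(x, ...) {
  cat(sprintf("hep_counts: %d genes x %d cells (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (ncol(x$counts)) {
    tab <- table(x$cell_meta$condition)
    cat("conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a count matrix as triplet text plus TSV sidecars
#'
#' Writes `<prefix>.matrix.tsv` (a header line `n_genes n_cells nnz` followed
#' by 1-based `gene cell count` triplets), `<prefix>.genes.tsv`,
#' `<prefix>.barcodes.tsv` and `<prefix>.cell_meta.tsv`.
#'
#' @param m a `hep_counts` object
#' @param path_prefix file path prefix for the four files
#' @export
write_count_matrix <- function(m, path_prefix) {
  stopifnot(inherits(m, "hep_counts"))
  if (anyDuplicated(colnames(m$counts))) stopf("refusing to write: duplicate barcodes")
  if (anyDuplicated(rownames(m$counts))) stopf("refusing to write: duplicate gene symbols")
  tm <- methods::as(m$counts, "TsparseMatrix")
  con <- file(paste0(path_prefix, ".matrix.tsv"), "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("%d\t%d\t%d", nrow(tm), ncol(tm), length(tm@x)), con)
  if (length(tm@x)) {
    ord <- order(tm@j, tm@i)
    utils::write.table(
      data.frame(g = tm@i[ord] + 1L, c = tm@j[ord] + 1L, v = as.integer(tm@x[ord])),
      con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  writeLines(rownames(tm) %||% character(0), paste0(path_prefix, ".genes.tsv"))
  writeLines(colnames(tm) %||% character(0), paste0(path_prefix, ".barcodes.tsv"))
  meta <- m$cell_meta[, c("barcode", "condition", "mouse", "injury_model"), drop = FALSE]
  utils::write.table(meta, paste0(path_prefix, ".cell_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' Validates dimensions against the sidecars and recomputes per-cell
#' statistics from the counts.
#'
#' @param path_prefix file path prefix used when writing
#' @return a `hep_counts` object
#' @export
read_count_matrix <- function(path_prefix) {
  paths <- paste0(path_prefix, c(".matrix.tsv", ".genes.tsv", ".barcodes.tsv"))
  for (p in paths) if (!file.exists(p)) stopf("missing file: %s", p)
  lines <- readLines(paths[1L])
  hdr <- as.numeric(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  if (length(hdr) != 3L || any(is.na(hdr))) stopf("malformed triplet header")
  genes <- readLines(paths[2L])
  cells <- readLines(paths[3L])
  if (length(genes) != hdr[1L]) {
    stopf("gene sidecar lists %d genes but header declares %d", length(genes), hdr[1L])
  }
  if (length(cells) != hdr[2L]) {
    stopf("barcode sidecar lists %d cells but header declares %d", length(cells), hdr[2L])
  }
  if (length(lines) - 1L != hdr[3L]) {
    stopf("triplet body has %d entries but header declares %d", length(lines) - 1L, hdr[3L])
  }
  if (hdr[3L] > 0) {
    body <- utils::read.table(text = lines[-1L], sep = "\t",
                              colClasses = "numeric", col.names = c("g", "c", "v"))
    if (any(body$v < 0) || any(body$v != round(body$v))) {
      stopf("negative or non-integer count entry in %s", paths[1L])
    }
    if (any(body$g < 1 | body$g > hdr[1L] | body$c < 1 | body$c > hdr[2L])) {
      stopf("triplet index out of declared bounds")
    }
    counts <- Matrix::sparseMatrix(i = body$g, j = body$c, x = body$v,
                                   dims = c(hdr[1L], hdr[2L]),
                                   dimnames = list(genes, cells))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = double(0),
                                   dims = c(hdr[1L], hdr[2L]),
                                   dimnames = list(genes, cells))
  }
  meta_path <- paste0(path_prefix, ".cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "")
  } else {
    NULL
  }
  if (!is.null(meta) && nrow(meta) > 0 && !identical(meta$barcode, cells)) {
    stopf("cell_meta barcodes do not match barcode sidecar")
  }
  if (!is.null(meta) && nrow(meta) == 0 && length(cells) > 0) {
    stopf("cell_meta is empty but barcodes exist")
  }
  hep_counts(counts, meta)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path
#' @return a named list of class `gene_set_collection`; each element has
#'   `description` and `genes`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields: %s", substr(ln, 1, 60))
    nm <- f[1L]
    if (!is.null(sets[[nm]])) stopf("duplicate gene-set name: %s", nm)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("empty gene set: %s", nm)
    sets[[nm]] <- list(description = f[2L], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param sets a `gene_set_collection` (or compatible named list)
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    paste(c(nm, s$description %||% "", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read lobule geometry from JSON
#'
#' The schema holds image bounds `[x0, y0, x1, y1]` and pixel size in
#' micrometres, a central-vein polygon, per-cell centroids/outlines/labels,
#' and per-gene smFISH spot coordinates. All coordinates are micrometres with
#' the origin at the image lower-left.
#'
#' @param path JSON file path
#' @param keep_out_of_bounds keep spots outside the image bounds (with a
#'   warning) instead of dropping them
#' @return an object of class `lobule_image`
#' @export
read_lobule_image <- function(path, keep_out_of_bounds = TRUE) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lobule_image(
    image_bounds = as.numeric(raw$image_bounds),
    pixel_size = as.numeric(raw$pixel_size),
    vein_polygon = raw$vein_polygon,
    cells = lapply(seq_len(length(raw$cells$id %||% integer(0))), function(i) {
      out <- raw$cells$outline
      # jsonlite collapses equal-shaped outlines into a cells x vertex x 2 array
      out <- if (is.array(out) && length(dim(out)) == 3L) out[i, , ] else out[[i]]
      list(id = raw$cells$id[i],
           centroid = as.numeric(raw$cells$centroid[i, ]),
           outline = as_polygon(out, "cell outline"),
           labels = as.list(lapply(raw$cells$labels, `[`, i)))
    }),
    spots = lapply(raw$spots %||% list(), function(s) {
      if (!length(s)) return(matrix(numeric(0), ncol = 2))
      if (is.matrix(s)) s else matrix(as.numeric(unlist(s)), ncol = 2, byrow = TRUE)
    }),
    keep_out_of_bounds = keep_out_of_bounds
  )
}

#' Construct a validated lobule image
#'
#' @param image_bounds numeric `c(x0, y0, x1, y1)` in micrometres
#' @param pixel_size micrometres per pixel, positive
#' @param vein_polygon simple polygon (n x 2 matrix) inside the bounds
#' @param cells list of `list(id, centroid, outline, labels)`
#' @param spots named list mapping gene symbol to an n x 2 coordinate matrix
#' @param keep_out_of_bounds keep out-of-bounds spots (flagged) or drop them
#' @return an object of class `lobule_image`
#' @export
lobule_image <- function(image_bounds, pixel_size, vein_polygon,
                         cells = list(), spots = list(),
                         keep_out_of_bounds = TRUE) {
  if (length(image_bounds) != 4L || !all(is.finite(image_bounds)) ||
      image_bounds[3L] <= image_bounds[1L] || image_bounds[4L] <= image_bounds[2L]) {
    stopf("image_bounds must be finite c(x0, y0, x1, y1) with x1 > x0, y1 > y0")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  vein <- as_polygon(vein_polygon, "vein polygon")
  if (!polygon_is_simple(vein)) stopf("vein polygon is self-intersecting")
  if (any(vein[, 1L] < image_bounds[1L] | vein[, 1L] > image_bounds[3L] |
          vein[, 2L] < image_bounds[2L] | vein[, 2L] > image_bounds[4L])) {
    stopf("vein polygon extends outside image bounds")
  }
  cells <- lapply(cells, function(cl) {
    cl$outline <- as_polygon(cl$outline, sprintf("outline of cell %s", cl$id))
    cl$centroid <- as.numeric(cl$centroid)
    cl$labels <- as.list(cl$labels %||% list())
    cl
  })
  ids <- vapply(cells, function(cl) as.character(cl$id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate cell ids")
  spots <- lapply(spots, function(s) {
    s <- as.matrix(s)
    if (length(s) == 0) return(matrix(numeric(0), ncol = 2))
    if (ncol(s) != 2L || !all(is.finite(s))) stopf("spot coordinates must be finite n x 2")
    storage.mode(s) <- "double"
    s
  })
  oob_flags <- lapply(spots, function(s) {
    if (!nrow(s)) return(logical(0))
    s[, 1L] < image_bounds[1L] | s[, 1L] > image_bounds[3L] |
      s[, 2L] < image_bounds[2L] | s[, 2L] > image_bounds[4L]
  })
  n_oob <- sum(vapply(oob_flags, sum, numeric(1)))
  if (n_oob > 0) {
    warnf("%d spot(s) fall outside image bounds%s", n_oob,
          if (keep_out_of_bounds) " (retained, flagged)" else " (dropped)")
    if (!keep_out_of_bounds) {
      spots <- Map(function(s, f) s[!f, , drop = FALSE], spots, oob_flags)
      oob_flags <- lapply(oob_flags, function(f) f[!f])
    }
  }
  structure(list(image_bounds = as.numeric(image_bounds),
                 pixel_size = as.numeric(pixel_size),
                 vein_polygon = vein,
                 cells = cells,
                 spots = spots,
                 spot_out_of_bounds = oob_flags),
            class = "lobule_image")
}

#' Write lobule geometry to JSON
#' @param img a `lobule_image`
#' @param path output path
#' @export
write_lobule_image <- function(img, path) {
  stopifnot(inherits(img, "lobule_image"))
  obj <- list(
    image_bounds = img$image_bounds,
    pixel_size = img$pixel_size,
    vein_polygon = unname(lapply(seq_len(nrow(img$vein_polygon)),
                                 function(i) img$vein_polygon[i, ])),
    cells = list(
      id = vapply(img$cells, function(cl) as.character(cl$id), character(1)),
      centroid = do.call(rbind, lapply(img$cells, `[[`, "centroid")),
      outline = lapply(img$cells, function(cl) unname(cl$outline)),
      labels = if (length(img$cells)) {
        lab_names <- unique(unlist(lapply(img$cells, function(cl) names(cl$labels))))
        stats::setNames(lapply(lab_names, function(nm) {
          vapply(img$cells, function(cl) isTRUE(cl$labels[[nm]]), logical(1))
        }), lab_names)
      } else {
        stats::setNames(list(), character(0))
      }
    ),
    spots = lapply(img$spots, function(s) unname(s))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(NULL)
}

#' Write a result table as TSV (UTF-8, "." decimal)
#' @param df data.frame
#' @param path output path
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(NULL)
}
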