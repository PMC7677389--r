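# Vein-anchored smFISH quantification: spot-to-cell assignment, concentric
# ring radial profiles with exact in-image ring areas, the AUC and 90%-AUC
# zonation boundary, pseudo-color cell maps, macrophage-proximity profiles,
# and two-sample distribution comparison.

#' Assign smFISH spots to segmented cells
#'
#' Each spot is counted for the unique cell whose outline contains it. A
#' spot strictly inside two outlines indicates overlapping segmentation and
#' raises an error; a spot on a shared boundary goes to the containing cell
#' with the lexicographically lowest id (counted in `n_boundary_ties`).
#' Spots inside no cell go to an unassigned bucket.
#'
#' @param img a `lobule_image`
#' @param gene gene symbol present in the image's spot map
#' @return list: `counts` (named integer vector per cell id), `unassigned`
#'   (number of spots outside all outlines), `n_boundary_ties`
#' @export
assign_spots_to_cells <- function(img, gene) {
  stopifnot(inherits(img, "lobule_image"))
  if (!gene %in% names(img$spots)) stopf("gene %s has no spots in this image", gene)
  spots <- img$spots[[gene]]
  ids <- vapply(img$cells, function(cl) as.character(cl$id), character(1))
  counts <- stats::setNames(integer(length(ids)), ids)
  if (!nrow(spots)) return(list(counts = counts, unassigned = 0L, n_boundary_ties = 0L))
  bboxes <- t(vapply(img$cells, function(cl) {
    c(range(cl$outline[, 1L]), range(cl$outline[, 2L]))
  }, numeric(4)))
  unassigned <- 0L; ties <- 0L
  ord <- order(ids)
  for (s in seq_len(nrow(spots))) {
    x <- spots[s, 1L]; y <- spots[s, 2L]
    cand <- which(bboxes[, 1L] <= x & bboxes[, 2L] >= x &
                    bboxes[, 3L] <= y & bboxes[, 4L] >= y)
    hits <- cand[vapply(cand, function(i) {
      points_in_polygon(x, y, img$cells[[i]]$outline)
    }, logical(1))]
    if (length(hits) == 0L) {
      unassigned <- unassigned + 1L
    } else if (length(hits) == 1L) {
      counts[hits] <- counts[hits] + 1L
    } else {
      d <- vapply(hits, function(i) {
        points_to_polygon_boundary(x, y, img$cells[[i]]$outline)
      }, numeric(1))
      if (sum(d > 1e-6) > 1L) {
        stopf("overlapping cell outlines share interior area near (%.2f, %.2f)", x, y)
      }
      ties <- ties + 1L
      win <- hits[order(ids[hits])][1L]
      counts[win] <- counts[win] + 1L
    }
  }
  list(counts = counts, unassigned = unassigned, n_boundary_ties = ties)
}

# Area of {x : dist(x, vein) <= r} intersected with the image rectangle,
# minus nothing (the vein interior is part of the region; ring differences
# cancel it). Exact up to the fine polygonalisation of the offset arcs.
.offset_area_in_image <- function(vein, r, bounds, arc_step) {
  p <- offset_convex_polygon(vein, r, arc_step)
  p <- clip_polygon_rect(p, bounds)
  if (nrow(p) < 3L) return(0)
  polygon_area(p)
}

#' Radial expression profile in concentric rings around the central vein
#'
#' Every spot's radius is its Euclidean distance to the nearest point of the
#' vein polygon boundary; spots inside the vein lumen are excluded and
#' counted separately. Rings of width `ring_width` cover distances up to the
#' farthest in-image point. Each ring's raw count is renormalized by the
#' ring area contained within the image (computed by exact polygon clipping
#' of the vein's outward offset, minus the vein lumen), giving a density in
#' counts per square micrometre. The profile's reported AUC is the
#' trapezoidal integral of density over ring midpoints; the zonation
#' boundary is the smallest radius at which the cumulative density mass
#' over radius (per-ring density integrated over ring width, linear within
#' a ring) reaches 90% of its total.
#'
#' @param img a `lobule_image`; the vein polygon must be convex (the offset
#'   construction used for exact ring areas requires it)
#' @param gene gene symbol
#' @param ring_width ring width in micrometres (default 30, one hepatocyte
#'   diameter)
#' @return list of class `radial_profile`: `gene`, `rings` data.frame
#'   (r_inner, r_outer, raw_count, in_image_area, density), `total_auc`,
#'   `boundary_radius`, `n_inside_vein`, `n_out_of_bounds`
#' @export
radial_profile <- function(img, gene, ring_width = 30) {
  stopifnot(inherits(img, "lobule_image"))
  if (ring_width <= 0) stopf("ring_width must be positive")
  if (!gene %in% names(img$spots)) stopf("gene %s has no spots in this image", gene)
  vein <- img$vein_polygon
  if (!polygon_is_convex(vein)) {
    stopf("ring-area computation requires a convex vein polygon")
  }
  spots <- img$spots[[gene]]
  oob <- img$spot_out_of_bounds[[gene]] %||% logical(nrow(spots))
  spots_in <- spots[!oob, , drop = FALSE]
  n_oob <- sum(oob)
  inside <- if (nrow(spots_in)) {
    points_in_polygon(spots_in[, 1L], spots_in[, 2L], vein)
  } else {
    logical(0)
  }
  n_in_vein <- sum(inside)
  radii <- if (any(!inside)) {
    points_to_polygon_boundary(spots_in[!inside, 1L], spots_in[!inside, 2L], vein)
  } else {
    numeric(0)
  }
  if (!length(radii) && nrow(spots)) {
    if (n_in_vein == nrow(spots)) stopf("all spots lie inside the vein lumen")
  }
  b <- img$image_bounds
  corners <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]), c(b[1], b[4]))
  max_dist <- max(points_to_polygon_boundary(corners[, 1L], corners[, 2L], vein))
  n_rings <- max(1L, ceiling(max_dist / ring_width))
  edges <- ring_width * (0:n_rings)
  ring_idx <- findInterval(radii, edges, rightmost.closed = FALSE)
  beyond <- sum(ring_idx > n_rings | ring_idx < 1)
  raw <- tabulate(ring_idx[ring_idx >= 1 & ring_idx <= n_rings], nbins = n_rings)
  arc_step <- 2 * pi / 20000
  cum_area <- vapply(edges, function(r) {
    .offset_area_in_image(vein, r, b, arc_step)
  }, numeric(1))
  area <- diff(cum_area)
  if (any(area <= 0 & raw > 0)) stopf("ring with zero in-image area holds spots")
  density <- ifelse(area > 0, raw / area, NA_real_)
  rings <- data.frame(r_inner = edges[-length(edges)], r_outer = edges[-1L],
                      raw_count = raw, in_image_area = area, density = density)
  mid <- (rings$r_inner + rings$r_outer) / 2
  ok <- !is.na(density)
  m <- mid[ok]; rho <- density[ok]
  # reported AUC: trapezoid over the ring-midpoint density curve (the
  # "Average Total RNA Counts" statistic as a plotting tool would compute it)
  total_auc <- if (length(m) >= 2) {
    sum(diff(m) * (rho[-1] + rho[-length(rho)]) / 2)
  } else if (length(rho)) {
    rho[1] * ring_width
  } else {
    0
  }
  # boundary: cumulative density mass over radius (step density integrated,
  # so linear within each ring); smallest r reaching 90% of the total
  dens0 <- ifelse(is.na(density), 0, density)
  widths <- rings$r_outer - rings$r_inner
  cum_end <- cumsum(dens0 * widths)
  total_step <- cum_end[length(cum_end)]
  if (total_step > 0) {
    target <- 0.9 * total_step
    i <- which(cum_end >= target - 1e-12)[1]
    before <- if (i == 1L) 0 else cum_end[i - 1L]
    boundary <- rings$r_inner[i] + (target - before) / dens0[i]
    boundary <- min(max(boundary, rings$r_inner[i]), rings$r_outer[i])
  } else {
    boundary <- NA_real_
  }
  structure(list(gene = gene, rings = rings, ring_width = ring_width,
                 total_auc = total_auc, boundary_radius = boundary,
                 n_inside_vein = n_in_vein, n_out_of_bounds = n_oob,
                 n_beyond_rings = beyond),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial profile of %s: %d rings x %.0f um, AUC %.4g, 90%%-AUC boundary %.1f um\n",
              x$gene, nrow(x$rings), x$ring_width, x$total_auc, x$boundary_radius))
  invisible(x)
}

#' Shift of the 90%-AUC zonation boundary between two conditions
#'
#' @param profile_treated,profile_ut `radial_profile`s of the same gene at
#'   the same ring width
#' @return boundary shift in micrometres (positive = outward expansion in
#'   the treated condition)
#' @export
boundary_shift <- function(profile_treated, profile_ut) {
  if (!identical(profile_treated$gene, profile_ut$gene)) {
    stopf("profiles are for different genes (%s vs %s)",
          profile_treated$gene, profile_ut$gene)
  }
  if (!identical(profile_treated$ring_width, profile_ut$ring_width)) {
    stopf("profiles use different ring widths")
  }
  profile_treated$boundary_radius - profile_ut$boundary_radius
}

#' Pseudo-color map of per-cell transcript counts
#'
#' Rasterizes the segmentation at the image's pixel size: every pixel whose
#' center falls inside a cell outline carries that cell's count; background
#' pixels are `NA`.
#'
#' @param img a `lobule_image`
#' @param per_cell_counts named numeric vector over cell ids (e.g. the
#'   `counts` element of [assign_spots_to_cells()])
#' @param file optional PNG path; written with a linear grey ramp when the
#'   `png` package is available
#' @return numeric matrix (rows = y from top, columns = x), invisibly when
#'   `file` is given
#' @export
pseudocolor_map <- function(img, per_cell_counts, file = NULL) {
  stopifnot(inherits(img, "lobule_image"))
  b <- img$image_bounds
  ps <- img$pixel_size
  nx <- max(1L, floor((b[3] - b[1]) / ps))
  ny <- max(1L, floor((b[4] - b[2]) / ps))
  ras <- matrix(NA_real_, nrow = ny, ncol = nx)
  xc <- b[1] + (seq_len(nx) - 0.5) * ps
  yc <- b[2] + (seq_len(ny) - 0.5) * ps
  for (cl in img$cells) {
    id <- as.character(cl$id)
    val <- per_cell_counts[[id]]
    if (is.null(val) || is.na(val)) next
    out <- cl$outline
    ix <- which(xc >= min(out[, 1]) & xc <= max(out[, 1]))
    iy <- which(yc >= min(out[, 2]) & yc <= max(out[, 2]))
    if (!length(ix) || !length(iy)) next
    gx <- rep(xc[ix], times = length(iy))
    gy <- rep(yc[iy], each = length(ix))
    inside <- points_in_polygon(gx, gy, out)
    rows <- ny + 1L - rep(iy, each = length(ix))[inside]  # y increases upward
    cols <- rep(ix, times = length(iy))[inside]
    ras[cbind(rows, cols)] <- val
  }
  if (!is.null(file)) {
    if (requireNamespace("png", quietly = TRUE)) {
      mx <- max(ras, na.rm = TRUE)
      grey <- ras / max(mx, 1)
      grey[is.na(grey)] <- 0
      png::writePNG(grey, file)
    } else {
      warnf("png package unavailable; no image written")
    }
    return(invisible(ras))
  }
  ras
}

#' Expression as a function of distance to the nearest macrophage
#'
#' For every non-macrophage cell, the distance to the nearest
#' macrophage-labeled cell (centroid to centroid) is binned in contiguous
#' bins of `bin_width` micrometres from zero; the profile reports the mean
#' per-cell transcript count and the number of cells per bin.
#'
#' @param img a `lobule_image` with at least one cell labeled `macrophage`
#' @param gene gene symbol
#' @param bin_width bin width in micrometres (default 30, one hepatocyte
#'   diameter)
#' @return data.frame (class `proximity_profile`): bin_lo, bin_hi,
#'   mean_count, n_cells
#' @export
macrophage_proximity <- function(img, gene, bin_width = 30) {
  stopifnot(inherits(img, "lobule_image"))
  is_mac <- vapply(img$cells, function(cl) isTRUE(cl$labels$macrophage), logical(1))
  if (!any(is_mac)) stopf("no cell labeled macrophage")
  counts <- assign_spots_to_cells(img, gene)$counts
  centroids <- do.call(rbind, lapply(img$cells, `[[`, "centroid"))
  macs <- centroids[is_mac, , drop = FALSE]
  others <- which(!is_mac)
  d <- vapply(others, function(i) {
    min(sqrt((macs[, 1] - centroids[i, 1])^2 + (macs[, 2] - centroids[i, 2])^2))
  }, numeric(1))
  cnt <- counts[others]
  n_bins <- max(1L, ceiling(max(d) / bin_width))
  bin <- pmin(n_bins, 1L + floor(d / bin_width))
  out <- data.frame(bin_lo = bin_width * (seq_len(n_bins) - 1L),
                    bin_hi = bin_width * seq_len(n_bins),
                    mean_count = vapply(seq_len(n_bins), function(bn) {
                      if (any(bin == bn)) mean(cnt[bin == bn]) else NA_real_
                    }, numeric(1)),
                    n_cells = tabulate(bin, nbins = n_bins))
  class(out) <- c("proximity_profile", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The statistic is the supremum of the absolute difference between the two
#' empirical CDFs; the p-value is the asymptotic two-sided one.
#'
#' @param sample_a,sample_b numeric vectors, each nonempty
#' @return list with `D` and `p`
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stopf("empty sample")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
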