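test_that("spots are assigned to the containing cell, with buckets for the rest", {
  cells <- list(square_cell("a", 100, 100), square_cell("b", 120, 100))
  img <- toy_image(cells = cells,
                   spots = list(G = rbind(c(100, 100),   # centroid of a
                                          c(120, 103),   # inside b
                                          c(5, 5))))     # nowhere
  res <- assign_spots_to_cells(img, "G")
  expect_equal(unname(res$counts[c("a", "b")]), c(1, 1))
  expect_equal(res$unassigned, 1)
  expect_error(assign_spots_to_cells(img, "missing"), "no spots")
})

test_that("overlapping interiors error; shared boundaries break by lowest id", {
  overlap <- toy_image(cells = list(square_cell("a", 100, 100),
                                    square_cell("b", 104, 100)),
                       spots = list(G = rbind(c(102, 100))))
  expect_error(assign_spots_to_cells(overlap, "G"), "overlapping")
  # exactly shared edge: the spot lands in exactly one cell, never both
  touching <- toy_image(cells = list(square_cell("b2", 100, 100),
                                     square_cell("a1", 110, 100)),
                        spots = list(G = rbind(c(105, 100))))
  res <- assign_spots_to_cells(touching, "G")
  expect_equal(sum(res$counts), 1)
  expect_equal(res$unassigned, 0)
  # sub-micron sliver overlap: treated as a boundary tie, lowest id wins
  eps <- 1e-9
  sliver <- toy_image(cells = list(square_cell("b2", 100, 100),
                                   square_cell("a1", 110 - 2 * eps, 100)),
                      spots = list(G = rbind(c(105 - eps, 100))))
  res2 <- assign_spots_to_cells(sliver, "G")
  expect_equal(res2$n_boundary_ties, 1)
  expect_equal(unname(res2$counts["a1"]), 1)
})

test_that("assignment equals brute-force point-in-polygon on random fixtures", {
  for (seed in 1:10) {
    fix <- withr::with_seed(seed, {
      centers <- cbind(stats::runif(12, 50, 350), stats::runif(12, 50, 350))
      # spaced cells: keep centers at least 25 apart to avoid overlap
      keep <- rep(TRUE, 12)
      for (i in 2:12) {
        if (any(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                                matrix(centers[i, ], i - 1, 2, byrow = TRUE))^2))[keep[seq_len(i - 1)]] < 25)) {
          keep[i] <- FALSE
        }
      }
      cells <- lapply(which(keep), function(i) {
        square_cell(sprintf("c%02d", i), centers[i, 1], centers[i, 2], r = 10)
      })
      spots <- cbind(stats::runif(200, 0, 400), stats::runif(200, 0, 400))
      list(cells = cells, spots = spots)
    })
    img <- toy_image(cells = fix$cells, spots = list(G = fix$spots))
    res <- assign_spots_to_cells(img, "G")
    brute <- sapply(fix$cells, function(cl) {
      sum(pracma::inpolygon(fix$spots[, 1], fix$spots[, 2],
                            cl$outline[, 1], cl$outline[, 2]))
    })
    expect_equal(unname(res$counts), unname(brute))
  }
})

test_that("in-image ring areas match the analytic annulus", {
  img <- toy_image(half = 500, vein_r = 40, n_vertices = 512,
                   spots = list(G = matrix(numeric(0), ncol = 2)))
  rp <- radial_profile(img, "G", ring_width = 30)
  vein <- img$vein_polygon
  a_eff <- polygon_area(vein)          # polygonal vein, not the ideal circle
  per <- hepcompass:::polygon_perimeter(vein)
  # offset of a convex polygon: area(r) = A + P*r + pi*r^2, rings fully inside
  for (i in 1:5) {
    r1 <- (i - 1) * 30; r2 <- i * 30
    analytic <- per * (r2 - r1) + pi * (r2^2 - r1^2)
    expect_lt(abs(rp$rings$in_image_area[i] - analytic) / analytic, 1e-6)
  }
  # and close to the ideal circular annulus at this vertex count
  expect_lt(abs(rp$rings$in_image_area[1] - pi * (70^2 - 40^2)) / (pi * (70^2 - 40^2)),
            1e-3)
})

test_that("ring areas survive image clipping and Monte-Carlo validation", {
  img <- toy_image(half = 100, vein_r = 30, n_vertices = 256,
                   spots = list(G = matrix(numeric(0), ncol = 2)))
  rp <- radial_profile(img, "G", ring_width = 40)
  vein <- img$vein_polygon
  n_mc <- 1e6
  pts <- withr::with_seed(5, cbind(stats::runif(n_mc, 0, 200),
                                   stats::runif(n_mc, 0, 200)))
  inside_vein <- hepcompass:::points_in_polygon(pts[, 1], pts[, 2], vein)
  d <- hepcompass:::points_to_polygon_boundary(pts[, 1], pts[, 2], vein)
  for (i in seq_len(nrow(rp$rings))) {
    r1 <- rp$rings$r_inner[i]; r2 <- rp$rings$r_outer[i]
    frac <- mean(!inside_vein & d >= r1 & d < r2)
    est <- frac * 200 * 200
    se <- 200 * 200 * sqrt(frac * (1 - frac) / n_mc)
    expect_lt(abs(rp$rings$in_image_area[i] - est), 3 * se + 1e-9)
  }
  # total conservation of area across rings
  covered <- mean(!inside_vein) * 200 * 200
  expect_lt(abs(sum(rp$rings$in_image_area) - covered) / covered, 1e-3)
})

test_that("radial profile counts are conserved and the boundary behaves", {
  img <- toy_image(half = 200, vein_r = 40,
                   spots = list(G = rbind(c(240, 200),    # 0 from vein? no: 0.., ring 1
                                          c(260, 200),    # ring 1
                                          c(330, 200),    # ring 3
                                          c(200, 200))))  # inside vein
  rp <- radial_profile(img, "G", ring_width = 30)
  expect_equal(rp$n_inside_vein, 1)
  expect_equal(sum(rp$rings$raw_count) + rp$n_inside_vein +
                 rp$n_beyond_rings + rp$n_out_of_bounds, 4)
  # all spots in ring 1 -> boundary inside ring 1
  img2 <- toy_image(half = 200, vein_r = 40,
                    spots = list(G = cbind(stats::runif(30, 241, 269), 200)))
  rp2 <- radial_profile(img2, "G", ring_width = 30)
  expect_lte(rp2$boundary_radius, rp2$rings$r_outer[1])
  # adding spots to the last ring never decreases the boundary
  sp <- img$spots$G
  img3 <- toy_image(half = 200, vein_r = 40,
                    spots = list(G = rbind(sp, c(395, 200), c(396, 200))))
  expect_gte(radial_profile(img3, "G", 30)$boundary_radius, rp$boundary_radius)
  expect_error(radial_profile(toy_image(spots = list(G = rbind(c(200, 200)))), "G"),
               "inside the vein")
})

test_that("uniform density gives the analytic 90%-AUC boundary", {
  # uniform spot density on an annulus fully inside the image
  img <- withr::with_seed(8, {
    n <- 40000
    r_v <- 40; r_max <- 150; half <- 300
    rr <- sqrt(stats::runif(n, r_v^2, r_max^2))
    th <- stats::runif(n, 0, 2 * pi)
    toy_image(half = half, vein_r = r_v, n_vertices = 256,
              spots = list(G = cbind(half + rr * cos(th), half + rr * sin(th))))
  })
  rp <- radial_profile(img, "G", ring_width = 10)
  rings <- rp$rings
  core <- rings$r_outer <= 110   # fully populated rings
  dens <- rings$density[core]
  expect_true(all(abs(dens - mean(dens)) <=
                    3 * sqrt(rings$raw_count[core]) / rings$in_image_area[core]))
  # constant density -> cumulative linear in distance from the vein edge ->
  # the 90% point sits at 0.9 of the populated span (here 0 to 110)
  expect_lt(abs(rp$boundary_radius - 0.9 * 110), 10 / 2 + 3)
})

test_that("boundary shift recovers a planted expansion and is antisymmetric", {
  prof_ut <- list(Glul = function(d) 30 * exp(-d / 40))
  prof_tr <- list(Glul = function(d) ifelse(d < 60, 0.5, 30 * exp(-(d - 60) / 40)))
  shifts <- sapply(1:10, function(seed) {
    ut <- simulate_lobule_image(spatial_sim_config(profiles = prof_ut, seed = seed))
    tr <- simulate_lobule_image(spatial_sim_config(profiles = prof_tr, seed = seed + 50))
    p_ut <- radial_profile(ut$image, "Glul")
    p_tr <- radial_profile(tr$image, "Glul")
    expect_equal(boundary_shift(p_ut, p_tr), -boundary_shift(p_tr, p_ut))
    c(planted = unname(tr$truth$r90["Glul"] - ut$truth$r90["Glul"]),
      got = boundary_shift(p_tr, p_ut))
  })
  expect_gte(sum(abs(shifts["got", ] - shifts["planted", ]) <= 30), 9)
  p1 <- radial_profile(simulate_lobule_image(spatial_sim_config(seed = 1))$image, "Glul")
  expect_equal(boundary_shift(p1, p1), 0)
  p2 <- radial_profile(simulate_lobule_image(spatial_sim_config(seed = 1))$image, "Cyp2e1")
  expect_error(boundary_shift(p1, p2), "different genes")
})

test_that("pseudo-color map carries per-cell counts onto pixels", {
  cells <- list(square_cell("a", 50, 50, r = 8), square_cell("b", 120, 80, r = 8))
  img <- lobule_image(c(0, 0, 200, 200), pixel_size = 1,
                      vein_polygon = rbind(c(95, 95), c(105, 95), c(105, 105), c(95, 105)),
                      cells = cells)
  ras <- pseudocolor_map(img, c(a = 0, b = 10))
  vals <- unique(ras[!is.na(ras)])
  expect_setequal(vals, c(0, 10))
  # permuting the cell order leaves the raster unchanged
  img2 <- img; img2$cells <- rev(img2$cells)
  expect_identical(pseudocolor_map(img2, c(b = 10, a = 0)), ras)
  # rasterized mass recovers totals within 2%
  area_px <- sum(ras == 10, na.rm = TRUE)
  expect_lt(abs(area_px * 1 - 16 * 16) / (16 * 16), 0.02)
})

test_that("macrophage proximity profile detects a planted boost", {
  wins <- sapply(1:10, function(seed) {
    sim <- simulate_lobule_image(spatial_sim_config(
      profiles = list(G = function(d) 5), n_macrophages = 10,
      macrophage_boost = 3, macrophage_range = 30, seed = seed))
    pp <- macrophage_proximity(sim$image, "G", bin_width = 30)
    pp$mean_count[1] > pp$mean_count[2]
  })
  expect_gte(sum(wins), 9)
  # no boost: per-bin means are statistically flat
  sim0 <- simulate_lobule_image(spatial_sim_config(
    profiles = list(G = function(d) 5), n_macrophages = 10,
    macrophage_boost = 1, seed = 3))
  pp0 <- macrophage_proximity(sim0$image, "G", bin_width = 30)
  ok <- pp0$n_cells >= 10
  se <- sqrt(5 / pp0$n_cells[ok])
  expect_true(all(abs(pp0$mean_count[ok] - 5) <= 3.5 * se))
  expect_error(macrophage_proximity(simulate_lobule_image(
    spatial_sim_config(seed = 1))$image, "Glul"), "macrophage")
})

test_that("KS comparison equals the brute-force ECDF supremum", {
  same <- compare_distributions(1:5, 1:5)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(compare_distributions(c(1, 2, 3, 4), c(5, 6, 7, 8))$D, 1)
  brute_D <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(g) - stats::ecdf(b)(g)))
  }
  for (seed in 1:30) {
    withr::with_seed(seed, {
      a <- stats::rnorm(sample(5:50, 1))
      b <- stats::rnorm(sample(5:50, 1), mean = stats::runif(1, -1, 1))
    })
    expect_equal(compare_distributions(a, b)$D, brute_D(a, b), tolerance = 1e-12)
  }
  expect_error(compare_distributions(numeric(0), 1:3), "empty")
})
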