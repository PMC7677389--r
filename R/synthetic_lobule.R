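# Synthetic liver-lobule data generator. Produces count matrices with
# planted zonation (exponential layer profiles), injury perturbations
# (pericentral necrosis, midzonal expansion of the pericentral program,
# injury-scaled upregulation of function genes, a cycling subpopulation with
# a down-scaled hepatocyte program) and 2-D smFISH spot maps around a
# circular central vein, together with full ground truth for parameter
# recovery.

#' Default per-condition injury parameters
#'
#' The shipped conditions emulate one untreated and three injured states:
#' `UT` (homeostasis), `A6` (early toxic injury: the two pericentral layers
#' necrotic, mild functional upregulation), `A24` (compensation phase:
#' persistent pericentral necrosis, the pericentral program expanded two
#' layers into the midzone, a cycling subpopulation with a down-scaled
#' hepatocyte program), and `P3` (early post-resection: no zonal necrosis
#' but strong global functional upregulation reflecting the larger loss of
#' tissue mass).
#'
#' @return named list of per-condition parameter lists
#' @export
default_conditions <- function() {
  list(
    UT  = list(injury_model = "none", necrosis_layers = 0L, expansion_layers = 0L,
               function_gene_factor = 1, cycling_fraction = 0,
               cycling_hepatocyte_scale = 1),
    A6  = list(injury_model = "APAP", necrosis_layers = 2L, expansion_layers = 0L,
               function_gene_factor = 1.5, cycling_fraction = 0.01,
               cycling_hepatocyte_scale = 0.7),
    A24 = list(injury_model = "APAP", necrosis_layers = 2L, expansion_layers = 2L,
               function_gene_factor = 2, cycling_fraction = 0.05,
               cycling_hepatocyte_scale = 0.7),
    P3  = list(injury_model = "PH", necrosis_layers = 0L, expansion_layers = 1L,
               function_gene_factor = 3, cycling_fraction = 0.01,
               cycling_hepatocyte_scale = 0.7)
  )
}

#' Simulation configuration for the expression generator
#'
#' @param n_layers number of lobule layers L >= 3; layer 1 is pericentral
#' @param cells_per_layer_per_condition cells drawn per surviving layer
#' @param conditions named list of per-condition parameters (see
#'   [default_conditions()]); each has `injury_model`, `necrosis_layers` k
#'   (pericentral layers removed, k + 1 < L), `expansion_layers` Delta
#'   (outward shift of the pericentral program, Delta <= L - 1),
#'   `function_gene_factor` f >= 1, `cycling_fraction` in [0, 1) and
#'   `cycling_hepatocyte_scale` delta in (0, 1]
#' @param gene_panel named integer vector: counts of pericentral, periportal,
#'   flat, function, cycle and stress genes
#' @param nb_dispersion negative-binomial size parameter shared by all genes
#' @param libsize_lognormal `c(meanlog, sdlog)` of the per-cell library size
#' @param dropout_rate extra independent zero probability in [0, 1); the
#'   default is small because negative-binomial sampling already produces
#'   the bulk of observed zeros in real droplet/nanowell data
#' @param slope_range range of per-gene zonation slopes; a degenerate range
#'   (equal endpoints) plants slope-matched zonated genes
#' @param cycle_gene_boost fold elevation of cycle genes in cycling cells
#' @param seed integer seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_layers = 9,
                       cells_per_layer_per_condition = 60,
                       conditions = default_conditions(),
                       gene_panel = c(pericentral = 20, periportal = 20,
                                      flat = 200, functional = 10,
                                      cycle = 20, stress = 10),
                       nb_dispersion = 4,
                       libsize_lognormal = c(log(4000), 0.35),
                       dropout_rate = 0.01,
                       slope_range = c(0.15, 0.4),
                       cycle_gene_boost = 40,
                       seed = 1) {
  if (n_layers < 3) stopf("n_layers must be >= 3")
  if (cells_per_layer_per_condition < 1) stopf("cells_per_layer_per_condition must be positive")
  if (any(gene_panel < 1)) stopf("all gene panel counts must be positive")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  for (nm in names(conditions)) {
    cc <- conditions[[nm]]
    if (cc$necrosis_layers + 1 >= n_layers) stopf("condition %s: necrosis_layers + 1 must be < n_layers", nm)
    if (cc$expansion_layers > n_layers - 1) stopf("condition %s: expansion_layers too large", nm)
    if (cc$function_gene_factor < 1) stopf("condition %s: function_gene_factor must be >= 1", nm)
    if (cc$cycling_fraction < 0 || cc$cycling_fraction >= 1) stopf("condition %s: cycling_fraction in [0, 1)", nm)
    if (cc$cycling_hepatocyte_scale <= 0 || cc$cycling_hepatocyte_scale > 1) stopf("condition %s: cycling_hepatocyte_scale in (0, 1]", nm)
  }
  structure(list(n_layers = n_layers,
                 cells_per_layer_per_condition = cells_per_layer_per_condition,
                 conditions = conditions, gene_panel = gene_panel,
                 nb_dispersion = nb_dispersion,
                 libsize_lognormal = libsize_lognormal,
                 dropout_rate = dropout_rate,
                 slope_range = slope_range,
                 cycle_gene_boost = cycle_gene_boost,
                 seed = seed),
            class = "sim_config")
}

# Gene panel with real marker symbols at the head of each class so that the
# fixed hepatocyte signature, the Cyp2e1 anchor and the shipped cell-cycle
# panel all intersect the simulated matrix.
build_gene_panel <- function(panel) {
  pad <- function(known, n, prefix) {
    if (n <= length(known)) known[seq_len(n)]
    else c(known, sprintf("%s%03d", prefix, seq_len(n - length(known))))
  }
  list(
    pericentral = pad(c("Cyp2e1", "Glul", "Cyp1a2", "Gstm3", "Axin2", "Oat"),
                      panel[["pericentral"]], "PCg"),
    periportal = pad(c("Cyp2f2", "Ass1", "Arg1", "Pck1", "G6pc", "Sds"),
                     panel[["periportal"]], "PPg"),
    flat = pad(c("Actb", "Gapdh", "Rpl13a", "Eef1a1", "B2m", "Ppia"),
               panel[["flat"]], "FLTg"),
    functional = pad(c("Alb", "Apoa1", "Asl", "Mup3", "Acly", "Fabp1",
                       "Tf", "Apoh", "Fga", "Fgb"),
                     panel[["functional"]], "FUNg"),
    cycle = pad(c("Mki67", "Top2a", "Pcna", "Mcm5", "Ccnb2", "Cdk1", "Birc5",
                  "Ube2c", "Tyms", "Mcm2"), panel[["cycle"]], "CYCg"),
    stress = pad(c("Txnrd1", "Gclc", "Hmox1", "Nqo1"), panel[["stress"]], "STRg")
  )
}

#' Simulate a zonated single-cell count matrix with injury perturbations
#'
#' Gene means follow exponential layer profiles: pericentral genes decay
#' with layer index (`exp(-beta * l)`, layer 1 pericentral), periportal genes
#' rise (`exp(+beta * l)`), flat/function/stress genes are layer-independent.
#' Per condition, cells are drawn for every surviving layer
#' (`l > necrosis_layers`); in expanded conditions pericentral genes use the
#' profile evaluated at `max(1, l - expansion_layers)`; function and stress
#' genes are multiplied by `function_gene_factor`; a `cycling_fraction`
#' subpopulation has the differentiated hepatocyte program (zonated,
#' function and stress genes; housekeeping is untouched) scaled by
#' `cycling_hepatocyte_scale` and cycle genes boosted. Each cell's rate
#' vector is normalized to sum to one and scaled by a log-normal library
#' size; counts are negative binomial with shared dispersion, then zeroed
#' independently with probability `dropout_rate`.
#'
#' @param cfg a `sim_config`
#' @return list with `counts` (a `hep_counts`) and `truth` (a `sim_truth`
#'   list: `gene_truth` data.frame with class and slope, `profile` the
#'   gene-by-layer relative mean matrix, `cell_truth` with the true layer and
#'   cycling flag per cell, and the per-condition planted parameters)
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    panel <- build_gene_panel(cfg$gene_panel)
    classes <- rep(names(panel), lengths(panel))
    genes <- unlist(panel, use.names = FALSE)
    n_genes <- length(genes)
    L <- cfg$n_layers
    slope <- numeric(n_genes)
    # per-gene gradient slopes: the default range spans roughly 3- to
    # 25-fold pericentral-to-periportal ratios across a 9-layer lobule, the
    # range typical of zonated genes in reference zonation profiles; a
    # degenerate range plants slope-matched genes
    sr <- cfg$slope_range
    slope[classes == "pericentral"] <- stats::runif(sum(classes == "pericentral"), sr[1], sr[2])
    slope[classes == "periportal"] <- stats::runif(sum(classes == "periportal"), sr[1], sr[2])
    # baseline class weights: hepatocyte program abundant, cycle genes near
    # silent outside cycling cells, stress genes low at baseline
    base_w <- c(pericentral = 1, periportal = 1, flat = 1,
                functional = 3, cycle = 0.05, stress = 0.2)[classes]
    # heterogeneous per-gene baseline abundance, as in real data where gene
    # means span decades; zonated genes draw from the upper half, matching
    # the highly expressed canonical zonation markers
    abundance <- exp(stats::rnorm(n_genes, 0, 1.1))
    zonated <- classes %in% c("pericentral", "periportal")
    abundance[zonated] <- exp(abs(stats::rnorm(sum(zonated), 0, 0.5)))
    base_w <- base_w * abundance
    # relative mean profile, gene x layer, before per-condition modifiers
    profile <- matrix(0, n_genes, L, dimnames = list(genes, NULL))
    for (l in seq_len(L)) {
      sgn <- ifelse(classes == "pericentral", -1, ifelse(classes == "periportal", 1, 0))
      profile[, l] <- base_w * exp(sgn * slope * (l - (L + 1) / 2))
    }
    cells_list <- list(); meta_list <- list()
    for (cond in names(cfg$conditions)) {
      cc <- cfg$conditions[[cond]]
      layers <- (cc$necrosis_layers + 1):L
      for (l in layers) {
        n_c <- cfg$cells_per_layer_per_condition
        l_eff <- l
        prof_l <- profile[, l]
        if (cc$expansion_layers > 0) {
          pc <- classes == "pericentral"
          prof_l[pc] <- profile[pc, max(1L, l - cc$expansion_layers)]
        }
        prof_l[classes %in% c("functional", "stress")] <-
          prof_l[classes %in% c("functional", "stress")] * cc$function_gene_factor
        cycling <- stats::runif(n_c) < cc$cycling_fraction
        libsize <- stats::rlnorm(n_c, cfg$libsize_lognormal[1], cfg$libsize_lognormal[2])
        m <- matrix(0L, n_genes, n_c)
        # the differentiated hepatocyte program; "flat" genes are
        # layer-independent housekeeping/background and are not scaled in
        # cycling cells
        hep <- classes %in% c("pericentral", "periportal", "functional", "stress")
        for (ci in seq_len(n_c)) {
          w <- prof_l
          if (cycling[ci]) {
            w[hep] <- w[hep] * cc$cycling_hepatocyte_scale
            w[classes == "cycle"] <- w[classes == "cycle"] * cfg$cycle_gene_boost
          }
          mu <- libsize[ci] * w / sum(w)
          cnt <- stats::rnbinom(n_genes, mu = mu, size = cfg$nb_dispersion)
          if (cfg$dropout_rate > 0) {
            cnt[stats::runif(n_genes) < cfg$dropout_rate] <- 0L
          }
          m[, ci] <- cnt
        }
        cells_list[[length(cells_list) + 1L]] <- m
        meta_list[[length(meta_list) + 1L]] <- data.frame(
          condition = cond, injury_model = cc$injury_model,
          true_layer = l, true_cycling = cycling,
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cells_list)
    meta <- do.call(rbind, meta_list)
    meta$barcode <- sprintf("%s_c%05d", meta$condition,
                            stats::ave(seq_len(nrow(meta)), meta$condition, FUN = seq_along))
    meta$mouse <- paste0(meta$condition, "_m", 1 + (seq_len(nrow(meta)) %% 2))
    rownames(counts) <- genes
    colnames(counts) <- meta$barcode
    cm <- hep_counts(Matrix::Matrix(counts, sparse = TRUE), meta)
    truth <- structure(list(
      gene_truth = data.frame(gene = genes, class = classes, slope = slope,
                              stringsAsFactors = FALSE),
      profile = profile,
      cell_truth = cm$cell_meta[, c("barcode", "condition", "true_layer", "true_cycling")],
      conditions = cfg$conditions,
      seed = cfg$seed), class = "sim_truth")
    list(counts = cm, truth = truth)
  })
}

#' Spatial simulation configuration
#'
#' @param vein_radius central-vein radius in micrometres
#' @param lobule_radius lobule (image half-width) radius in micrometres,
#'   must exceed `vein_radius`
#' @param cell_diameter hepatocyte diameter in micrometres (default 30, a
#'   typical hepatocyte)
#' @param profiles named list mapping gene to `function(distance_um)` giving
#'   the mean spot count per cell at that distance from the vein edge
#' @param n_macrophages number of cells labeled as macrophages
#' @param macrophage_boost multiplicative boost of spot counts for cells
#'   within `macrophage_range` of a macrophage
#' @param macrophage_range boost radius in micrometres (default 30)
#' @param seed integer seed
#' @return list of class `spatial_sim_config`
#' @export
spatial_sim_config <- function(vein_radius = 40, lobule_radius = 300,
                               cell_diameter = 30,
                               profiles = list(
                                 Glul = function(d) 30 * exp(-d / 40),
                                 Cyp2e1 = function(d) 25 * exp(-d / 120)),
                               n_macrophages = 0, macrophage_boost = 3,
                               macrophage_range = 30, seed = 1) {
  if (vein_radius >= lobule_radius) stopf("vein_radius must be < lobule_radius")
  if (cell_diameter <= 0) stopf("cell_diameter must be positive")
  structure(list(vein_radius = vein_radius, lobule_radius = lobule_radius,
                 cell_diameter = cell_diameter, profiles = profiles,
                 n_macrophages = n_macrophages,
                 macrophage_boost = macrophage_boost,
                 macrophage_range = macrophage_range, seed = seed),
            class = "spatial_sim_config")
}

#' Simulate an smFISH lobule image
#'
#' Places cells on concentric rings between the vein and the lobule radius
#' at roughly hexagonal spacing (one cell diameter along and between rings,
#' alternate rings phase-shifted). Per cell and gene the spot count is
#' Poisson with mean given by the radial profile at the cell's distance from
#' the vein edge, multiplied by `macrophage_boost` for cells within
#' `macrophage_range` of a macrophage; spots scatter uniformly inside the
#' cell outline. The truth records each gene's planted 90%-mass radius
#' (computed from the noise-free profile integrated over the annulus).
#'
#' @param cfg a `spatial_sim_config`
#' @return list with `image` (a `lobule_image`) and `truth` (per-gene planted
#'   `r90` distances from the vein edge, macrophage ids, and the config)
#' @export
simulate_lobule_image <- function(cfg) {
  stopifnot(inherits(cfg, "spatial_sim_config"))
  with_seed(cfg$seed, {
    cd <- cfg$cell_diameter
    centre <- cfg$lobule_radius + cd
    bounds <- c(0, 0, 2 * centre, 2 * centre)
    ang0 <- seq(0, 2 * pi, length.out = 65)[-65]
    vein <- cbind(centre + cfg$vein_radius * cos(ang0),
                  centre + cfg$vein_radius * sin(ang0))
    if (cfg$vein_radius + cd / 2 > cfg$lobule_radius - cd / 2) {
      stopf("lobule_radius too small to place a cell ring")
    }
    ring_radii <- seq(cfg$vein_radius + cd / 2, cfg$lobule_radius - cd / 2, by = cd)
    cells <- list(); id <- 0L
    for (ri in seq_along(ring_radii)) {
      r <- ring_radii[ri]
      n_on_ring <- max(3L, floor(2 * pi * r / cd))
      phase <- if (ri %% 2 == 0) pi / n_on_ring else 0
      th <- phase + 2 * pi * (seq_len(n_on_ring) - 1) / n_on_ring
      for (t in th) {
        id <- id + 1L
        # small positional jitter: real tissue is not a perfect lattice, and
        # it puts some centroid pairs below one cell diameter; the outline
        # radius is kept small enough that jittered outlines cannot overlap
        jx <- stats::runif(1, -0.12 * cd, 0.12 * cd)
        jy <- stats::runif(1, -0.12 * cd, 0.12 * cd)
        cx <- centre + r * cos(t) + jx; cy <- centre + r * sin(t) + jy
        hex <- seq(0, 2 * pi, length.out = 7)[-7] + t
        outline <- cbind(cx + 0.32 * cd * cos(hex), cy + 0.32 * cd * sin(hex))
        cells[[id]] <- list(id = sprintf("cell_%04d", id),
                            centroid = c(cx, cy), outline = outline,
                            labels = list(macrophage = FALSE))
      }
    }
    n_cells <- length(cells)
    mac_idx <- integer(0)
    if (cfg$n_macrophages > 0) {
      mac_idx <- sample(n_cells, min(cfg$n_macrophages, n_cells))
      for (i in mac_idx) cells[[i]]$labels$macrophage <- TRUE
    }
    centroids <- do.call(rbind, lapply(cells, `[[`, "centroid"))
    dist_to_mac <- if (length(mac_idx)) {
      apply(centroids, 1, function(p) {
        min(sqrt(rowSums((centroids[mac_idx, , drop = FALSE] -
                            matrix(p, length(mac_idx), 2, byrow = TRUE))^2)))
      })
    } else {
      rep(Inf, n_cells)
    }
    cell_dist <- sqrt(rowSums((centroids - centre)^2)) - cfg$vein_radius
    spots <- list()
    for (g in names(cfg$profiles)) {
      lam <- vapply(cell_dist, cfg$profiles[[g]], numeric(1))
      boosted <- dist_to_mac <= cfg$macrophage_range
      boosted[mac_idx] <- FALSE
      lam[boosted] <- lam[boosted] * cfg$macrophage_boost
      lam[mac_idx] <- 0   # macrophages carry no hepatocyte transcripts
      counts <- stats::rpois(n_cells, lam)
      pts <- vector("list", n_cells)
      for (i in which(counts > 0)) {
        out <- cells[[i]]$outline
        bb <- c(range(out[, 1]), range(out[, 2]))
        got <- matrix(numeric(0), ncol = 2)
        while (nrow(got) < counts[i]) {
          cand_x <- stats::runif(2 * counts[i], bb[1], bb[2])
          cand_y <- stats::runif(2 * counts[i], bb[3], bb[4])
          ok <- points_in_polygon(cand_x, cand_y, out)
          got <- rbind(got, cbind(cand_x[ok], cand_y[ok]))
        }
        pts[[i]] <- got[seq_len(counts[i]), , drop = FALSE]
      }
      spots[[g]] <- do.call(rbind, c(pts[!vapply(pts, is.null, logical(1))],
                                     list(matrix(numeric(0), ncol = 2))))
    }
    img <- lobule_image(bounds, pixel_size = 0.5, vein_polygon = vein,
                        cells = cells, spots = spots)
    # planted 90%-mass radius of the density curve: cell packing is uniform
    # per unit area, so the expected ring DENSITY is proportional to the
    # per-cell profile lambda(d); the planted boundary is the 90% point of
    # the cumulative of lambda over distance
    dd <- seq(0, cfg$lobule_radius - cfg$vein_radius, length.out = 2000)
    r90 <- vapply(names(cfg$profiles), function(g) {
      f <- cfg$profiles[[g]](dd)
      cum <- cumsum((f[-1] + f[-length(f)]) / 2 * diff(dd))
      dd[1 + which(cum >= 0.9 * cum[length(cum)])[1]]
    }, numeric(1))
    truth <- list(r90 = r90, macrophage_ids = vapply(cells[mac_idx], `[[`,
                                                     character(1), "id"),
                  cell_distance = cell_dist, config = cfg)
    list(image = img, truth = truth)
  })
}

#' Write a deterministic fixture suite
#'
#' Generates a small standard dataset (the default UT/A6/A24/P3 conditions,
#' one untreated and one expanded lobule image), writes it through the
#' package's own formats, and records a manifest with MD5 checksums.
#'
#' @param outdir output directory (created if absent)
#' @param seed integer seed
#' @param cells_per_layer cells per layer per condition (default 30, a small
#'   but analyzable matrix)
#' @return invisibly, the manifest data.frame (file, md5)
#' @export
write_fixture_suite <- function(outdir, seed = 1, cells_per_layer = 30) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(sim_config(cells_per_layer_per_condition = cells_per_layer,
                                        seed = seed))
  write_count_matrix(sim$counts, file.path(outdir, "counts"))
  write_result_table(sim$truth$cell_truth, file.path(outdir, "truth_cells.tsv"))
  write_result_table(sim$truth$gene_truth, file.path(outdir, "truth_genes.tsv"))
  ut <- simulate_lobule_image(spatial_sim_config(seed = seed))
  expanded <- simulate_lobule_image(spatial_sim_config(
    profiles = list(Glul = function(d) 30 * exp(-d / 100),
                    Cyp2e1 = function(d) 25 * exp(-d / 180)),
    seed = seed + 1))
  write_lobule_image(ut$image, file.path(outdir, "lobule_ut.json"))
  write_lobule_image(expanded$image, file.path(outdir, "lobule_expanded.json"))
  jsonlite::write_json(list(ut_r90 = as.list(ut$truth$r90),
                            expanded_r90 = as.list(expanded$truth$r90),
                            seed = seed),
                       file.path(outdir, "truth_spatial.json"),
                       auto_unbox = TRUE, digits = NA)
  class_sets <- split(sim$truth$gene_truth$gene, sim$truth$gene_truth$class)
  write_gmt(lapply(class_sets, function(g) {
    list(description = "simulated gene class", genes = g)
  }), file.path(outdir, "gene_sets.gmt"))
  files <- c("counts.matrix.tsv", "counts.genes.tsv", "counts.barcodes.tsv",
             "counts.cell_meta.tsv", "truth_cells.tsv", "truth_genes.tsv",
             "lobule_ut.json", "lobule_expanded.json", "truth_spatial.json",
             "gene_sets.gmt")
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  write_result_table(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
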