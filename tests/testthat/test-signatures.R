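# Module scoring, anchor-correlation signature derivation, composite score,
# zonation-table signatures, percent-positive, score agreement.

# a matrix whose genes are identical within each expression bin, so the
# bin-matched control mean is analytically known
homogeneous_bins_norm <- function(n_bins = 5, genes_per_bin = 10, n_cells = 20,
                                  seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0, n_bins * genes_per_bin, n_cells)
    for (b in seq_len(n_bins)) {
      row_vals <- stats::runif(n_cells, 0, 1) + b   # same vector for the bin
      idx <- (b - 1) * genes_per_bin + seq_len(genes_per_bin)
      m[idx, ] <- matrix(row_vals, genes_per_bin, n_cells, byrow = TRUE)
    }
    toy_norm(m)
  })
}

test_that("module score is zero when controls equal the program", {
  nm <- homogeneous_bins_norm()
  sig <- signature_definition("s", c("g01", "g12", "g23"))
  sc <- module_score(nm, sig, n_bins = 5, n_ctrl = 10, seed = 42)
  expect_true(all(abs(sc$score) < 1e-9))
})

test_that("adding a constant to program genes shifts the score by it", {
  nm <- homogeneous_bins_norm()
  sig_genes <- c("g01", "g12", "g23")
  shifted <- as.matrix(nm$values)
  # +0.1 keeps each program gene inside its original expression bin, whose
  # other members are identical, so the control mean is unchanged and the
  # score shift is exact
  shifted[sig_genes, ] <- shifted[sig_genes, ] + 0.1
  nm2 <- toy_norm(shifted, genes = rownames(nm$values))
  sc <- module_score(nm2, signature_definition("s", sig_genes),
                     n_bins = 5, n_ctrl = 10, seed = 42)
  expect_true(all(abs(sc$score - 0.1) < 1e-9))
})

test_that("module score is seed-reproducible and unbiased over reseedings", {
  nm <- toy_norm(withr::with_seed(5, matrix(stats::rexp(50 * 40), 50, 40)))
  sig <- signature_definition("s", c("g03", "g17", "g44"))
  a <- module_score(nm, sig, n_bins = 5, n_ctrl = 20, seed = 9)
  b <- module_score(nm, sig, n_bins = 5, n_ctrl = 20, seed = 9)
  expect_identical(a$score, b$score)
  # expectation over control draws = program mean minus bin-mean-of-pool
  gmeans <- rowMeans(as.matrix(nm$values))
  bin <- as.integer(cut(rank(gmeans, ties.method = "first"), 5,
                        labels = FALSE, include.lowest = TRUE))
  names(bin) <- rownames(nm$values)
  pool_mean <- sapply(colnames(nm$values), function(cc) {
    mean(sapply(sig$genes, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], sig$genes)
      mean(as.matrix(nm$values)[pool, cc])
    }))
  })
  analytic <- colMeans(as.matrix(nm$values)[sig$genes, ]) - pool_mean
  many <- rowMeans(vapply(1:200, function(s) {
    module_score(nm, sig, n_bins = 5, n_ctrl = 20, seed = s)$score
  }, numeric(40)))
  expect_equal(many, unname(analytic), tolerance = 0.02)
})

test_that("missing signature genes are dropped with warning, none left errors", {
  nm <- toy_norm(matrix(stats::runif(100), 10, 10))
  expect_warning(sc <- module_score(nm, signature_definition("s", c("g03", "absent")),
                                    n_bins = 2, n_ctrl = 3, seed = 1),
                 "absent from matrix")
  expect_equal(sc$genes_used, "g03")
  expect_error(suppressWarnings(
    module_score(nm, signature_definition("s", "nothere"), seed = 1)),
    "empty after intersecting")
})

test_that("anchor correlation screen computes Pearson r with exact summary", {
  withr::with_seed(3, {
    anchor <- stats::rnorm(200)
    m <- rbind(anchor,
               -anchor,
               anchor * 0.5 + stats::rnorm(200, sd = 2),
               rep(1, 200),
               stats::rnorm(200))
  })
  nm <- toy_norm(m, genes = c("Cyp2e1", "anti", "partial", "const", "noise"))
  scr <- anchor_correlation_screen(nm)
  expect_equal(unname(scr$r["Cyp2e1"]), 1)
  expect_equal(unname(scr$r["anti"]), -1, tolerance = 1e-12)
  expect_equal(unname(scr$r["const"]), 0)
  expect_true(scr$zero_variance["const"])
  expect_equal(unname(scr$r["partial"]),
               cor(m[3, ], m[1, ]), tolerance = 1e-12)
  # summary arithmetic is exact: mean +/- 3 sd
  s <- scr$summary
  expect_identical(unname(s["mean_plus_3sd"] - s["mean"]),
                   unname(s["mean"] - s["mean_minus_3sd"]))
  expect_equal(unname(s["mean_plus_3sd"]), unname(s["mean"] + 3 * s["sd"]))
  expect_error(anchor_correlation_screen(toy_norm(matrix(1, 2, 5),
                                                  genes = c("Cyp2e1", "x"))),
               "zero variance")
})

test_that("an independent gene's correlation with the anchor stays near 0", {
  withr::with_seed(8, {
    m <- rbind(stats::rnorm(1000), stats::rnorm(1000))
  })
  nm <- toy_norm(m, genes = c("Cyp2e1", "indep"))
  expect_lt(abs(anchor_correlation_screen(nm)$r[["indep"]]), 0.11)
})

test_that("zonal signature derivation recovers planted gene labels", {
  hits <- sapply(101:110, function(seed) {
    # planted zonated genes are slope-matched to the anchor, the situation
    # the correlation screen is built for
    sim <- simulate_expression(sim_config(
      cells_per_layer_per_condition = 25,
      conditions = default_conditions()["UT"],
      slope_range = c(0.35, 0.35), seed = seed))
    nm <- normalize_counts(sim$counts)
    scr <- anchor_correlation_screen(nm)
    sigs <- derive_zonal_signatures(scr, nm)
    truth <- sim$truth$gene_truth
    true_pc <- truth$gene[truth$class == "pericentral"]
    true_pp <- truth$gene[truth$class == "periportal"]
    c(prec_pc = mean(sigs$pch$genes %in% true_pc),
      rec_pc = mean(true_pc %in% sigs$pch$genes),
      prec_pp = mean(sigs$pph$genes %in% true_pp),
      rec_pp = mean(true_pp %in% sigs$pph$genes))
  })
  hits <- as.matrix(hits)
  expect_gte(sum(apply(hits >= 0.9, 2, all)), 9)
})

test_that("zonal signature derivation boundary and error cases", {
  sim <- simulate_expression(sim_config(cells_per_layer_per_condition = 15,
                                        conditions = default_conditions()["UT"],
                                        seed = 4))
  nm <- normalize_counts(sim$counts)
  scr <- anchor_correlation_screen(nm)
  # r_cut = 1 leaves only the anchor in pch and empties pph -> error
  expect_error(derive_zonal_signatures(scr, nm, r_cut = 1.0), "periportal")
  # squeezing all r into (-0.3, 0.3): fake screen
  scr2 <- scr
  scr2$r[] <- 0.1
  scr2$r[scr$anchor] <- 1
  expect_error(derive_zonal_signatures(scr2, nm), "periportal")
})

test_that("composite score is the elementwise PPH minus PCH difference", {
  mk <- function(v) structure(list(score = v, cells = c("a", "b"), genes_used = "g",
                                   n_bins = 25, n_ctrl = 100, seed = 1),
                              class = "module_score_vector")
  expect_equal(composite_zonation_score(mk(c(1, 2)), mk(c(1, 2)))$score, c(0, 0))
  expect_equal(composite_zonation_score(mk(c(0, 0)), mk(c(1, 1)))$score, c(-1, -1))
  bad <- mk(c(1, 2)); bad$cells <- c("x", "y")
  expect_error(composite_zonation_score(mk(c(1, 2)), bad), "same cells")
})

test_that("composite score tracks the true lobule layer on untreated data", {
  rho <- sapply(201:210, function(seed) {
    sim <- simulate_expression(sim_config(
      cells_per_layer_per_condition = 25,
      conditions = default_conditions()["UT"], seed = seed))
    nm <- normalize_counts(sim$counts)
    sigs <- derive_zonal_signatures(anchor_correlation_screen(nm), nm)
    pch <- module_score(nm, sigs$pch, seed = seed + 1)
    pph <- module_score(nm, sigs$pph, seed = seed + 2)
    comp <- composite_zonation_score(pph, pch)
    cor(comp$score, sim$truth$cell_truth$true_layer, method = "spearman")
  })
  expect_true(all(rho > 0.7))
})

test_that("zonation-table signatures apply q, expression and half-mass rules", {
  nm <- toy_norm(matrix(2, 4, 6),
                 genes = c("gene1", "gene2", "gene3", "tie"))
  z <- data.frame(gene = c("gene1", "gene2", "gene3", "tie"),
                  L1 = c(10, 1, 0, 2), L2 = c(5, 1, 0, 3),
                  L3 = c(1, 1, 5, 3), L4 = c(0, 1, 10, 2),
                  q = c(0.001, 0.5, 0.005, 0.001))
  sigs <- halpern_signatures(z, nm)
  expect_equal(sigs$pch$genes, "gene1")
  expect_equal(sigs$pph$genes, "gene3")   # gene2 fails q; tie dropped
  expect_error(halpern_signatures(z, nm, q_cut = 0), "pass")
})

test_that("percent positive uses one pooled threshold and strict inequality", {
  nm <- toy_norm(matrix(c(0, 1, 2, 3, 0, 0, 0, 0), 1, 8),
                 conditions = rep(c("X", "Y"), each = 4), genes = "g")
  pp <- percent_positive(nm, "g")
  expect_equal(pp[["X"]], 75)
  expect_equal(pp[["Y"]], 0)
  # all equal -> nothing strictly above the mean
  nm2 <- toy_norm(matrix(1, 1, 6), conditions = rep(c("X", "Y"), 3), genes = "g")
  expect_equal(unname(percent_positive(nm2, "g")), c(0, 0))
})

test_that("percent positive equals a brute-force two-pass count", {
  for (seed in 1:25) {
    nm <- withr::with_seed(seed, {
      v <- stats::rpois(60, 1.5)
      toy_norm(matrix(v, 1, 60),
               conditions = sample(c("UT", "A6", "A24"), 60, replace = TRUE),
               genes = "g", cells = sprintf("c%03d", 1:60))
    })
    pp <- percent_positive(nm, "g")
    v <- as.numeric(nm$values[1, ])
    thr <- mean(v)
    for (cond in names(pp)) {
      idx <- nm$cell_meta$condition == cond
      expect_equal(pp[[cond]], 100 * sum(v[idx] > thr) / sum(idx))
    }
  }
})

test_that("score agreement computes R^2 with affine invariance", {
  withr::with_seed(2, a <- stats::rnorm(50))
  perfect <- score_agreement(a, 2 * a + 1)
  expect_equal(perfect$r2, 1, tolerance = 1e-12)
  b <- withr::with_seed(3, stats::rnorm(50))
  base <- score_agreement(a, b)
  resc <- score_agreement(3 * a - 2, -0.5 * b + 4)
  expect_equal(base$r2, resc$r2, tolerance = 1e-12)
  # independent large samples give near-zero R^2
  withr::with_seed(4, {
    x <- stats::rnorm(10000); y <- stats::rnorm(10000)
  })
  expect_lt(score_agreement(x, y)$r2, 0.001)
  expect_error(score_agreement(a, rep(1, 50)), "zero variance")
})
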