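test_that("rank-1 shape data yields a single nonzero eigenvalue", {
  set.seed(41)
  a <- matrix(rnorm(60, 0, 30), 20, 3)
  b <- a + matrix(rnorm(60, 0, 3), 20, 3)
  fit <- gpa(c(replicate(4, a, simplify = FALSE), replicate(4, b, simplify = FALSE)))
  pca <- shape_pca(fit)
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-9)
  expect_lt(pca$eigenvalues[2] / pca$eigenvalues[1], 1e-12)
})

test_that("shape PCA matches an independent SVD oracle and conserves variance", {
  set.seed(42)
  spec <- tiny_cohort(n_subjects = 3, noise_sd = 0.5, subject_shape_sd = 5)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  fit <- gpa(extract_cohort_configs(sim, topo))
  pca <- shape_pca(fit)
  n <- dim(fit$aligned)[1]; k <- dim(fit$aligned)[2]
  flat <- t(vapply(seq_len(n), function(i) as.vector(t(fit$aligned[i, , ])),
                   numeric(3 * k)))
  oracle <- svd_pca_oracle(flat)
  m <- min(n - 1, 3 * k)
  expect_equal(pca$eigenvalues[1:m], oracle$eigenvalues[1:m], tolerance = 1e-9)
  sc_pkg <- as.matrix(pca$scores[, paste0("PC", 1:5)])
  for (j in 1:5) { # compare up to the deterministic sign flip
    expect_equal(abs(sc_pkg[, j]), abs(oracle$scores[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:5) expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  # total variance conservation
  total_var <- sum(apply(flat, 2, stats::var))
  expect_equal(sum(pca$eigenvalues), total_var, tolerance = 1e-10 * total_var)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-12)
})

test_that("scores reconstruct aligned coordinates and zero scores give the mean shape", {
  set.seed(43)
  cfgs <- lapply(1:6, function(i) matrix(rnorm(45, 0, 20), 15, 3))
  fit <- gpa(cfgs)
  pca <- shape_pca(fit)
  mean_cfg <- config_matrix(shape_at_scores(pca, numeric(0)))
  expect_equal(mean_cfg, pca$mean_shape, tolerance = 1e-12, ignore_attr = TRUE)
  sc <- as.numeric(as.matrix(pca$scores[3, grep("^PC", names(pca$scores))]))
  rec <- config_matrix(shape_at_scores(pca, sc))
  expect_equal(rec, fit$aligned[3, , ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(shape_at_scores(pca, rep(1, 100)), class = "respmorph_invalid")
})

test_that("PC1 of a breathing-dominated cohort aligns with the generator's deformation mode", {
  # subject variation kept tiny so breathing is the dominant mode
  spec <- tiny_cohort(n_subjects = 3, subject_shape_sd = 0.5, seed = 19)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  fit <- gpa(extract_cohort_configs(sim, topo))
  pca <- shape_pca(fit)
  plus <- config_matrix(shape_at_scores(pca, 2 * sd(pca$scores$PC1)))
  minus <- config_matrix(shape_at_scores(pca, -2 * sd(pca$scores$PC1)))
  pc_mode <- as.vector(plus - minus)
  # generator mode: aligned IN minus aligned EX of one subject (REC)
  info <- fit$info
  rows_in <- which(info$condition == "REC" & info$instant == "IN")
  rows_ex <- which(info$condition == "REC" & info$instant == "EX")
  gen_mode <- as.vector(apply(fit$aligned[rows_in, , , drop = FALSE], c(2, 3), mean) -
                          apply(fit$aligned[rows_ex, , , drop = FALSE], c(2, 3), mean))
  cosine <- abs(sum(pc_mode * gen_mode)) / sqrt(sum(pc_mode^2) * sum(gen_mode^2))
  expect_gt(cosine, 0.9)
})

test_that("functional size recovers the generator truth and responds to amplitude", {
  spec <- tiny_cohort(n_subjects = 3, seed = 23)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  configs <- extract_cohort_configs(sim, topo)
  fs <- functional_size(cohort_cs_table(configs))
  truth <- dplyr::arrange(sim$truth_metrics, subject_id, condition)
  fs <- dplyr::arrange(fs, subject_id, condition)
  expect_equal(fs$FS, truth$true_FS, tolerance = 1e-6)
  # identical instants give FS = 0
  cs0 <- tibble::tibble(subject_id = "A", condition = "QB",
                        instant = c("EX", "EX", "IN", "IN"),
                        centroid_size = c(5, 7, 5, 7))
  expect_equal(functional_size(cs0)$FS, 0)
})

test_that("functional shape is zero for identical shapes and scale-invariant", {
  set.seed(44)
  base <- matrix(rnorm(60, 0, 30), 20, 3)
  cfgs <- list(base, base %*% random_rotation() * 2, base + 100, base * 0.5)
  info <- tibble::tibble(subject_id = "A", condition = "QB",
                         instant = c("EX", "IN", "EX", "IN"), cycle = c(1, 1, 2, 2))
  configs <- dplyr::bind_rows(lapply(1:4, function(i) {
    m <- cfgs[[i]]; rownames(m) <- sprintf("L%02d", 1:20)
    respmorph:::as_config_tibble(m, as.list(info[i, ]))
  }))
  fit <- gpa(configs)
  fsh <- functional_shape(fit)
  expect_equal(fsh$FSh, 0, tolerance = 1e-9)
  # scale invariance on a real cohort
  spec <- tiny_cohort(n_subjects = 2, seed = 45)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  configs <- extract_cohort_configs(sim, topo)
  f1 <- functional_shape(gpa(configs))
  scaled <- dplyr::mutate(configs, x = 3.7 * x, y = 3.7 * y, z = 3.7 * z)
  f2 <- functional_shape(gpa(scaled))
  expect_equal(f1$FSh, f2$FSh, tolerance = 1e-6)
})

test_that("noise-free FSh ranks match the generator truth and grow with amplitude", {
  spec <- tiny_cohort(n_subjects = 4, subject_shape_sd = 6, seed = 29)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  fit <- gpa(extract_cohort_configs(sim, topo))
  fsh <- dplyr::arrange(functional_shape(fit), subject_id, condition)
  truth <- dplyr::arrange(sim$truth_metrics, subject_id, condition)
  expect_equal(rank(fsh$FSh), rank(truth$true_FSh))
})

test_that("respiratory vectors: null when IN equals EX, larger for larger amplitudes", {
  spec <- tiny_cohort(n_subjects = 3, noise_sd = 0.5, subject_shape_sd = 5, seed = 31)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  pca <- shape_pca(gpa(extract_cohort_configs(sim, topo)))
  rv <- respiratory_vectors(pca)
  expect_equal(nrow(rv), 4) # 2 conditions x 2 PCs
  mod <- dplyr::distinct(rv, condition, module)
  expect_gt(mod$module[mod$condition == "REC"], mod$module[mod$condition == "QB"])
  # oracle: direct per-subject summation
  sc <- pca$scores
  for (cond in c("QB", "REC")) {
    per_subj <- sapply(unique(sc$subject_id), function(s) {
      rows <- sc[sc$subject_id == s & sc$condition == cond, ]
      mean(rows$PC1[rows$instant == "IN"]) - mean(rows$PC1[rows$instant == "EX"])
    })
    expect_equal(rv$delta[rv$condition == cond & rv$pc == "PC1"],
                 mean(per_subj), tolerance = 1e-12)
  }
  # degenerate: IN scores equal EX scores
  sc2 <- sc
  sc2[grep("^PC", names(sc2))] <- 0
  pca2 <- pca; pca2$scores <- sc2
  rv2 <- respiratory_vectors(pca2)
  expect_equal(rv2$delta, rep(0, 4))
  expect_equal(rv2$module, rep(0, 4))
})
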