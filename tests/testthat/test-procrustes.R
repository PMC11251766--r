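test_that("centroid size: closed form, homogeneity and the direct-formula oracle", {
  quad <- matrix(c(1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1, 0), 4, 3, byrow = TRUE)
  expect_equal(centroid_size(quad), sqrt(8), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rnorm(89 * 3, 0, 120), 89, 3)
    expect_equal(centroid_size(m), naive_centroid_size(m), tolerance = 1e-12)
    s <- runif(1, 0.1, 10)
    expect_equal(centroid_size(s * m), s * centroid_size(m), tolerance = 1e-12)
  }
  expect_error(centroid_size(matrix(1, 1, 3)), class = "respmorph_invalid")
  expect_error(centroid_size(matrix(NA_real_, 4, 3)), class = "respmorph_invalid")
})

test_that("pairwise alignment recovers a known rotation exactly", {
  set.seed(3)
  m <- matrix(rnorm(30, 0, 50), 10, 3)
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  res <- align_pair(m %*% Rz, m)
  expect_equal(res$residual, 0, tolerance = 1e-9)
  expect_equal(res$rotation, t(Rz), tolerance = 1e-9)
})

test_that("reflection semantics: forbidden by default, recoverable when allowed", {
  set.seed(4)
  m <- matrix(rnorm(30, 0, 50), 10, 3)
  mirrored <- m %*% diag(c(-1, 1, 1))
  strict <- align_pair(mirrored, m, allow_reflection = FALSE)
  loose <- align_pair(mirrored, m, allow_reflection = TRUE)
  expect_gt(strict$residual, 0.1)
  expect_equal(loose$residual, 0, tolerance = 1e-9)
  expect_equal(det(strict$rotation), 1, tolerance = 1e-9)
})

test_that("no random rotation beats the SVD optimum", {
  set.seed(5)
  a <- respmorph:::center_scale(matrix(rnorm(45, 0, 10), 15, 3))$x
  b <- respmorph:::center_scale(matrix(rnorm(45, 0, 10), 15, 3))$x
  best <- align_pair(a, b)$residual
  rand <- replicate(1000, sqrt(sum((a %*% random_rotation() - b)^2)))
  expect_true(all(best <= rand + 1e-12))
})

test_that("GPA of one shape under random similarity motions collapses to a point", {
  set.seed(6)
  base <- config_matrix(cw_template())
  cfgs <- lapply(1:6, function(i) {
    runif(1, 0.5, 2) * base %*% random_rotation() +
      matrix(runif(3, -500, 500), nrow(base), 3, byrow = TRUE)
  })
  fit <- gpa(cfgs)
  expect_true(fit$converged)
  expect_lt(max(fit$distance_matrix), 1e-9)
  # aligned coordinates: centered, unit centroid size
  for (i in 1:6) {
    m <- fit$aligned[i, , ]
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)
  }
  # recorded centroid sizes equal the raw input sizes exactly
  expect_equal(fit$info$centroid_size, vapply(cfgs, centroid_size, numeric(1)))
})

test_that("two-configuration GPA consensus is equidistant from both shapes", {
  set.seed(8)
  a <- matrix(rnorm(89 * 3, 0, 100), 89, 3)
  b <- a + matrix(rnorm(89 * 3, 0, 5), 89, 3)
  fit <- gpa(list(a, b))
  d <- vapply(1:2, function(i) sqrt(sum((fit$aligned[i, , ] - fit$consensus)^2)),
              numeric(1))
  expect_equal(d[1], d[2], tolerance = 1e-9)
})

test_that("Procrustes sum of squares decreases monotonically over iterations", {
  set.seed(9)
  cfgs <- lapply(1:10, function(i) matrix(rnorm(60, 0, 40), 20, 3))
  fit <- gpa(cfgs, tol = 1e-12)
  expect_true(all(diff(fit$ss_history) <= 1e-12))
  expect_true(fit$converged)
})

test_that("GPA distances are invariant to input order and rigid pre-motions", {
  set.seed(10)
  spec <- tiny_cohort(n_subjects = 2, noise_sd = 0.5, subject_shape_sd = 5)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  configs <- extract_cohort_configs(sim, topo)
  fit <- gpa(configs)
  parts <- respmorph:::configs_to_list(configs)
  n <- length(parts$mats)
  # random permutation
  perm <- sample(n)
  fit_perm <- gpa(parts$mats[perm])
  expect_equal(fit_perm$distance_matrix[order(perm), order(perm)],
               fit$distance_matrix, tolerance = 1e-6)
  # random rigid motions and scalings of each input
  moved <- lapply(parts$mats, function(m) {
    runif(1, 0.2, 3) * m %*% random_rotation() +
      matrix(runif(3, -200, 200), nrow(m), 3, byrow = TRUE)
  })
  fit_moved <- gpa(moved)
  expect_equal(fit_moved$distance_matrix, fit$distance_matrix, tolerance = 1e-6)
})

test_that("Procrustes distance is a premetric on shapes: zero, symmetric, triangular", {
  set.seed(12)
  for (i in 1:5) {
    a <- matrix(rnorm(45, 0, 30), 15, 3)
    b <- matrix(rnorm(45, 0, 30), 15, 3)
    c <- matrix(rnorm(45, 0, 30), 15, 3)
    expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-9)
    fit <- gpa(list(a, b, c))
    d <- fit$distance_matrix
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(0, 3))
  }
  expect_error(procrustes_distance(matrix(0, 4, 3) + rnorm(12), matrix(rnorm(15), 5, 3)),
               class = "respmorph_invalid")
})

test_that("GPA rejects degenerate input and flags non-convergence without error", {
  expect_error(gpa(list(matrix(rnorm(12), 4, 3))), class = "respmorph_invalid")
  set.seed(14)
  cfgs <- lapply(1:8, function(i) matrix(rnorm(60, 0, 40), 20, 3))
  fit <- gpa(cfgs, tol = 0, max_iter = 2) # cannot converge in 2 iterations
  expect_false(fit$converged)
  expect_s3_class(fit, "cw_gpa")
})
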