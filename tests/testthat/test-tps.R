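test_that("TPS with target = source is the identity with zero bending energy", {
  set.seed(31)
  src <- matrix(rnorm(60, 0, 50), 20, 3)
  map <- solve_tps(src, src)
  expect_equal(map$bending_energy, 0, tolerance = 1e-8)
  pts <- matrix(rnorm(30, 0, 80), 10, 3)
  expect_equal(predict(map, pts), pts, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("affine targets give zero bending energy and exact affine reproduction", {
  set.seed(32)
  src <- matrix(rnorm(60, 0, 50), 20, 3)
  A <- matrix(rnorm(9, 0, 0.5), 3, 3) + diag(3)
  b <- rnorm(3, 0, 20)
  tgt <- src %*% A + matrix(b, 20, 3, byrow = TRUE)
  map <- solve_tps(src, tgt)
  expect_equal(map$bending_energy, 0, tolerance = 1e-6)
  pts <- matrix(rnorm(300, 0, 100), 100, 3)
  expect_equal(predict(map, pts), pts %*% A + matrix(b, 100, 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("TPS interpolates exactly and matches an independent dense solve off-grid", {
  set.seed(33)
  src <- config_matrix(cw_template())[seq(1, 89, by = 3), ]
  tgt <- src + matrix(rnorm(length(src), 0, 8), nrow(src), 3)
  map <- solve_tps(src, tgt)
  expect_equal(predict(map, src), tgt, tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(map$bending_energy, 0)
  # independent literal kernel-matrix solve, assembled from scratch
  k <- nrow(src)
  K <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) K[i, j] <- sqrt(sum((src[i, ] - src[j, ])^2))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  coefs <- qr.solve(L, rbind(tgt, matrix(0, 4, 3)))
  test_pts <- matrix(rnorm(45, 0, 150), 15, 3)
  manual <- sapply(1:3, function(dd) {
    sapply(seq_len(nrow(test_pts)), function(i) {
      u <- sqrt(colSums((t(src) - test_pts[i, ])^2))
      sum(u * coefs[1:k, dd]) + coefs[k + 1, dd] + sum(test_pts[i, ] * coefs[k + 2:4, dd])
    })
  })
  expect_equal(predict(map, test_pts), manual, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate TPS sources are rejected or warned about", {
  src <- matrix(rnorm(30), 10, 3)
  src[2, ] <- src[1, ]
  expect_error(solve_tps(src, src + 1), class = "respmorph_invalid")
  flat <- cbind(matrix(rnorm(20), 10, 2), 0) # coplanar
  expect_warning(try(solve_tps(flat, flat + rnorm(30)), silent = TRUE), "coplanar")
  expect_error(solve_tps(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3)),
               class = "respmorph_invalid")
})

test_that("missing-landmark estimation recovers held-out markers on a smooth cohort", {
  set.seed(34)
  tmpl <- cw_template()
  ref <- tibble::as_tibble(tmpl[, c("marker_id", "x", "y", "z")])
  # a subject-like smooth deformation of the template
  subject <- dplyr::mutate(ref,
    x = x * 1.04 + 0.02 * z, y = y * 0.97 + 8 * sin(z / 200), z = z * 1.01)
  holdout <- sample(89, 5)
  incomplete <- subject
  incomplete[holdout, c("x", "y", "z")] <- NA
  est <- estimate_missing(incomplete, ref)
  err <- sqrt(rowSums((as.matrix(est[holdout, c("x", "y", "z")]) -
                         as.matrix(subject[holdout, c("x", "y", "z")]))^2))
  expect_lt(max(err), 0.02 * centroid_size(subject)) # within 2% of CS
  # present landmarks untouched
  kept <- setdiff(1:89, holdout)
  expect_identical(as.matrix(est[kept, c("x", "y", "z")]),
                   as.matrix(subject[kept, c("x", "y", "z")]))
})

test_that("estimation is refused above the missing-fraction threshold and is a no-op when complete", {
  tmpl <- cw_template()
  ref <- tibble::as_tibble(tmpl[, c("marker_id", "x", "y", "z")])
  expect_identical(estimate_missing(ref, ref), ref)
  incomplete <- ref
  incomplete[1:30, c("x", "y", "z")] <- NA # 30 of 89 > 20%
  expect_error(estimate_missing(incomplete, ref), class = "respmorph_too_missing")
})

test_that("missing-landmark estimation commutes with rigid motion", {
  set.seed(35)
  tmpl <- cw_template()
  ref <- tibble::as_tibble(tmpl[, c("marker_id", "x", "y", "z")])
  subject <- dplyr::mutate(ref, x = x * 1.03, y = y * 0.96, z = z + 4 * sin(x / 100))
  holdout <- sample(89, 6)
  incomplete <- subject
  incomplete[holdout, c("x", "y", "z")] <- NA
  est_plain <- estimate_missing(incomplete, ref)
  R <- random_rotation()
  rot_tbl <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% R
    dplyr::mutate(df, x = m[, 1], y = m[, 2], z = m[, 3])
  }
  est_rot <- estimate_missing(rot_tbl(incomplete), rot_tbl(ref))
  expect_equal(as.matrix(est_rot[, c("x", "y", "z")]),
               as.matrix(rot_tbl(est_plain)[, c("x", "y", "z")]),
               tolerance = 1e-8)
})

test_that("mesh warping: identity, rigid motion, and EX->IN volume increase", {
  mesh <- template_mesh()
  lms <- mesh$vertices
  warped_id <- warp_mesh(mesh, lms, lms)
  expect_equal(warped_id$vertices, mesh$vertices, tolerance = 1e-8)
  R <- random_rotation()
  shift <- matrix(c(10, -20, 5), nrow(lms), 3, byrow = TRUE)
  warped_rigid <- warp_mesh(mesh, lms, lms %*% R + shift)
  expect_equal(warped_rigid$vertices, mesh$vertices %*% R + shift, tolerance = 1e-7)
  # EX -> IN targets from the generator increase the warped enclosed volume
  spec <- tiny_cohort(n_subjects = 1)
  sim <- simulate_cohort(spec)
  topo <- default_topology(spec$template)
  tc <- sim$truth_configs
  ex <- config_matrix(dplyr::filter(tc, condition == "REC", instant == "EX"),
                      topo$marker_ids)
  inn <- config_matrix(dplyr::filter(tc, condition == "REC", instant == "IN"),
                       topo$marker_ids)
  mesh_ex <- warp_mesh(mesh, lms, ex)
  mesh_in <- warp_mesh(mesh, lms, inn)
  vol <- function(m) respmorph:::signed_volume(m$vertices, m$faces)
  expect_gt(vol(mesh_in), vol(mesh_ex))
})
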