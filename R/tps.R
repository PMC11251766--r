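#' Solve a 3D thin-plate spline interpolant
#'
#' Classical thin-plate spline in three dimensions with kernel
#' `U(r) = r`, a full affine part, and the usual side conditions that make
#' the non-affine weights orthogonal to the affine space. The map
#' interpolates: evaluating at source landmark i returns target landmark i
#' exactly (to numerical precision). The bending energy is the non-affine
#' quadratic form; it is zero exactly when the map is affine.
#'
#' @param source,target k x 3 matrices (or configuration tibbles) of paired
#'   landmarks, k >= 5, source points not coplanar.
#' @return An object of class `tps_map`: list with `source`, `weights`
#'   (k x 3 non-affine coefficients), `affine` (4 x 3: translation row then
#'   linear map), and `bending_energy`.
#' @export
solve_tps <- function(source, target) {
  src <- config_matrix(source); tgt <- config_matrix(target)
  if (nrow(src) != nrow(tgt)) stop_invalid("Source and target landmark counts differ.")
  k <- nrow(src)
  if (k < 5) stop_invalid("3D TPS needs at least 5 landmarks.")
  D <- as.matrix(stats::dist(src))
  if (any(D[upper.tri(D)] == 0)) {
    stop_invalid("Duplicate source landmarks make the TPS system singular.")
  }
  P <- cbind(1, src)
  qr_rank <- qr(P)$rank
  if (qr_rank < 4) warn("Source landmarks are coplanar; TPS system is ill-conditioned.")
  L <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  coefs <- tryCatch(solve(L, rhs),
                    error = function(e) stop_invalid(paste0("Singular TPS system: ", conditionMessage(e))))
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:4, , drop = FALSE]
  # |r| is conditionally negative definite under the side conditions, so the
  # positive bending energy is the negated form
  be <- -sum(diag(t(W) %*% D %*% W))
  be <- max(be, 0)
  structure(list(source = src, weights = W, affine = A, bending_energy = be,
                 marker_ids = rownames(src)),
            class = "tps_map")
}

#' Evaluate a thin-plate spline map at new points
#'
#' @param object A `tps_map`.
#' @param newdata Points to map: m x 3 matrix or configuration tibble.
#' @param ... Unused.
#' @return m x 3 matrix of mapped points.
#' @export
predict.tps_map <- function(object, newdata, ...) {
  pts <- config_matrix(newdata)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(object$source))) +
    outer(rep(1, nrow(pts)), rowSums(object$source^2)) -
    2 * pts %*% t(object$source)
  K <- sqrt(pmax(d2, 0))
  out <- K %*% object$weights + cbind(1, pts) %*% object$affine
  rownames(out) <- rownames(pts)
  out
}

#' @export
print.tps_map <- function(x, ...) {
  cat(sprintf("<tps_map> %d control points, bending energy %.4g\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

#' Estimate missing landmarks by thin-plate spline from a reference
#'
#' Solves a TPS from the reference configuration to the incomplete
#' configuration on the landmarks present in both, then reads the missing
#' positions off the warped reference — the classical TPS missing-landmark
#' recovery used in geometric morphometrics. Present landmarks are returned
#' untouched.
#'
#' @param config Configuration tibble with `NA` coordinates at missing
#'   markers.
#' @param reference Complete reference configuration with the same marker
#'   set (typically the mean of the subject's complete configurations, else
#'   a cohort mean; see [complete_reference()]).
#' @param max_missing_frac Refuse estimation if more than this fraction of
#'   landmarks is missing (default 0.2).
#' @return The completed configuration tibble.
#' @export
estimate_missing <- function(config, reference, max_missing_frac = 0.2) {
  cm <- config_matrix(config)
  rm_ <- config_matrix(reference, rownames(cm))
  if (anyNA(rm_)) stop_invalid("Reference configuration must be complete.")
  miss <- rowSums(is.na(cm)) > 0
  if (!any(miss)) return(config)
  frac <- mean(miss)
  if (frac > max_missing_frac) {
    stop_invalid(sprintf("%.0f%% of landmarks missing exceeds max_missing_frac = %.0f%%.",
                         100 * frac, 100 * max_missing_frac),
                 class = "respmorph_too_missing")
  }
  if (sum(!miss) < 5) stop_invalid("Need at least 5 shared landmarks to estimate the rest.")
  map <- solve_tps(rm_[!miss, , drop = FALSE], cm[!miss, , drop = FALSE])
  est <- predict(map, rm_[miss, , drop = FALSE])
  cm[miss, ] <- est
  filled <- config
  filled$x <- cm[, 1]; filled$y <- cm[, 2]; filled$z <- cm[, 3]
  filled
}

#' Reference configuration for missing-landmark estimation
#'
#' Marker-wise mean of the complete configurations of the same subject when
#' at least `min_n` exist (they share the subject's laboratory frame, and
#' subject-specific shape is closest to the incomplete configuration,
#' reducing estimation bias). Otherwise the cohort consensus is used:
#' the GPA consensus of all complete configurations, rescaled to their mean
#' centroid size — subjects sit in different laboratory frames, so a raw
#' coordinate-wise mean across subjects would not be a valid torso shape
#' (the TPS affine part absorbs the frame difference between reference and
#' configuration).
#'
#' @param configs Tidy configurations tibble.
#' @param subject Subject id the reference is for.
#' @param min_n Minimum number of complete own configurations (default 2).
#' @return A complete configuration tibble (`marker_id`, `x`, `y`, `z`), or
#'   an error if the dataset holds no complete configuration at all.
#' @export
complete_reference <- function(configs, subject, min_n = 2) {
  parts <- configs_to_list(configs)
  complete <- vapply(parts$mats, function(m) !anyNA(m), logical(1))
  if (!any(complete)) stop_invalid("No complete configuration available as TPS reference.")
  own <- complete & (parts$info$subject_id %||% "") == subject
  if (sum(own) >= min_n) {
    mean_m <- Reduce(`+`, parts$mats[own]) / sum(own)
  } else if (sum(complete) == 1) {
    mean_m <- parts$mats[complete][[1]]
  } else {
    fit <- gpa(parts$mats[complete])
    mean_m <- fit$consensus * mean(fit$info$centroid_size)
  }
  rownames(mean_m) <- parts$marker_ids
  as_config_tibble(mean_m)
}

#' Warp a triangulated surface mesh through a thin-plate spline
#'
#' Maps every mesh vertex through the TPS defined by paired source and
#' target landmark sets; faces are unchanged. Used to visualize theoretical
#' shapes (e.g. mean end-expiratory vs end-inspiratory configurations) on a
#' torso surface.
#'
#' @param mesh A `surface_mesh` (see [surface_mesh()]).
#' @param source_lms,target_lms Paired landmark sets in the mesh's frame.
#' @return The warped `surface_mesh`.
#' @export
warp_mesh <- function(mesh, source_lms, target_lms) {
  stopifnot(inherits(mesh, "surface_mesh"))
  map <- solve_tps(source_lms, target_lms)
  out <- mesh
  out$vertices <- predict(map, mesh$vertices)
  out
}
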