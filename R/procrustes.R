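#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances between each landmark and the
#' configuration centroid — the standard geometric-morphometric size measure
#' that is separated from shape.
#'
#' @param config A configuration tibble (`marker_id`, `x`, `y`, `z`) or a
#'   k x 3 matrix.
#' @return Centroid size in the units of the coordinates (mm).
#' @examples
#' centroid_size(matrix(c(1, 1, -1, -1, 1, -1, 1, -1, 0, 0, 0, 0), 4, 3)) # sqrt(8)
#' @export
centroid_size <- function(config) {
  m <- config_matrix(config)
  if (nrow(m) < 2) stop_invalid("Centroid size needs at least 2 landmarks.")
  if (anyNA(m)) stop_invalid("Configuration has missing landmarks; estimate them first.")
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

center_scale <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  if (cs == 0) stop_invalid("Degenerate configuration: all landmarks coincide.")
  list(x = m / cs, cs = cs)
}

#' Optimal superimposition of one configuration onto another
#'
#' Centers both configurations, scales them to unit centroid size, and finds
#' the rotation of `mobile` minimizing the summed squared differences to
#' `target` (orthogonal Procrustes, via SVD). Reflections are forbidden by
#' default (`det(R) = +1`), as appropriate for anatomical data.
#'
#' @param mobile,target Configurations with identical landmark count/order.
#' @param allow_reflection If `TRUE`, improper rotations are allowed.
#' @return List with `rotation` (3 x 3), `residual` (the Procrustes distance
#'   between the superimposed unit-size shapes), and the aligned `mobile`
#'   coordinates (`aligned`).
#' @export
align_pair <- function(mobile, target, allow_reflection = FALSE) {
  xm <- config_matrix(mobile); xt <- config_matrix(target)
  if (nrow(xm) != nrow(xt)) stop_invalid("Landmark counts differ between configurations.")
  a <- center_scale(xm); b <- center_scale(xt)
  rot <- optimal_rotation(a$x, b$x, allow_reflection)
  aligned <- a$x %*% rot
  list(rotation = rot, residual = sqrt(sum((aligned - b$x)^2)), aligned = aligned)
}

optimal_rotation <- function(x, target, allow_reflection = FALSE) {
  s <- svd(crossprod(x, target))
  rot <- s$u %*% t(s$v)
  if (!allow_reflection && det(rot) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    rot <- u %*% t(s$v)
  }
  rot
}

#' Procrustes distance between two shapes
#'
#' Euclidean distance between the centered, unit-centroid-size coordinate
#' sets — the conventional partial-Procrustes shape distance of standard
#' geometric-morphometric software. With `align = TRUE` (default) the mobile
#' shape is first rotated optimally onto the other; with `align = FALSE` the
#' shapes are assumed already superimposed (e.g. both from a common GPA).
#'
#' @param a,b Configurations (tibbles or k x 3 matrices).
#' @param align Optimally rotate `b` onto `a` before measuring.
#' @param allow_reflection Passed to the rotation step.
#' @return Dimensionless distance, >= 0, symmetric, 0 iff same shape.
#' @export
procrustes_distance <- function(a, b, align = TRUE, allow_reflection = FALSE) {
  xa <- center_scale(config_matrix(a)); xb <- center_scale(config_matrix(b))
  if (nrow(xa$x) != nrow(xb$x)) stop_invalid("Landmark counts differ between configurations.")
  if (align) {
    rot <- optimal_rotation(xb$x, xa$x, allow_reflection)
    sqrt(sum((xb$x %*% rot - xa$x)^2))
  } else {
    sqrt(sum((xb$x - xa$x)^2))
  }
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of many landmark configurations: every
#' configuration is centered, scaled to unit centroid size (full Procrustes,
#' Kendall shape), registered to the first configuration, and then repeatedly
#' rotated onto the running consensus until the total Procrustes sum of
#' squares stops changing. Original centroid sizes are recorded before
#' scaling so that size can be analysed separately from shape.
#'
#' @param configs A tidy configurations tibble (one row per marker per
#'   configuration) with id columns (any of `subject_id`, `posture`,
#'   `condition`, `instant`, `cycle`) plus `marker_id`, `x`, `y`, `z`; or a
#'   list of k x 3 matrices.
#' @param tol Convergence tolerance on the change in total Procrustes sum of
#'   squares (default 1e-8).
#' @param max_iter Maximum number of consensus iterations (default 100).
#' @param allow_reflection Allow improper rotations (default `FALSE`).
#' @return An object of class `cw_gpa`: list with `consensus` (k x 3, unit
#'   centroid size), `aligned` (n x k x 3 array), `info` (tibble of id
#'   columns plus `centroid_size`), `distance_matrix` (n x n Procrustes
#'   distances between aligned shapes), `marker_ids`, `iterations`,
#'   `converged`, `ss_history`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 100, allow_reflection = FALSE) {
  parts <- configs_to_list(configs)
  mats <- parts$mats
  n <- length(mats)
  if (n < 2) stop_invalid("GPA needs at least 2 configurations.")
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 1L) != k)) stop_invalid("Configurations have mismatched landmark sets.")

  cs <- vapply(mats, centroid_size, numeric(1))
  scaled <- lapply(mats, function(m) center_scale(m)$x)

  # initial registration on the first configuration
  aligned <- lapply(scaled, function(m) m %*% optimal_rotation(m, scaled[[1]], allow_reflection))
  consensus <- renorm(Reduce(`+`, aligned) / n)
  ss_history <- numeric(0)
  ss_old <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    aligned <- lapply(aligned, function(m) m %*% optimal_rotation(m, consensus, allow_reflection))
    consensus <- renorm(Reduce(`+`, aligned) / n)
    ss <- sum(vapply(aligned, function(m) sum((m - consensus)^2), numeric(1)))
    ss_history <- c(ss_history, ss)
    if (abs(ss_old - ss) < tol) { converged <- TRUE; break }
    ss_old <- ss
  }

  arr <- array(NA_real_, c(n, k, 3))
  for (i in seq_len(n)) arr[i, , ] <- aligned[[i]]
  flat <- matrix(arr, n, k * 3)
  dm <- as.matrix(stats::dist(flat))
  dimnames(dm) <- NULL

  info <- parts$info
  info$centroid_size <- cs
  structure(list(consensus = structure(consensus, dimnames = list(parts$marker_ids, c("x", "y", "z"))),
                 aligned = arr, info = info, distance_matrix = dm,
                 marker_ids = parts$marker_ids,
                 iterations = iter, converged = converged, ss_history = ss_history,
                 tol = tol),
            class = "cw_gpa")
}

renorm <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

id_cols <- c("subject_id", "posture", "condition", "instant", "cycle")

configs_to_list <- function(configs) {
  if (is.list(configs) && !is.data.frame(configs)) {
    mats <- lapply(configs, config_matrix)
    ids <- rownames(mats[[1]]) %||% sprintf("L%03d", seq_len(nrow(mats[[1]])))
    return(list(mats = mats, marker_ids = ids,
                info = tibble(config = seq_along(mats))))
  }
  stopifnot(is.data.frame(configs))
  present <- intersect(id_cols, names(configs))
  if (!length(present)) {
    return(list(mats = list(config_matrix(configs)),
                marker_ids = configs$marker_id,
                info = tibble(config = 1L)))
  }
  keys <- do.call(paste, c(configs[present], sep = "\r"))
  ord <- !duplicated(keys)
  info <- as_tibble(configs[ord, present, drop = FALSE])
  marker_ids <- configs$marker_id[keys == keys[1]]
  mats <- lapply(split(seq_len(nrow(configs)), factor(keys, levels = unique(keys))),
                 function(i) config_matrix(configs[i, ], marker_ids))
  list(mats = unname(mats), marker_ids = marker_ids, info = info)
}

#' @export
print.cw_gpa <- function(x, ...) {
  cat(sprintf("<cw_gpa> %d configurations x %d landmarks; %d iterations (%s)\n",
              nrow(x$info), length(x$marker_ids), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
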