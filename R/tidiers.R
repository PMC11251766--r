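#' Tidy a trajectory set into long format
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return Long tibble: `subject_id`, `condition`, `frame`, `time_s`,
#'   `marker_id`, `x`, `y`, `z`, `missing`.
#' @method tidy trajectory_set
#' @export
tidy.trajectory_set <- function(x, ...) {
  nf <- dim(x$coords)[1]; k <- length(x$marker_ids)
  tibble(subject_id = x$subject_id, condition = x$condition,
         frame = rep(seq_len(nf), each = k),
         time_s = rep(x$time_s, each = k),
         marker_id = rep(x$marker_ids, nf),
         x = as.vector(t(x$coords[, , 1])),
         y = as.vector(t(x$coords[, , 2])),
         z = as.vector(t(x$coords[, , 3])),
         missing = as.vector(t(x$missing)))
}

#' @method glance trajectory_set
#' @export
glance.trajectory_set <- function(x, ...) {
  tibble(subject_id = x$subject_id, condition = x$condition, posture = x$posture,
         n_frames = dim(x$coords)[1], n_markers = length(x$marker_ids),
         sampling_rate_hz = x$sampling_rate_hz,
         duration_s = diff(range(x$time_s)),
         missing_frac = mean(x$missing))
}

#' Tidy Procrustes-aligned coordinates
#'
#' @param x A `cw_gpa`.
#' @param ... Unused.
#' @return Long tibble of aligned coordinates with the configuration id
#'   columns.
#' @method tidy cw_gpa
#' @export
tidy.cw_gpa <- function(x, ...) {
  n <- dim(x$aligned)[1]
  bind_rows(lapply(seq_len(n), function(i) {
    m <- x$aligned[i, , ]
    rownames(m) <- x$marker_ids
    as_config_tibble(m, as.list(x$info[i, , drop = FALSE]))
  }))
}

#' @method glance cw_gpa
#' @export
glance.cw_gpa <- function(x, ...) {
  tibble(n_configurations = dim(x$aligned)[1], n_landmarks = dim(x$aligned)[2],
         iterations = x$iterations, converged = x$converged,
         procrustes_ss = tail(x$ss_history, 1),
         mean_centroid_size = mean(x$info$centroid_size))
}

#' Tidy shape-PCA eigenvalues or scores
#'
#' @param x A `shape_pca`.
#' @param what `"eigenvalues"` (default) or `"scores"`.
#' @param ... Unused.
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, what = c("eigenvalues", "scores"), ...) {
  what <- match.arg(what)
  if (what == "scores") return(x$scores)
  tibble(pc = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         variance_fraction = x$variance_fraction,
         cumulative_fraction = cumsum(x$variance_fraction))
}

#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(n = x$n, n_components = length(x$eigenvalues),
         pc1_fraction = x$variance_fraction[1],
         pc2_fraction = x$variance_fraction[2],
         total_variance = sum(x$eigenvalues))
}
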