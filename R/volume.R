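#' Enclosed volume of a closed landmark mesh
#'
#' Volume enclosed by the triangulated marker surface, computed by the
#' divergence theorem as the sum of signed tetrahedra spanned by the origin
#' and each triangle. For a closed, consistently outward-oriented surface the
#' result is independent of the origin (asserted in the test suite) and
#' positive.
#'
#' @param config A single landmark configuration (tibble with `marker_id`,
#'   `x`, `y`, `z`, or k x 3 matrix ordered like `topo$marker_ids`).
#' @param topo A `mesh_topology` from [default_topology()] or [read_topology()].
#' @return Enclosed volume in mm^3 (scalar).
#' @examples
#' tmpl <- cw_template()
#' topo <- default_topology(tmpl)
#' enclosed_volume(tmpl, topo)
#' @export
enclosed_volume <- function(config, topo) {
  m <- config_matrix(config, if (is.matrix(config)) NULL else topo$marker_ids)
  if (nrow(m) != length(topo$marker_ids)) {
    stop_invalid("Configuration and topology marker counts differ.")
  }
  if (anyNA(m)) {
    stop_invalid(paste("Configuration has missing markers; estimate them first",
                       "(see estimate_missing()) before computing volumes."),
                 class = "respmorph_missing_markers")
  }
  signed_volume(m, topo$triangles)
}

signed_volume <- function(m, tri) {
  v1 <- m[tri[, 1], , drop = FALSE]
  v2 <- m[tri[, 2], , drop = FALSE]
  v3 <- m[tri[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(v1 * cr) / 6
}

#' Per-frame chest-wall volume signal of a trajectory
#'
#' Applies [enclosed_volume()] to every frame of a trajectory. Frames with
#' any missing marker yield `NA` volumes (flagged, never fabricated).
#'
#' @param traj A `trajectory_set` (see [simulate_cohort()] /
#'   [read_trajectories()]).
#' @param topo A `mesh_topology`.
#' @return A tibble with columns `subject_id`, `condition`, `frame`, `time_s`,
#'   `volume_mm3`, `n_missing`, of class `breath_signal`.
#' @export
volume_signal <- function(traj, topo) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (!identical(traj$marker_ids, topo$marker_ids)) {
    ord <- match(topo$marker_ids, traj$marker_ids)
    if (anyNA(ord)) stop_invalid("Trajectory markers do not match the topology marker set.")
  } else {
    ord <- seq_along(topo$marker_ids)
  }
  nf <- dim(traj$coords)[1]
  n_missing <- rowSums(traj$missing)
  # fully vectorized: frames x triangles blocks of the divergence-theorem sum
  X <- traj$coords[, ord, 1, drop = TRUE]
  Y <- traj$coords[, ord, 2, drop = TRUE]
  Z <- traj$coords[, ord, 3, drop = TRUE]
  if (nf == 1L) { X <- matrix(X, 1); Y <- matrix(Y, 1); Z <- matrix(Z, 1) }
  tri <- topo$triangles
  i <- tri[, 1]; j <- tri[, 2]; l <- tri[, 3]
  vol <- rowSums(
    X[, i, drop = FALSE] * (Y[, j, drop = FALSE] * Z[, l, drop = FALSE] -
                              Z[, j, drop = FALSE] * Y[, l, drop = FALSE]) +
      Y[, i, drop = FALSE] * (Z[, j, drop = FALSE] * X[, l, drop = FALSE] -
                                X[, j, drop = FALSE] * Z[, l, drop = FALSE]) +
      Z[, i, drop = FALSE] * (X[, j, drop = FALSE] * Y[, l, drop = FALSE] -
                                Y[, j, drop = FALSE] * X[, l, drop = FALSE])) / 6
  vol[n_missing > 0] <- NA_real_
  out <- tibble(subject_id = traj$subject_id, condition = traj$condition,
                frame = seq_len(nf), time_s = traj$time_s,
                volume_mm3 = vol, n_missing = n_missing)
  class(out) <- c("breath_signal", class(out))
  out
}
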