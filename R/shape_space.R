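#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigendecomposition of the variance–covariance matrix of the mean-centered,
#' flattened Procrustes-aligned coordinates of a GPA. PC signs follow a
#' deterministic convention (the largest-magnitude loading entry of each PC
#' is positive) so that score medians are comparable across runs.
#'
#' @param fit A `cw_gpa` from [gpa()] with at least 3 configurations.
#' @return An object of class `shape_pca`: list with `eigenvalues`
#'   (descending, >= 0), `variance_fraction`, `scores` (tibble: id columns
#'   plus `PC1`, `PC2`, ...), `loadings` (3k x m orthonormal columns, rows in
#'   x,y,z-per-landmark order), `mean_shape` (k x 3), `marker_ids`.
#' @export
shape_pca <- function(fit) {
  stopifnot(inherits(fit, "cw_gpa"))
  n <- dim(fit$aligned)[1]; k <- dim(fit$aligned)[2]
  if (n < 3) stop_invalid("Shape PCA needs at least 3 configurations.")
  flat <- t(vapply(seq_len(n), function(i) as.vector(t(fit$aligned[i, , ])), numeric(3 * k)))
  mu <- colMeans(flat)
  centered <- sweep(flat, 2, mu)
  S <- crossprod(centered) / (n - 1)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  m <- min(n - 1, 3 * k)
  vec <- eig$vectors[, seq_len(m), drop = FALSE]
  ev <- ev[seq_len(m)]
  # sign convention
  for (j in seq_len(m)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- centered %*% vec
  colnames(scores) <- paste0("PC", seq_len(m))
  structure(list(eigenvalues = ev, variance_fraction = ev / sum(ev),
                 scores = bind_cols(fit$info, as_tibble(scores)),
                 loadings = vec,
                 mean_shape = matrix(mu, k, 3, byrow = TRUE,
                                     dimnames = list(fit$marker_ids, c("x", "y", "z"))),
                 marker_ids = fit$marker_ids, n = n),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d configurations; PC1 %.2f%%, PC2 %.2f%% of shape variance\n",
              x$n, 100 * x$variance_fraction[1], 100 * x$variance_fraction[2]))
  invisible(x)
}

#' Functional size: net centroid-size change per breath
#'
#' FS = mean centroid size over end-inspiratory cycles minus mean centroid
#' size over end-expiratory cycles, per subject and breathing condition.
#' Positive FS means the chest wall is larger at end inspiration, as the
#' inspired tidal volume implies.
#'
#' @param cs_table Tibble with columns `subject_id`, `condition`, `instant`,
#'   `centroid_size` (plus optional `posture`, `cycle`) — e.g. the `info`
#'   element of a [gpa()] fit, or any table of raw centroid sizes (FS does
#'   not depend on superimposition).
#' @return Tibble per subject x condition with `FS` (mm) and cycle counts.
#'   Subjects lacking one instant get `NA` with a warning.
#' @export
functional_size <- function(cs_table) {
  grp <- intersect(c("subject_id", "posture", "condition"), names(cs_table))
  out <- cs_table %>%
    group_by(across(all_of(grp))) %>%
    summarise(FS = mean(.data$centroid_size[.data$instant == "IN"]) -
                mean(.data$centroid_size[.data$instant == "EX"]),
              n_in = sum(.data$instant == "IN"),
              n_ex = sum(.data$instant == "EX"), .groups = "drop")
  if (anyNA(out$FS) || any(out$n_in == 0 | out$n_ex == 0)) {
    warn("Some subject/condition cells lack an EX or IN configuration; FS set to NA there.")
  }
  out
}

#' Functional shape: net shape change per breath
#'
#' FSh = Procrustes distance between the cycle-mean end-inspiratory and
#' cycle-mean end-expiratory aligned shapes of each subject and condition,
#' measured inside a common GPA. The mean per-cycle distance taken from the
#' GPA distance matrix is emitted alongside for audit.
#'
#' @param fit A `cw_gpa` whose `info` carries `subject_id`, `condition`,
#'   `instant` (and optionally `cycle`, `posture`).
#' @return Tibble per subject x condition with `FSh` and `FSh_cycle_mean`.
#' @export
functional_shape <- function(fit) {
  stopifnot(inherits(fit, "cw_gpa"))
  info <- fit$info
  if (!all(c("subject_id", "condition", "instant") %in% names(info))) {
    stop_invalid("GPA info lacks subject_id/condition/instant metadata needed for FSh.")
  }
  grp <- intersect(c("subject_id", "posture", "condition"), names(info))
  keys <- do.call(paste, c(info[grp], sep = "\r"))
  out <- lapply(unique(keys), function(kk) {
    rows <- which(keys == kk)
    i_in <- rows[info$instant[rows] == "IN"]
    i_ex <- rows[info$instant[rows] == "EX"]
    if (!length(i_in) || !length(i_ex)) {
      stop_invalid(sprintf("Subject/condition cell lacks an EX or IN configuration (%s).",
                           gsub("\r", "/", kk)))
    }
    mean_cfg <- function(ix) apply(fit$aligned[ix, , , drop = FALSE], c(2, 3), mean)
    d_means <- procrustes_distance(mean_cfg(i_in), mean_cfg(i_ex), align = FALSE)
    pairs <- expand.grid(a = i_in, b = i_ex)
    same_cycle <- if ("cycle" %in% names(info)) {
      info$cycle[pairs$a] == info$cycle[pairs$b]
    } else rep(TRUE, nrow(pairs))
    if (!any(same_cycle)) same_cycle <- rep(TRUE, nrow(pairs))
    d_cyc <- mean(fit$distance_matrix[cbind(pairs$a, pairs$b)][same_cycle])
    bind_cols(info[rows[1], grp], tibble(FSh = d_means, FSh_cycle_mean = d_cyc))
  })
  bind_rows(out)
}

#' Mean respiratory vectors in PC-score space
#'
#' The mean (over subjects) displacement from end-expiratory to
#' end-inspiratory PC scores, per breathing condition, in a chosen PC
#' subspace (PC1–PC2 by default). The vector's module summarises how much
#' breathing moves configurations through shape space; larger tidal volumes
#' yield larger modules.
#'
#' @param pca A `shape_pca`.
#' @param pcs Integer vector of PCs spanning the subspace (default `1:2`).
#' @return Tibble with columns `condition`, `pc`, `delta` (mean IN - EX
#'   score) and `module` (vector norm, repeated within condition).
#' @export
respiratory_vectors <- function(pca, pcs = 1:2) {
  stopifnot(inherits(pca, "shape_pca"))
  sc <- pca$scores
  if (!all(c("condition", "instant", "subject_id") %in% names(sc))) {
    stop_invalid("PC scores lack subject/condition/instant metadata.")
  }
  pc_cols <- paste0("PC", pcs)
  if (!all(pc_cols %in% names(sc))) stop_invalid("Requested PCs exceed those available.")
  per_subj <- sc %>%
    group_by(.data$condition, .data$subject_id, .data$instant) %>%
    summarise(across(all_of(pc_cols), mean), .groups = "drop") %>%
    tidyr::pivot_longer(all_of(pc_cols), names_to = "pc", values_to = "score") %>%
    tidyr::pivot_wider(names_from = "instant", values_from = "score") %>%
    mutate(delta = .data$IN - .data$EX)
  if (!nrow(per_subj)) stop_invalid("No configurations for any condition.")
  out <- per_subj %>%
    group_by(.data$condition, .data$pc) %>%
    summarise(delta = mean(.data$delta), .groups = "drop_last") %>%
    mutate(module = sqrt(sum(.data$delta^2))) %>%
    ungroup()
  out
}

#' Theoretical shape at given PC scores
#'
#' Reconstructs the landmark configuration `mean_shape + sum(score_i *
#' loading_i)`, the "theoretical shape" used as warping target: feeding a
#' configuration's own full score vector reproduces its aligned coordinates.
#'
#' @param pca A `shape_pca`.
#' @param scores Numeric vector of PC scores (recycled zeros for omitted
#'   trailing PCs).
#' @return Configuration tibble (`marker_id`, `x`, `y`, `z`).
#' @export
shape_at_scores <- function(pca, scores) {
  stopifnot(inherits(pca, "shape_pca"))
  m <- ncol(pca$loadings)
  if (length(scores) > m) stop_invalid("More scores supplied than available PCs.")
  s <- c(scores, rep(0, m - length(scores)))
  flat <- as.vector(pca$mean_shape |> t()) + as.vector(pca$loadings %*% s)
  mat <- matrix(flat, ncol = 3, byrow = TRUE,
                dimnames = list(pca$marker_ids, c("x", "y", "z")))
  as_config_tibble(mat)
}
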