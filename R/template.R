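#' Standard 89-marker chest-wall template
#'
#' Builds the idealized marker template used throughout the package: eight
#' circumferential rows of markers on an elliptical-cross-section torso plus a
#' single cranial pole marker, 89 markers in total for the default layout.
#' The upper four rows (and the pole) are thoracic, the lower four abdominal.
#' Marker columns are angularly aligned across rows so that column 1 forms the
#' sternal (ventral midline) line and the opposite column the vertebral line.
#'
#' The exact anatomical placement used by commercial optoelectronic
#' plethysmography systems is proprietary; this layout is a documented
#' stand-in with the same marker count and thoracic/abdominal partition, and
#' all downstream computations accept any template that follows the
#' row-by-column naming scheme.
#'
#' Coordinates are in millimetres: +x subject's left, +y ventral, +z cranial,
#' torso base centred at the origin.
#'
#' @param n_rows Number of circumferential marker rows (default 8).
#' @param n_cols Markers per row (default 11; `n_rows * n_cols + 1 = 89`).
#' @param torso_dims Numeric length-3: overall width (x), depth (y) and
#'   height (z) of the torso in mm.
#' @return A tibble with columns `marker_id`, `region` (`"thoracic"` or
#'   `"abdominal"`), `row`, `col`, `x`, `y`, `z`, carrying a `layout`
#'   attribute used by [default_topology()].
#' @examples
#' tmpl <- cw_template()
#' nrow(tmpl) # 89
#' @export
cw_template <- function(n_rows = 8, n_cols = 11,
                        torso_dims = c(width = 300, depth = 220, height = 500)) {
  if (length(torso_dims) != 3 || any(!is.finite(torso_dims)) || any(torso_dims <= 0)) {
    stop_invalid("`torso_dims` must be three positive finite dimensions (width, depth, height).")
  }
  if (n_rows < 2 || n_cols < 3) {
    stop_invalid("Template needs at least 2 rows and 3 markers per row.")
  }
  a <- torso_dims[[1]] / 2 # mediolateral semi-axis
  b <- torso_dims[[2]] / 2 # dorsoventral semi-axis
  h <- torso_dims[[3]]

  # Gentle girth profile, shoulders to pelvis (row 1 = most cranial).
  profile <- stats::approx(seq(0, 1, length.out = 8),
                           c(0.84, 0.96, 1.00, 1.00, 0.97, 0.94, 0.91, 0.86),
                           xout = seq(0, 1, length.out = n_rows))$y
  z_rows <- h * (1 - (seq_len(n_rows) - 0.5) / n_rows)
  theta <- 2 * pi * (seq_len(n_cols) - 1) / n_cols # 0 = ventral midline

  grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  grid <- mutate(grid,
    marker_id = sprintf("R%dC%02d", .data$row, .data$col),
    region = ifelse(.data$row <= n_rows / 2, "thoracic", "abdominal"),
    x = a * profile[.data$row] * sin(theta[.data$col]),
    y = b * profile[.data$row] * cos(theta[.data$col]),
    z = z_rows[.data$row]
  )
  pole <- tibble(row = 0L, col = 0L, marker_id = "POLE", region = "thoracic",
                 x = 0, y = 0, z = h * 1.05)
  out <- bind_rows(select(grid, "marker_id", "region", "row", "col", "x", "y", "z"),
                   select(pole, "marker_id", "region", "row", "col", "x", "y", "z"))
  attr(out, "layout") <- list(n_rows = n_rows, n_cols = n_cols, torso_dims = unname(torso_dims))
  out
}

#' Convert a single-configuration tibble to a k x 3 coordinate matrix
#'
#' @param config A tibble with columns `marker_id`, `x`, `y`, `z` (one row per
#'   marker), or a numeric k x 3 matrix (returned as-is).
#' @param marker_ids Optional ordering to enforce; defaults to file order.
#' @return k x 3 numeric matrix with marker ids as row names.
#' @export
config_matrix <- function(config, marker_ids = NULL) {
  if (is.matrix(config)) {
    if (ncol(config) != 3) stop_invalid("Configuration matrix must have 3 columns.")
    return(config)
  }
  needed <- c("marker_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(config))
  if (length(missing_cols)) {
    stop_invalid(paste0("Configuration lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(config$marker_id)) {
    stop_invalid("Configuration has duplicated marker ids; expected one row per marker.")
  }
  if (!is.null(marker_ids)) {
    idx <- match(marker_ids, config$marker_id)
    if (anyNA(idx)) stop_invalid("Configuration is missing markers required by the template ordering.")
    config <- config[idx, ]
  }
  m <- as.matrix(config[, c("x", "y", "z")])
  rownames(m) <- config$marker_id
  m
}

as_config_tibble <- function(mat, meta = list()) {
  n <- nrow(mat)
  cols <- c(lapply(meta, rep, length.out = n),
            list(marker_id = rownames(mat) %||% sprintf("L%03d", seq_len(n)),
                 x = unname(mat[, 1]), y = unname(mat[, 2]), z = unname(mat[, 3])))
  tibble::new_tibble(cols, nrow = n)
}
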