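#' Read marker trajectories from a long-CSV file
#'
#' The canonical interchange dialect is "long-csv": columns `frame`,
#' `time_s`, `marker_id`, `x_mm`, `y_mm`, `z_mm`, one row per marker per
#' frame, empty coordinate cells marking missing markers (zeros are valid
#' coordinates, so they are never used as sentinels). Metadata
#' (`subject_id`, `condition`, `posture`, `sampling_rate_hz`) is carried in
#' `# key=value` comment lines at the top of the file.
#'
#' A `"c3d"` dialect is reserved for binary motion-capture files but no C3D
#' reader ships with this package; supply data converted to long-csv instead.
#'
#' @param path File path.
#' @param dialect `"long-csv"` (default) or `"c3d"`.
#' @return A `trajectory_set`.
#' @export
read_trajectories <- function(path, dialect = "long-csv") {
  if (identical(dialect, "c3d")) {
    stop_invalid("No C3D reader is available; convert to the long-csv dialect first.")
  }
  if (!identical(dialect, "long-csv")) {
    stop_invalid(sprintf("Unknown trajectory dialect '%s'.", dialect))
  }
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  meta <- read_meta_comments(path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  needed <- c("frame", "time_s", "marker_id", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop_invalid(paste0("Trajectory file lacks required column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "respmorph_format")
  }
  frames <- sort(unique(df$frame))
  markers <- unique(df$marker_id[df$frame == frames[1]])
  counts <- table(df$frame)
  if (length(unique(counts)) != 1) {
    stop_invalid("Inconsistent marker count across frames.", class = "respmorph_format")
  }
  nf <- length(frames); k <- length(markers)
  df <- arrange(df, .data$frame, factor(.data$marker_id, levels = markers))
  coords <- array(NA_real_, c(nf, k, 3))
  coords[, , 1] <- matrix(df$x_mm, nf, k, byrow = TRUE)
  coords[, , 2] <- matrix(df$y_mm, nf, k, byrow = TRUE)
  coords[, , 3] <- matrix(df$z_mm, nf, k, byrow = TRUE)
  mask <- is.na(coords[, , 1, drop = FALSE]) | is.na(coords[, , 2, drop = FALSE]) |
    is.na(coords[, , 3, drop = FALSE])
  mask <- matrix(mask, nf, k)
  for (d in 1:3) coords[, , d][mask] <- NA_real_
  time_s <- df$time_s[seq(1, nrow(df), by = k)]
  fs <- as.numeric(meta$sampling_rate_hz %||%
                     (1 / stats::median(diff(time_s))))
  traj <- new_trajectory_set(meta$subject_id %||% "unknown",
                             meta$condition %||% "QB",
                             meta$posture %||% "SIT",
                             fs, markers, coords, mask, time_s)
  inform(sprintf("Read %d frames x %d markers from %s (%.2f%% missing).",
                 nf, k, basename(path), 100 * mean(mask)))
  traj
}

read_meta_comments <- function(path) {
  lines <- character(0)
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, 1)
    if (!length(l) || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv)]
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) trimws(p[2])),
                  vapply(parts, function(p) trimws(p[1]), ""))
}

#' Write marker trajectories to a long-CSV file
#'
#' @param traj A `trajectory_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname read_trajectories
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  nf <- dim(traj$coords)[1]; k <- length(traj$marker_ids)
  df <- tibble(frame = rep(seq_len(nf), each = k),
               time_s = rep(traj$time_s, each = k),
               marker_id = rep(traj$marker_ids, nf),
               x_mm = as.vector(t(traj$coords[, , 1])),
               y_mm = as.vector(t(traj$coords[, , 2])),
               z_mm = as.vector(t(traj$coords[, , 3])))
  header <- sprintf("# %s=%s", c("subject_id", "condition", "posture", "sampling_rate_hz"),
                    c(traj$subject_id, traj$condition, traj$posture,
                      format(traj$sampling_rate_hz, digits = 15)))
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, na = "", progress = FALSE)
  inform(sprintf("Wrote %d records (%.2f%% missing) to %s.",
                 nrow(df), 100 * mean(traj$missing), basename(path)))
  invisible(path)
}

#' Write / read landmark configuration sets as wide CSV
#'
#' One row per configuration: id columns (`subject_id`, `posture`,
#' `condition`, `instant`, `cycle`) followed by `<marker>_x`, `<marker>_y`,
#' `<marker>_z` for every marker, in template order. The round trip is
#' lossless for finite coordinates; missing markers are empty cells.
#'
#' @param configs Tidy configurations tibble (one row per marker per
#'   configuration).
#' @param path File path.
#' @return `write_configurations()`: `path`, invisibly.
#'   `read_configurations()`: tidy configurations tibble.
#' @export
write_configurations <- function(configs, path) {
  if ((is.data.frame(configs) && nrow(configs) == 0) ||
      (is.list(configs) && !is.data.frame(configs) && !length(configs))) {
    hdr <- if (is.data.frame(configs)) intersect(id_cols, names(configs)) else id_cols
    writeLines(paste(hdr, collapse = ","), path)
    return(invisible(path))
  }
  parts <- configs_to_list(configs)
  wide <- parts$info
  n <- length(parts$mats)
  flat <- t(vapply(parts$mats, function(m) as.vector(t(m)), numeric(3 * length(parts$marker_ids))))
  if (n == 1) flat <- matrix(flat, 1)
  colnames(flat) <- paste(rep(parts$marker_ids, each = 3), c("x", "y", "z"), sep = "_")
  out <- bind_cols(wide, as_tibble(flat))
  readr::write_csv(out, path, na = "", progress = FALSE)
  inform(sprintf("Wrote %d configurations to %s.", n, basename(path)))
  invisible(path)
}

#' @rdname write_configurations
#' @export
read_configurations <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  coord_cols <- grep("_[xyz]$", names(df), value = TRUE)
  ids <- setdiff(names(df), coord_cols)
  markers <- unique(sub("_[xyz]$", "", coord_cols))
  long <- list()
  for (i in seq_len(nrow(df))) {
    m <- matrix(unlist(df[i, paste(rep(markers, each = 3), c("x", "y", "z"), sep = "_")]),
                ncol = 3, byrow = TRUE)
    rownames(m) <- markers
    long[[i]] <- as_config_tibble(m, as.list(df[i, ids]))
  }
  bind_rows(long)
}
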