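#' Closed triangulation of the chest-wall marker template
#'
#' Builds the default watertight triangulation over the row-by-column marker
#' grid: quad bands between adjacent rows split into triangles, a fan from the
#' cranial pole to the top row, and an ear-fan closing the caudal ring.
#' Every edge is shared by exactly two triangles and faces are consistently
#' oriented with outward normals, so the enclosed volume of any configuration
#' can be computed by the divergence theorem.
#'
#' The triangulation is a documented stand-in for the proprietary geometric
#' models used by commercial systems; any alternative topology can be supplied
#' as a JSON triangle list via [read_topology()].
#'
#' @param template A template tibble from [cw_template()] (carries the grid
#'   layout attribute).
#' @return An object of class `mesh_topology`: list with `triangles`
#'   (F x 3 integer matrix of 1-based marker indices), `marker_ids`.
#' @export
default_topology <- function(template) {
  layout <- attr(template, "layout")
  if (is.null(layout)) {
    stop_invalid("Template lacks the grid layout attribute; use cw_template() or read_topology().")
  }
  R <- layout$n_rows; C <- layout$n_cols
  if (nrow(template) != R * C + 1 || !"POLE" %in% template$marker_id) {
    stop_invalid("Template marker set does not match its declared row/column layout.")
  }
  idx <- function(r, j) (r - 1L) * C + j # row-major grid, pole last
  pole <- R * C + 1L

  # side bands; caps wound to oppose the band edges so each undirected edge
  # is traversed once in each direction
  band <- vector("list", R - 1L)
  for (r in seq_len(R - 1L)) {
    j <- seq_len(C); j2 <- j %% C + 1L
    band[[r]] <- rbind(cbind(idx(r, j), idx(r + 1L, j), idx(r + 1L, j2)),
                       cbind(idx(r, j), idx(r + 1L, j2), idx(r, j2)))
  }
  j <- seq_len(C); j2 <- j %% C + 1L
  cap_top <- cbind(rep(pole, C), idx(1L, j), idx(1L, j2))
  ear <- 2:(C - 1L)
  cap_bottom <- cbind(rep(idx(R, 1L), C - 2L), idx(R, ear + 1L), idx(R, ear))
  triangles <- rbind(do.call(rbind, band), cap_top, cap_bottom)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL

  topo <- structure(list(triangles = triangles, marker_ids = template$marker_id),
                    class = "mesh_topology")
  if (enclosed_volume(template, topo) < 0) { # enforce outward orientation
    topo$triangles <- triangles[, c(1L, 3L, 2L)]
  }
  validate_topology(topo)
  topo
}

#' Validate a mesh topology
#'
#' Checks closedness (every edge in exactly two triangles, used once in each
#' direction) and the spherical Euler characteristic V - E + F = 2.
#'
#' @param topo A `mesh_topology`.
#' @return `topo`, invisibly; errors if invalid.
#' @export
validate_topology <- function(topo) {
  tri <- topo$triangles
  v <- length(topo$marker_ids)
  if (any(tri < 1L) || any(tri > v)) stop_invalid("Triangle indices out of range.")
  dir_edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(dir_edges[, 1], dir_edges[, 2])
  if (anyDuplicated(key)) stop_invalid("Topology is not consistently oriented (repeated directed edge).")
  ukey <- paste(pmin(dir_edges[, 1], dir_edges[, 2]), pmax(dir_edges[, 1], dir_edges[, 2]))
  cnt <- table(ukey)
  if (any(cnt != 2)) stop_invalid("Topology is not closed: some edges are not shared by exactly 2 triangles.")
  e <- length(cnt); f <- nrow(tri)
  if (v - e + f != 2L) {
    stop_invalid(sprintf("Euler characteristic V - E + F = %d, expected 2.", v - e + f))
  }
  invisible(topo)
}

#' @export
print.mesh_topology <- function(x, ...) {
  cat(sprintf("<mesh_topology> %d markers, %d triangles (closed)\n",
              length(x$marker_ids), nrow(x$triangles)))
  invisible(x)
}

#' Read / write a topology as a JSON triangle list
#'
#' The on-disk format is a JSON object with `marker_ids` (ordered names) and
#' `triangles` (array of 0-based index triples), so externally supplied
#' geometric models can be dropped in.
#'
#' @param path File path.
#' @return For `read_topology`, a validated `mesh_topology`.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tri <- matrix(as.integer(obj$triangles), ncol = 3) + 1L
  topo <- structure(list(triangles = tri, marker_ids = obj$marker_ids),
                    class = "mesh_topology")
  validate_topology(topo)
  topo
}

#' @param topo A `mesh_topology`.
#' @rdname read_topology
#' @export
write_topology <- function(topo, path) {
  jsonlite::write_json(list(marker_ids = topo$marker_ids,
                            triangles = topo$triangles - 1L),
                       path, auto_unbox = TRUE)
  invisible(path)
}
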