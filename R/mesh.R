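#' Triangulated surface mesh
#'
#' Minimal vertex/face container used for thin-plate-spline warping and for
#' writing warped breathing shapes to ASCII PLY/OBJ files.
#'
#' @param vertices V x 3 numeric matrix, mm.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop_invalid("Vertices must be V x 3.")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_invalid("Face indices out of vertex range.")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' Build the template torso mesh
#'
#' The marker template together with its closed triangulation, as a
#' `surface_mesh` suitable for [warp_mesh()].
#'
#' @param template Template tibble from [cw_template()].
#' @param topo Optional `mesh_topology`; default [default_topology()].
#' @return A `surface_mesh` whose vertices are the template landmarks.
#' @export
template_mesh <- function(template = cw_template(), topo = default_topology(template)) {
  surface_mesh(config_matrix(template, topo$marker_ids), topo$triangles)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read and write ASCII PLY / OBJ meshes
#'
#' Minimal readers/writers for the two interchange formats used by the
#' warping workflow. Only triangular faces and plain `x y z` vertices are
#' supported.
#'
#' @param mesh A `surface_mesh`.
#' @param path File path; format chosen by extension for the `write_mesh()` /
#'   `read_mesh()` wrappers.
#' @return Readers return a `surface_mesh`; writers return `path` invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vdat <- utils::read.table(text = lines[end + seq_len(nv)])
  fdat <- utils::read.table(text = lines[end + nv + seq_len(nf)])
  surface_mesh(as.matrix(vdat[, 1:3]), as.matrix(fdat[, 2:4]) + 1L)
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  vdat <- utils::read.table(text = sub("^v ", "", vl))
  f <- do.call(rbind, lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(p) {
    as.integer(sub("/.*$", "", p))
  }))
  surface_mesh(as.matrix(vdat[, 1:3]), f)
}

#' @rdname write_ply
#' @export
write_mesh <- function(mesh, path) {
  switch(tolower(tools::file_ext(path)),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop_invalid("Unsupported mesh format; use .ply or .obj."))
}

#' @rdname write_ply
#' @export
read_mesh <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ply = read_ply(path),
         obj = read_obj(path),
         stop_invalid("Unsupported mesh format; use .ply or .obj."))
}
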