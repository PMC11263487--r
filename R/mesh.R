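#' Construct a tooth mesh
#'
#' A `tooth_mesh` is a closed triangle surface for a single tooth:
#' a numeric vertex matrix (mm) and an integer face matrix of 1-based
#' vertex indices.  Construction validates the invariants every other
#' operation in the package relies on.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param name character label for the tooth.
#' @param label positive integer segment label.
#' @return an object of class `tooth_mesh` with elements `name`, `label`,
#'   `vertices` and `faces`.
#' @examples
#' m <- make_cone(height = 4, radius = 1, segments = 32)
#' m
#' @export
tooth_mesh <- function(vertices, faces, name = "tooth", label = 1L) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  obj <- structure(
    list(name = as.character(name)[1], label = as.integer(label)[1],
         vertices = vertices, faces = faces),
    class = "tooth_mesh")
  validate_tooth_mesh(obj)
}

#' Validate a tooth mesh
#'
#' Checks the `tooth_mesh` invariants: at least 4 vertices and 4 faces,
#' all coordinates finite, every face index valid, positive label.
#'
#' @param mesh object to validate.
#' @return the mesh, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_tooth_mesh <- function(mesh) {
  if (!inherits(mesh, "tooth_mesh")) stop("not a tooth_mesh object")
  v <- mesh$vertices; f <- mesh$faces
  if (ncol(v) != 3) stop("vertices must have 3 columns")
  if (ncol(f) != 3) stop("faces must have 3 columns (triangles only)")
  if (nrow(v) < 4 || nrow(f) < 4)
    stop(sprintf("degenerate mesh '%s': need >= 4 vertices and >= 4 faces, got %d/%d",
                 mesh$name, nrow(v), nrow(f)))
  if (!all(is.finite(v))) stop(sprintf("mesh '%s' has non-finite coordinates", mesh$name))
  if (anyNA(f) || min(f) < 1 || max(f) > nrow(v))
    stop(sprintf("mesh '%s' has face indices outside 1..%d", mesh$name, nrow(v)))
  if (is.na(mesh$label) || mesh$label < 1) stop("mesh label must be a positive integer")
  mesh
}

#' @export
print.tooth_mesh <- function(x, ...) {
  cat(sprintf("tooth_mesh '%s' (label %d): %d vertices, %d faces\n",
              x$name, x$label, nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# face areas (vector) and face centroids (matrix) for a tooth_mesh
face_areas_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cross_mm(b - a, c_ - a)
  list(areas = 0.5 * sqrt(rowSums(cr * cr)), centroids = (a + b + c_) / 3)
}
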