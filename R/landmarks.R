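#' Construct a jaw landmark set
#'
#' A `landmark_set` is a named list of 3D points (mm) describing the jaw
#' lever frame: `jaw_joint` and `jaw_tip` are required and must be
#' distinct; up to three muscle insertion sites `insertion_1..3` and
#' matching (optional) `origin_1..3` points may be present.  An origin
#' is only allowed when its insertion is present.  All points are in a
#' single right-handed frame; FCSV files are converted from their
#' declared coordinate system (LPS/RAS) on read, see [read_landmarks()].
#'
#' @param points named list of numeric length-3 vectors.
#' @return an object of class `landmark_set`.
#' @examples
#' landmark_set(list(jaw_joint = c(0, 0, 0), jaw_tip = c(10, 0, 0)))
#' @export
landmark_set <- function(points) {
  if (!is.list(points) || is.null(names(points)))
    stop("landmarks must be a named list of 3D points")
  allowed <- c("jaw_joint", "jaw_tip",
               paste0("insertion_", 1:3), paste0("origin_", 1:3))
  bad <- setdiff(names(points), allowed)
  if (length(bad))
    stop("unknown landmark label(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(c("jaw_joint", "jaw_tip"), names(points))
  if (length(missing))
    stop("missing required landmark(s): ", paste(missing, collapse = ", "))
  points <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || !all(is.finite(p)))
      stop("each landmark must be a finite 3D point")
    p
  })
  if (vnorm(points$jaw_joint - points$jaw_tip) < .Machine$double.eps)
    stop("jaw_joint and jaw_tip must be distinct points")
  for (k in 1:3) {
    if (!is.null(points[[paste0("origin_", k)]]) &&
        is.null(points[[paste0("insertion_", k)]]))
      stop(sprintf("origin_%d present without insertion_%d", k, k))
  }
  structure(points[order(match(names(points), allowed))], class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set with %d points:\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-12s (%.4g, %.4g, %.4g)\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

# number of muscles implied by a landmark set
n_insertions <- function(lm) sum(paste0("insertion_", 1:3) %in% names(lm))
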