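#' Principal axis and centroid of a tooth mesh
#'
#' The centroid is the area-weighted mean of the face centroids.  The
#' axis is the eigenvector of the area-weighted covariance of the face
#' centroids that captures the tooth's elongation.  Conical and
#' near-conical teeth are surfaces of revolution, so their covariance
#' has one rotationally distinct eigenvalue (the symmetry axis) and two
#' nearly equal ones (the base plane); the distinct eigenvector is the
#' anatomical long axis whether the tooth is slender (distinct value
#' largest) or squat (distinct value smallest).  The rule used is:
#' with eigenvalues l1 >= l2 >= l3, return e1 if (l1 - l2) >= (l2 - l3),
#' else e3.  The sign of the axis is unconstrained here; orientation is
#' resolved by [detect_tip_base()].
#'
#' When all three eigenvalues coincide within 1e-9 (relative), the mesh
#' is isotropic (e.g. a sphere); a warning is raised and a deterministic
#' tie-break is applied: the eigenvector with the largest absolute dot
#' product with `vertical` if supplied, else the one with the largest
#' absolute x component (ties broken on y).
#'
#' @param mesh a [tooth_mesh()].
#' @param vertical optional 3-vector used only to break isotropic ties
#'   (e.g. the normal of the jaw plane).
#' @return a list with `centroid` (3-vector, mm), `axis` (unit
#'   3-vector) and `eigenvalues` (decreasing).
#' @export
principal_axis <- function(mesh, vertical = NULL) {
  validate_tooth_mesh(mesh)
  fac <- face_areas_centroids(mesh)
  w <- fac$areas / sum(fac$areas)
  centroid <- colSums(fac$centroids * w)
  X <- sweep(fac$centroids, 2, centroid)
  C <- crossprod(X, X * w)
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  tol <- 1e-9 * max(ev[1], 1)
  if (ev[1] - ev[3] < tol) {
    warning(sprintf("mesh '%s' is isotropic; principal axis is ambiguous, using tie-break",
                    mesh$name))
    if (!is.null(vertical)) {
      k <- which.max(abs(as.numeric(t(eg$vectors) %*% unit(as.numeric(vertical)))))
    } else {
      ax <- abs(eg$vectors)
      k <- order(-ax[1, ], -ax[2, ], -ax[3, ])[1]
    }
    axis <- eg$vectors[, k]
  } else if ((ev[1] - ev[2]) >= (ev[2] - ev[3])) {
    axis <- eg$vectors[, 1]
  } else {
    axis <- eg$vectors[, 3]
  }
  # deterministic sign: largest-magnitude component positive
  k <- which.max(abs(axis))
  if (axis[k] < 0) axis <- -axis
  list(centroid = as.numeric(centroid), axis = as.numeric(axis),
       eigenvalues = ev)
}

# first intersection of the ray origin + t*dir (t > 0) with the mesh
# (Moller-Trumbore, vectorized over faces); NULL if no hit
ray_mesh_first_hit <- function(origin, dir, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - A
  e2 <- v[f[, 3], , drop = FALSE] - A
  pvec <- cross_mv(e2, dir)        # dir x e2 = -(e2 x dir)
  pvec <- -pvec
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- matrix(origin, nrow(A), 3, byrow = TRUE) - A
  u <- rowSums(tvec * pvec) / det
  qvec <- cross_mm(tvec, e1)
  vpar <- as.numeric(qvec %*% dir) / det
  tt <- rowSums(e2 * qvec) / det
  eps <- 1e-9
  hit <- ok & u >= -eps & vpar >= -eps & (u + vpar) <= 1 + eps & tt > 1e-9
  if (!any(hit)) return(NULL)
  origin + min(tt[hit]) * dir
}

# closest point on the mesh surface to p (exact point-triangle distance,
# Ericson's region algorithm vectorized over faces)
closest_point_on_mesh <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A
  ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  setres <- function(mask, value) {
    m <- mask & !done
    res[m, ] <<- value[m, , drop = FALSE]
    done <<- done | m
  }
  setres(d1 <= 0 & d2 <= 0, A)                                   # vertex A
  setres(d3 >= 0 & d4 <= d3, B)                                  # vertex B
  setres(d6 >= 0 & d5 <= d6, C)                                  # vertex C
  t_ab <- d1 / (d1 - d3); t_ab[!is.finite(t_ab)] <- 0
  setres(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * t_ab)             # edge AB
  t_ac <- d2 / (d2 - d6); t_ac[!is.finite(t_ac)] <- 0
  setres(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * t_ac)             # edge AC
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6)); t_bc[!is.finite(t_bc)] <- 0
  setres(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * t_bc)  # edge BC
  denom <- va + vb + vc
  denom[denom == 0] <- 1
  setres(rep(TRUE, n), A + ab * (vb / denom) + ac * (vc / denom)) # interior
  d2all <- rowSums((res - P)^2)
  res[which.min(d2all), ]
}

#' Detect the tip and base of a tooth
#'
#' Places two candidate landmarks at the extremes of the vertex
#' projections on the tooth's principal axis.  The candidate nearer (in
#' Euclidean distance) to the reference point on the jaw-joint to
#' jaw-tip segment — the orthogonal projection of the tooth centroid
#' onto that segment, clamped to it — is taken as the base side.  The
#' base is then the first intersection of a ray cast along the axis
#' from just outside the tooth toward its centroid (the center of the
#' base); if the ray misses (pathological concavity), the extreme
#' vertex is used with a warning.  The tip candidate is raised beyond
#' the extreme projection by `raise_frac` of the axial extent and
#' snapped to the nearest point on the mesh surface.
#'
#' @param mesh a [tooth_mesh()].
#' @param jaw_joint,jaw_tip 3D points (mm) defining the jaw line.
#' @param raise_frac fraction of the axial extent by which the tip
#'   candidate is raised before snapping (default 0.1).
#' @param vertical optional tie-break vector passed to [principal_axis()].
#' @return list with `tip`, `base` (3D points, mm), `axis` (unit vector
#'   oriented base to tip) and `centroid`.
#' @export
detect_tip_base <- function(mesh, jaw_joint, jaw_tip, raise_frac = 0.1,
                            vertical = NULL) {
  jaw_joint <- as.numeric(jaw_joint); jaw_tip <- as.numeric(jaw_tip)
  pa <- principal_axis(mesh, vertical = vertical)
  tproj <- as.numeric((mesh$vertices - matrix(pa$centroid, nrow(mesh$vertices), 3,
                                              byrow = TRUE)) %*% pa$axis)
  tmin <- min(tproj); tmax <- max(tproj)
  extent <- tmax - tmin
  cand_lo <- pa$centroid + tmin * pa$axis
  cand_hi <- pa$centroid + tmax * pa$axis

  # reference point: projection of the centroid onto the jaw segment, clamped
  seg <- jaw_tip - jaw_joint
  s <- sum((pa$centroid - jaw_joint) * seg) / sum(seg * seg)
  ref <- jaw_joint + min(max(s, 0), 1) * seg

  if (vnorm(cand_lo - ref) <= vnorm(cand_hi - ref)) {
    base_cand <- cand_lo; tip_cand <- cand_hi
  } else {
    base_cand <- cand_hi; tip_cand <- cand_lo
  }
  up <- unit(tip_cand - base_cand)  # base -> tip direction along the axis

  # base: slide along the axis from outside until the surface is hit
  ray_origin <- base_cand - raise_frac * extent * up
  base <- ray_mesh_first_hit(ray_origin, up, mesh)
  if (is.null(base)) {
    warning(sprintf("base ray missed mesh '%s'; falling back to extreme vertex",
                    mesh$name))
    base <- mesh$vertices[which.min(as.numeric(mesh$vertices %*% up)), ]
  }
  # tip: raise above the tooth, then snap to the nearest surface point
  raised <- tip_cand + raise_frac * extent * up
  tip <- closest_point_on_mesh(raised, mesh)
  list(tip = as.numeric(tip), base = as.numeric(base),
       axis = up, centroid = pa$centroid)
}

#' Exact surface area of a triangle mesh
#'
#' Sum over faces of half the norm of the edge cross product.
#'
#' @param mesh a [tooth_mesh()].
#' @return surface area in mm^2 (strictly positive).
#' @export
surface_area <- function(mesh) {
  validate_tooth_mesh(mesh)
  a <- sum(face_areas_centroids(mesh)$areas)
  if (a <= 0) stop(sprintf("mesh '%s' has zero surface area", mesh$name))
  a
}

#' Tooth height and width
#'
#' Height is the straight-line tip-base distance.  Width is the maximum
#' caliper extent of the vertices falling in the basal `basal_frac`
#' axial slab, projected onto the plane normal to the tip-base
#' direction; for a cone this equals the basal diameter 2r.
#'
#' @param mesh a [tooth_mesh()].
#' @param tip,base 3D points from [detect_tip_base()] (tip != base).
#' @param basal_frac axial fraction of the tooth defining the basal slab
#'   used for the width measurement (default 0.1).
#' @return list with `height` and `width` in mm.
#' @export
tooth_height_width <- function(mesh, tip, base, basal_frac = 0.1) {
  tip <- as.numeric(tip); base <- as.numeric(base)
  height <- vnorm(tip - base)
  if (height < .Machine$double.eps) stop("tip and base coincide")
  u <- (tip - base) / height
  tproj <- as.numeric((mesh$vertices - matrix(base, nrow(mesh$vertices), 3,
                                              byrow = TRUE)) %*% u)
  lo <- min(tproj)
  slab <- tproj <= lo + basal_frac * (max(tproj) - lo)
  pts <- mesh$vertices[slab, , drop = FALSE]
  if (nrow(pts) < 2) pts <- mesh$vertices
  # orthonormal basis of the plane normal to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unit(ref - sum(ref * u) * u)
  b2 <- c(u[2] * b1[3] - u[3] * b1[2],
          u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  xy <- cbind(as.numeric(pts %*% b1), as.numeric(pts %*% b2))
  width <- max_caliper(xy)
  if (width <= 0) width <- max_caliper(cbind(as.numeric(mesh$vertices %*% b1),
                                             as.numeric(mesh$vertices %*% b2)))
  list(height = height, width = width)
}

# maximum pairwise distance among 2D points (via convex hull)
max_caliper <- function(xy) {
  if (nrow(xy) < 2) return(0)
  h <- unique(xy[grDevices::chull(xy), , drop = FALSE])
  if (nrow(h) < 2) return(0)
  max(stats::dist(h))
}

#' Full geometric description of one tooth
#'
#' Convenience wrapper running [principal_axis()], [detect_tip_base()],
#' [tooth_height_width()] and [surface_area()] on one mesh.
#'
#' @inheritParams detect_tip_base
#' @inheritParams tooth_height_width
#' @return list with `tooth`, `tip`, `base`, `axis`, `height`, `width`,
#'   `aspect_ratio` (= height / width) and `surface_area`.
#' @export
tooth_geometry <- function(mesh, jaw_joint, jaw_tip, basal_frac = 0.1,
                           raise_frac = 0.1, vertical = NULL) {
  tb <- detect_tip_base(mesh, jaw_joint, jaw_tip, raise_frac = raise_frac,
                        vertical = vertical)
  hw <- tooth_height_width(mesh, tb$tip, tb$base, basal_frac = basal_frac)
  list(tooth = mesh$name, tip = tb$tip, base = tb$base, axis = tb$axis,
       height = hw$height, width = hw$width,
       aspect_ratio = hw$height / hw$width,
       surface_area = surface_area(mesh))
}

#' Swap tip and base landmarks for selected teeth
#'
#' Mirrors the manual override in interactive use: when automatic
#' detection orients a tooth the wrong way, flipping exchanges its tip
#' and base exactly (an involution).  Height and width are unchanged;
#' downstream mechanics must be recomputed.
#'
#' @param geometries a named list of records from [tooth_geometry()] (or
#'   any list elements carrying `tooth`, `tip`, `base`, `axis`).
#' @param selection `"all"` or a character vector of tooth names.
#' @return the list with tip/base (and axis sign) swapped for the
#'   selected teeth.
#' @export
flip_tip_base <- function(geometries, selection = "all") {
  nms <- vapply(geometries, function(g) g$tooth, character(1))
  if (identical(selection, "all")) {
    sel <- nms
  } else {
    unknown <- setdiff(selection, nms)
    if (length(unknown))
      stop("unknown tooth name(s): ", paste(unknown, collapse = ", "))
    sel <- selection
  }
  for (i in which(nms %in% sel)) {
    g <- geometries[[i]]
    tmp <- g$tip; g$tip <- g$base; g$base <- tmp
    if (!is.null(g$axis)) g$axis <- -g$axis
    geometries[[i]] <- g
  }
  geometries
}
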