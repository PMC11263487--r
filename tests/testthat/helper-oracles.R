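# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately coded apart from the package internals
# so the tests are not circular.

# exhaustive 2-medoids over all medoid pairs (oracle for medoids2_1d)
brute_medoids2 <- function(x) {
  n <- length(x)
  best <- Inf; bm <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(abs(x - x[i]), abs(x - x[j])))
    if (cost < best - 1e-12) { best <- cost; bm <- sort(c(x[i], x[j])) }
  }
  bm
}

medoid_cost <- function(x, medoids) {
  sum(pmin(abs(x - medoids[1]), abs(x - medoids[2])))
}

# closed-form cone area, written independently of the package
cone_area_oracle <- function(h, r) pi * r * sqrt(r^2 + h^2) + pi * r^2

unitv <- function(v) v / sqrt(sum(v^2))

# rotation matrix about a unit axis by angle (Rodrigues)
rot_axis_angle <- function(axis, angle) {
  axis <- unitv(axis)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

apply_rigid <- function(mesh, R, t = c(0, 0, 0)) {
  tooth_mesh(mesh$vertices %*% t(R) + matrix(t, nrow(mesh$vertices), 3, byrow = TRUE),
             mesh$faces, name = mesh$name, label = mesh$label)
}

# regular icosahedron (isotropic second moment) for the tie-break test
make_icosahedron <- function(scale = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)) * scale
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  tooth_mesh(v, f, name = "icosahedron")
}

# independent minimal NRRD writer (raw little-endian int32) for fixtures
write_nrrd_fixture <- function(vol, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               "type: int32",
               "dimension: 3",
               sprintf("sizes: %d %d %d", dim(vol)[1], dim(vol)[2], dim(vol)[3]),
               "encoding: raw",
               "endian: little",
               sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                       spacing[1], spacing[2], spacing[3]),
               sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3]),
               ""), con)
  writeBin(as.integer(vol), con, size = 4L, endian = "little")
  invisible(path)
}

# max over rows of the distance to the nearest row of `ref` (order-free
# vertex-set comparison for formats that renumber vertices)
max_nn_dist <- function(verts, ref) {
  max(apply(verts, 1, function(p) sqrt(min(colSums((t(ref) - p)^2)))))
}

# a randomly posed cone plus a jaw line placed on its base side, the way
# jaw landmarks sit relative to real teeth
random_posed_cone <- function(h, r = 1, segments = 64) {
  axis <- unitv(rnorm(3))
  base <- rnorm(3, sd = 5)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  d1 <- unitv(ref - sum(ref * axis) * axis)
  list(mesh = make_cone(h, r, segments, base_center = base, axis = axis),
       apex = base + h * axis, base = base,
       jaw_joint = base - 10 * d1 + rnorm(3, sd = 0.5),
       jaw_tip = base + 10 * d1 + rnorm(3, sd = 0.5))
}
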