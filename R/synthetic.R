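#' Generate a cone tooth mesh
#'
#' Closed right cone: a lateral triangle fan from the apex plus a base
#' disk fan, with the base ring duplicated between the two fans so the
#' mesh has exactly `2 * segments + 2` vertices and `2 * segments`
#' faces.  The apex vertex sits exactly at
#' `base_center + height * axis`.
#'
#' @param height cone height (mm, > 0).
#' @param radius base radius (mm, > 0).
#' @param segments number of segments around the circumference (>= 16;
#'   use an even count so the basal caliper width equals the diameter
#'   exactly).
#' @param base_center 3D point (mm) of the base disk center.
#' @param axis direction from base to apex (normalized internally).
#' @param name,label passed to [tooth_mesh()].
#' @return a [tooth_mesh()].
#' @export
make_cone <- function(height, radius, segments = 64L, base_center = c(0, 0, 0),
                      axis = c(0, 0, 1), name = "cone", label = 1L) {
  if (height <= 0 || radius <= 0) stop("height and radius must be positive")
  segments <- as.integer(segments)
  if (segments < 16L) stop("segments must be >= 16")
  axis <- unit(as.numeric(axis))
  base_center <- as.numeric(base_center)
  # orthonormal basis perpendicular to the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- unit(ref - sum(ref * axis) * axis)
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
          axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  th <- 2 * pi * (seq_len(segments) - 1L) / segments
  ring <- matrix(base_center, segments, 3, byrow = TRUE) +
    radius * (cos(th) %o% b1 + sin(th) %o% b2)
  apex <- base_center + height * axis
  verts <- rbind(ring,                  # 1..s : lateral ring
                 apex,                  # s+1  : apex
                 ring,                  # s+2..2s+1 : base ring (duplicated)
                 base_center)           # 2s+2 : base center
  s <- segments
  nxt <- c(2:s, 1L)
  lateral <- cbind(seq_len(s), nxt, rep(s + 1L, s))
  base <- cbind(rep(2L * s + 2L, s), s + 1L + nxt, s + 1L + seq_len(s))
  tooth_mesh(verts, rbind(lateral, base), name = name, label = label)
}

#' Closed-form surface area of a cone
#'
#' Lateral area plus base disk: `pi * r * sqrt(r^2 + h^2) + pi * r^2`.
#' Used as the analytic ground truth for generated cone teeth.
#'
#' @param height,radius cone dimensions (mm).
#' @return area in mm^2.
#' @export
cone_area <- function(height, radius) {
  pi * radius * sqrt(radius^2 + height^2) + pi * radius^2
}

#' Specify a synthetic cone-tooth jaw
#'
#' Defines a parametric jaw: the joint at the origin, the jaw tip at
#' `(jaw_length, 0, 0)`, teeth as upright cones (optional tilt in the
#' x-z plane) with base centers on the joint-tip line, and one or more
#' muscle insertion (and optional origin) points.  All defaults
#' describe a plausible small-vertebrate jaw: 10 teeth on a 20 mm jaw,
#' 2 mm tall and 0.5 mm radius crowns, the insertion on a coronoid-like
#' process at 15% of the jaw length.  Optional lognormal jitter of
#' heights/radii (coefficient of variation `height_cv`, `radius_cv`,
#' seeded) emulates natural size variation.
#'
#' @param n_teeth number of teeth (>= 1).
#' @param jaw_length jaw joint to jaw tip distance (mm).
#' @param positions base-center distances from the joint (mm), strictly
#'   increasing, within (0, jaw_length).
#' @param heights,radii per-tooth cone dimensions (mm), recycled.  The
#'   default radius is 0.5 mm, shrunk to 35% of the smallest inter-tooth
#'   spacing when teeth are dense so crowns never overlap.
#' @param tilts per-tooth axis tilt in degrees in the x-z plane
#'   (0 = upright, positive leans toward the jaw tip), recycled.
#' @param insertions list of 3D insertion points (1-3 muscles).
#' @param origins optional list of 3D origin points (same length).
#' @param segments cone mesh resolution (even, >= 16).
#' @param height_cv,radius_cv lognormal coefficients of variation for
#'   per-tooth size jitter (default 0 = deterministic sizes).
#' @param seed integer seed used for the size jitter.
#' @return an object of class `jaw_spec`.
#' @export
jaw_spec <- function(n_teeth = 10L, jaw_length = 20,
                     positions = NULL, heights = 2, radii = NULL, tilts = 0,
                     insertions = list(c(0.15 * jaw_length, 0, 0.1 * jaw_length)),
                     origins = NULL, segments = 64L,
                     height_cv = 0, radius_cv = 0, seed = NULL) {
  n_teeth <- as.integer(n_teeth)
  if (n_teeth < 1) stop("n_teeth must be >= 1")
  if (is.null(positions))
    positions <- seq(0.2 * jaw_length, 0.9 * jaw_length, length.out = n_teeth)
  if (length(positions) != n_teeth) stop("positions must have length n_teeth")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(positions <= 0) || any(positions >= jaw_length))
    stop("positions must lie strictly inside (0, jaw_length)")
  heights <- rep_len(as.numeric(heights), n_teeth)
  if (is.null(radii)) {
    # default crown radius: 0.5 mm, shrunk so adjacent teeth never touch
    gap <- if (n_teeth > 1) min(diff(positions)) else jaw_length
    radii <- min(0.5, 0.35 * gap)
  }
  radii <- rep_len(as.numeric(radii), n_teeth)
  tilts <- rep_len(as.numeric(tilts), n_teeth)
  if (any(heights <= 0) || any(radii <= 0)) stop("heights and radii must be positive")
  if (height_cv > 0 || radius_cv > 0) {
    jit <- with_local_seed(seed, list(
      h = rlnorm(n_teeth, -0.5 * log(1 + height_cv^2), sqrt(log(1 + height_cv^2))),
      r = rlnorm(n_teeth, -0.5 * log(1 + radius_cv^2), sqrt(log(1 + radius_cv^2)))))
    heights <- heights * jit$h
    radii <- radii * jit$r
  }
  if (n_teeth > 1 && any(diff(positions) < radii[-n_teeth] + radii[-1]))
    stop("teeth overlap: inter-tooth spacing smaller than the sum of adjacent radii")
  if (!is.list(insertions) || length(insertions) < 1 || length(insertions) > 3)
    stop("insertions must be a list of 1-3 points")
  if (!is.null(origins) && length(origins) != length(insertions))
    stop("origins must match insertions in length")
  structure(list(n_teeth = n_teeth, jaw_length = jaw_length,
                 positions = positions, heights = heights, radii = radii,
                 tilts = tilts, insertions = lapply(insertions, as.numeric),
                 origins = if (is.null(origins)) NULL else lapply(origins, as.numeric),
                 segments = as.integer(segments), seed = seed),
            class = "jaw_spec")
}

#' Build a synthetic jaw from a specification
#'
#' Generates the cone meshes and landmark set described by a
#' [jaw_spec()], together with a ground-truth trait table computed from
#' plain closed forms (cone area, Euclidean lever distances, the static
#' lever model under the default assumptions of 1 N input force and a
#' 90-degree insertion angle per muscle).  The ground truth is coded
#' here independently of the measurement pipeline so it can serve as an
#' oracle for it.
#'
#' @param spec a [jaw_spec()].
#' @return list with `meshes` (named list of [tooth_mesh()]),
#'   `landmarks` ([landmark_set()]), `ground_truth` (data.frame) and
#'   `spec`.
#' @export
make_jaw <- function(spec) {
  if (!inherits(spec, "jaw_spec")) stop("make_jaw() needs a jaw_spec")
  n <- spec$n_teeth
  joint <- c(0, 0, 0)
  jaw_tip <- c(spec$jaw_length, 0, 0)
  pts <- list(jaw_joint = joint, jaw_tip = jaw_tip)
  for (k in seq_along(spec$insertions)) {
    pts[[paste0("insertion_", k)]] <- spec$insertions[[k]]
    if (!is.null(spec$origins)) pts[[paste0("origin_", k)]] <- spec$origins[[k]]
  }
  landmarks <- landmark_set(pts)
  in_levers <- vapply(spec$insertions, function(p) sqrt(sum((p - joint)^2)), numeric(1))

  meshes <- list()
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    name <- sprintf("T%02d", i)
    tilt <- deg2rad(spec$tilts[i])
    axis <- c(sin(tilt), 0, cos(tilt))   # upright, optional lean toward the tip
    base <- c(spec$positions[i], 0, 0)
    meshes[[name]] <- make_cone(spec$heights[i], spec$radii[i],
                                segments = spec$segments,
                                base_center = base, axis = axis,
                                name = name, label = i)
    # --- analytic ground truth (independent closed forms) ---
    h <- spec$heights[i]; r <- spec$radii[i]
    tip <- base + h * axis
    out_lever <- sqrt(sum(tip^2))
    position <- spec$positions[i]
    sa <- pi * r * sqrt(r^2 + h^2) + pi * r^2
    ma <- in_levers / out_lever
    force <- sum(1 * sin(pi / 2) * ma)   # defaults: F_in = 1 N, angle = 90 deg
    gt[[i]] <- data.frame(
      tooth = name, label = i,
      jaw_length = spec$jaw_length, position = position, out_lever = out_lever,
      height = h, width = 2 * r, aspect_ratio = h / (2 * r), surface_area = sa,
      in_lever_1 = in_levers[1], mechanical_advantage_1 = ma[1],
      force = force, stress = force / sa,
      tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
      base_x = base[1], base_y = base[2], base_z = base[3],
      stringsAsFactors = FALSE)
  }
  list(meshes = meshes, landmarks = landmarks,
       ground_truth = do.call(rbind, gt), spec = spec)
}

#' Inject a stress outlier into a jaw specification
#'
#' Rescales one tooth's radius (height fixed) so that its modeled
#' stress under the default lever assumptions equals `stress_factor`
#' times the median stress of the unmodified jaw.  Because the force on
#' a tooth does not depend on its radius, solving
#' `cone_area(h, r) = force / target_stress` for `r` changes only the
#' surface area.  Used to drive heterodonty-recovery experiments.
#'
#' @param spec a [jaw_spec()].
#' @param tooth_index index of the tooth to modify (1..n_teeth).
#' @param stress_factor target stress as a multiple of the unmodified
#'   median stress (> 0).
#' @return a modified `jaw_spec` with attribute `outlier` recording the
#'   tooth index and factor.
#' @export
inject_outlier <- function(spec, tooth_index, stress_factor) {
  if (!inherits(spec, "jaw_spec")) stop("inject_outlier() needs a jaw_spec")
  tooth_index <- as.integer(tooth_index)
  if (is.na(tooth_index) || tooth_index < 1 || tooth_index > spec$n_teeth)
    stop(sprintf("tooth_index must be in 1..%d", spec$n_teeth))
  if (!is.finite(stress_factor) || stress_factor <= 0)
    stop("stress_factor must be positive")
  gt <- make_jaw(spec)$ground_truth
  target <- stress_factor * median(gt$stress)
  force <- gt$force[tooth_index]
  h <- spec$heights[tooth_index]
  target_area <- force / target
  f <- function(r) cone_area(h, r) - target_area
  upper <- max(spec$radii[tooth_index], sqrt(target_area / pi)) * 2 + h
  r_new <- uniroot(f, lower = 1e-9, upper = upper, tol = 1e-12)$root
  spec$radii[tooth_index] <- r_new
  attr(spec, "outlier") <- list(tooth_index = tooth_index, factor = stress_factor)
  spec
}

#' Write a synthetic jaw bundle to disk
#'
#' Writes one ASCII PLY per tooth, the landmarks as both FCSV and JSON,
#' and the ground-truth CSV.  The bundle is a complete, self-contained
#' input for the `compute` pipeline.
#'
#' @param jaw result of [make_jaw()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the written paths.
#' @export
write_jaw_bundle <- function(jaw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh_paths <- character(0)
  for (nm in names(jaw$meshes)) {
    p <- file.path(dir, paste0(nm, ".ply"))
    write_mesh(jaw$meshes[[nm]], p)
    mesh_paths[nm] <- p
  }
  fcsv <- file.path(dir, "landmarks.fcsv")
  json <- file.path(dir, "landmarks.json")
  write_landmarks(jaw$landmarks, fcsv)
  write_landmarks(jaw$landmarks, json)
  gt <- file.path(dir, "ground_truth.csv")
  write.csv(jaw$ground_truth, gt, row.names = FALSE)
  invisible(list(meshes = mesh_paths, landmarks_fcsv = fcsv,
                 landmarks_json = json, ground_truth = gt))
}
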