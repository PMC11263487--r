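#' Specify a jaw-closing muscle
#'
#' Holds one closing muscle's force parameters.  Two pathways supply the
#' input force: a direct force in newtons (default 1 N when nothing is
#' given), or a physiological estimate from muscle volume,
#' `F_in = volume * cos(pennation) / fiber_length * f_max`, where the
#' fiber length defaults to the origin-insertion distance.  When both a
#' direct force and volume parameters are supplied the volume estimate
#' wins and a message is emitted (an explicit anatomical estimate beats
#' an assumed force).
#'
#' The insertion angle is the angle between the muscle's line of action
#' (insertion to origin) and the in-lever (insertion to jaw joint):
#' `sin(angle) = 1` means a perpendicular pull delivering maximal
#' torque.  Left `NULL`, it is measured from the origin landmark when
#' one is available and otherwise defaults to 90 degrees.
#'
#' @param name muscle name.
#' @param insertion,origin optional 3D points (mm); when omitted they
#'   are resolved from the jaw [landmark_set()] (`insertion_k`,
#'   `origin_k`) by [compute_dentition()].
#' @param input_force direct input force in N, or `NULL` (default 1 N).
#' @param insertion_angle_deg insertion angle in degrees (0, 180], or
#'   `NULL` to measure/default it.
#' @param volume muscle volume in mm^3 (enables the physiological
#'   pathway).
#' @param pennation_angle_deg fiber pennation angle in degrees
#'   \[0, 90).  Default 0.
#' @param f_max maximal isometric muscle stress in N/mm^2.  Default 0.2.
#' @param fiber_length optional fiber length in mm (overrides the
#'   origin-insertion proxy).
#' @return an object of class `muscle_spec`.
#' @export
muscle_spec <- function(name = "muscle", insertion = NULL, origin = NULL,
                        input_force = NULL, insertion_angle_deg = NULL,
                        volume = NULL, pennation_angle_deg = 0,
                        f_max = 0.2, fiber_length = NULL) {
  chk_pt <- function(p, what) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 3 || !all(is.finite(p)))
      stop(sprintf("%s must be a finite 3D point", what))
    p
  }
  chk_pos <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != 1 || !is.finite(x) || x <= 0)
      stop(sprintf("%s must be a single positive number", what))
    x
  }
  if (!is.null(insertion_angle_deg)) {
    insertion_angle_deg <- as.numeric(insertion_angle_deg)
    if (insertion_angle_deg <= 0 || insertion_angle_deg > 180)
      stop("insertion_angle_deg must be in (0, 180]")
  }
  pennation_angle_deg <- as.numeric(pennation_angle_deg)
  if (pennation_angle_deg < 0 || pennation_angle_deg >= 90)
    stop("pennation_angle_deg must be in [0, 90)")
  structure(list(
    name = as.character(name)[1],
    insertion = chk_pt(insertion, "insertion"),
    origin = chk_pt(origin, "origin"),
    input_force = chk_pos(input_force, "input_force"),
    insertion_angle_deg = insertion_angle_deg,
    volume = chk_pos(volume, "volume"),
    pennation_angle_deg = pennation_angle_deg,
    f_max = chk_pos(f_max, "f_max") %||% stop("f_max is required"),
    fiber_length = chk_pos(fiber_length, "fiber_length")),
    class = "muscle_spec")
}

#' @export
print.muscle_spec <- function(x, ...) {
  cat(sprintf("muscle_spec '%s': F_in=%s N, angle=%s deg, pennation=%g deg, F_max=%g N/mm^2\n",
              x$name,
              if (is.null(x$volume)) format(x$input_force %||% 1) else "volume-based",
              if (is.null(x$insertion_angle_deg)) "auto" else format(x$insertion_angle_deg),
              x$pennation_angle_deg, x$f_max))
  invisible(x)
}

#' Lever distances for one tooth
#'
#' All four quantities are straight-line Euclidean distances in mm:
#' in-lever (jaw joint to muscle insertion), out-lever (joint to tooth
#' tip), position (joint to tooth base) and jaw length (joint to jaw
#' tip).
#'
#' @param jaw a [landmark_set()].
#' @param muscle a [muscle_spec()] (its insertion point, or the jaw's
#'   `insertion_1` when unset).
#' @param tip,base detected tooth landmarks (3D points, mm).
#' @return list with `in_lever`, `out_lever`, `position`, `jaw_length`.
#' @export
levers <- function(jaw, muscle, tip, base) {
  if (!inherits(jaw, "landmark_set")) jaw <- landmark_set(jaw)
  insertion <- muscle$insertion %||% jaw$insertion_1
  if (is.null(insertion)) stop("no insertion point available for muscle")
  joint <- jaw$jaw_joint
  out <- list(in_lever  = vnorm(insertion - joint),
              out_lever = vnorm(as.numeric(tip) - joint),
              position  = vnorm(as.numeric(base) - joint),
              jaw_length = vnorm(jaw$jaw_tip - joint))
  bad <- names(out)[vapply(out, function(x) x < .Machine$double.eps, logical(1))]
  if (length(bad))
    stop("zero-length lever distance(s): ", paste(bad, collapse = ", "))
  out
}

#' Muscle input force
#'
#' Returns the direct input force (default 1 N) unless volume
#' parameters are supplied, in which case
#' `F_in = volume * cos(pennation) / fiber_length * f_max`
#' with the origin-insertion distance as the fiber-length proxy.
#'
#' @param muscle a [muscle_spec()].
#' @return input force in N.
#' @export
input_force <- function(muscle) {
  if (!inherits(muscle, "muscle_spec")) stop("input_force() needs a muscle_spec")
  if (is.null(muscle$volume)) return(muscle$input_force %||% 1)
  fl <- muscle$fiber_length
  if (is.null(fl)) {
    if (is.null(muscle$origin) || is.null(muscle$insertion))
      stop(sprintf("muscle '%s': volume given but no fiber_length and no origin/insertion to measure it",
                   muscle$name))
    fl <- vnorm(muscle$origin - muscle$insertion)
    if (fl < .Machine$double.eps)
      stop(sprintf("muscle '%s': origin and insertion coincide", muscle$name))
  }
  if (!is.null(muscle$input_force))
    message(sprintf("muscle '%s': both direct input_force and volume given; using the volume-based estimate",
                    muscle$name))
  muscle$volume * cos(deg2rad(muscle$pennation_angle_deg)) / fl * muscle$f_max
}

#' Muscle insertion angle
#'
#' The angle at the insertion point between the muscle's line of action
#' (insertion to origin) and the in-lever (insertion to jaw joint), in
#' degrees within (0, 180).  Collinear geometry (angle 0 or 180) raises
#' a warning but still returns the value.
#'
#' @param jaw_joint,insertion,origin three distinct 3D points (mm).
#' @return angle in degrees.
#' @export
insertion_angle <- function(jaw_joint, insertion, origin) {
  a <- as.numeric(jaw_joint) - as.numeric(insertion)
  b <- as.numeric(origin) - as.numeric(insertion)
  na <- vnorm(a); nb <- vnorm(b)
  if (na < .Machine$double.eps || nb < .Machine$double.eps)
    stop("insertion_angle needs three distinct points")
  cosang <- min(max(sum(a * b) / (na * nb), -1), 1)
  ang <- acos(cosang) * 180 / pi
  if (ang < 1e-6 || ang > 180 - 1e-6)
    warning(sprintf("degenerate insertion angle %.3g deg (collinear muscle line)", ang))
  ang
}

#' Output force at a tooth
#'
#' Static third-class lever model: each muscle contributes
#' `F_in * sin(angle) * (in_lever / out_lever)` and contributions are
#' summed over muscles.  With the defaults (1 N, 90 degrees) the force
#' equals the tooth's mechanical advantage.
#'
#' @param in_levers numeric vector of in-levers (mm), one per muscle.
#' @param out_lever out-lever of the tooth (mm, > 0).
#' @param input_forces numeric vector of muscle input forces (N),
#'   recycled to the number of muscles.  Default 1.
#' @param insertion_angles_deg numeric vector of insertion angles
#'   (degrees), recycled.  Default 90.
#' @return total output force in N.
#' @export
tooth_force <- function(in_levers, out_lever, input_forces = 1,
                        insertion_angles_deg = 90) {
  if (length(out_lever) != 1 || !is.finite(out_lever) || out_lever <= 0)
    stop("out_lever must be a single positive number")
  n <- length(in_levers)
  input_forces <- rep_len(input_forces, n)
  insertion_angles_deg <- rep_len(insertion_angles_deg, n)
  sum(input_forces * sin(deg2rad(insertion_angles_deg)) * (in_levers / out_lever))
}

#' Tooth stress
#'
#' Force transmitted per unit tooth surface: `stress = force /
#' surface_area`.
#'
#' @param force output force in N.
#' @param surface_area tooth surface area in mm^2 (> 0).
#' @return stress in N/mm^2.
#' @export
tooth_stress <- function(force, surface_area) {
  if (!is.finite(surface_area) || surface_area <= 0)
    stop("surface_area must be positive")
  force / surface_area
}

# resolve per-muscle constants (insertion point, F_in, angle, in-lever)
resolve_muscles <- function(jaw, muscles) {
  lapply(seq_along(muscles), function(k) {
    m <- muscles[[k]]
    if (!inherits(m, "muscle_spec")) stop("muscles must be muscle_spec objects")
    insertion <- m$insertion %||% jaw[[paste0("insertion_", k)]]
    if (is.null(insertion))
      stop(sprintf("muscle %d ('%s') has no insertion point (set it or provide landmark insertion_%d)",
                   k, m$name, k))
    origin <- m$origin %||% jaw[[paste0("origin_", k)]]
    m$insertion <- insertion; m$origin <- origin
    ang <- m$insertion_angle_deg
    if (is.null(ang)) {
      ang <- if (!is.null(origin)) insertion_angle(jaw$jaw_joint, insertion, origin) else 90
    }
    list(spec = m, insertion = insertion,
         in_lever = vnorm(insertion - jaw$jaw_joint),
         f_in = input_force(m), angle_deg = ang)
  })
}

#' Compute the full trait battery for a dentition
#'
#' Runs tooth geometry (principal axis, tip/base detection, height,
#' width, aspect ratio, surface area) and lever mechanics (position,
#' out-lever, per-muscle in-lever/insertion angle/mechanical advantage,
#' summed output force, stress) for every tooth of a jaw.  A failure on
#' one tooth does not abort the dentition: the failing tooth is
#' reported with `ok = FALSE` and a note, the rest are unaffected.
#'
#' @param meshes list of [tooth_mesh()] objects (>= 1).
#' @param jaw a [landmark_set()].
#' @param muscles list of [muscle_spec()] (default one muscle with the
#'   standard assumptions: 1 N input force, 90-degree insertion angle).
#' @param flip `"all"`, or character vector of tooth names whose
#'   detected tip/base should be exchanged before mechanics.
#' @param overrides optional named list (by tooth name) of lists with
#'   `tip` and/or `base` 3D points replacing the detected landmarks.
#' @param jaw_id,side identifiers repeated on every row of the output
#'   (used by [run_homodonty()] for grouping).
#' @param basal_frac,raise_frac geometry tunables, see
#'   [tooth_height_width()] and [detect_tip_base()].
#' @return a data.frame with one row per tooth in the stable column
#'   order of [traits_columns()].
#' @examples
#' jaw <- make_jaw(jaw_spec(n_teeth = 3))
#' compute_dentition(jaw$meshes, jaw$landmarks)
#' @export
compute_dentition <- function(meshes, jaw, muscles = list(muscle_spec()),
                              flip = NULL, overrides = NULL,
                              jaw_id = "jaw", side = "na",
                              basal_frac = 0.1, raise_frac = 0.1) {
  if (!is.list(meshes) || length(meshes) == 0 || inherits(meshes, "tooth_mesh"))
    stop("meshes must be a non-empty list of tooth_mesh objects")
  if (!inherits(jaw, "landmark_set")) jaw <- landmark_set(jaw)
  mus <- resolve_muscles(jaw, muscles)
  nm <- length(mus)
  jaw_length <- vnorm(jaw$jaw_tip - jaw$jaw_joint)
  # tie-break vertical: normal of the plane (joint, jaw tip, first insertion)
  vertical <- tryCatch({
    v1 <- jaw$jaw_tip - jaw$jaw_joint
    v2 <- mus[[1]]$insertion - jaw$jaw_joint
    unit(c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1]))
  }, error = function(e) NULL)

  rows <- lapply(meshes, function(mesh) {
    tooth_name <- if (inherits(mesh, "tooth_mesh")) mesh$name else "<invalid>"
    row <- tryCatch({
      geo <- tooth_geometry(mesh, jaw$jaw_joint, jaw$jaw_tip,
                            basal_frac = basal_frac, raise_frac = raise_frac,
                            vertical = vertical)
      do_flip <- identical(flip, "all") || (is.character(flip) && geo$tooth %in% flip)
      if (do_flip) geo <- flip_tip_base(list(geo), "all")[[1]]
      ov <- overrides[[geo$tooth]]
      if (!is.null(ov)) {
        if (!is.null(ov$tip)) geo$tip <- as.numeric(ov$tip)
        if (!is.null(ov$base)) geo$base <- as.numeric(ov$base)
        hw <- tooth_height_width(mesh, geo$tip, geo$base, basal_frac = basal_frac)
        geo$height <- hw$height; geo$width <- hw$width
        geo$aspect_ratio <- hw$height / hw$width
      }
      out_lever <- vnorm(geo$tip - jaw$jaw_joint)
      position <- vnorm(geo$base - jaw$jaw_joint)
      if (out_lever < .Machine$double.eps) stop("tooth tip coincides with jaw joint")
      in_l <- vapply(mus, `[[`, numeric(1), "in_lever")
      ang <- vapply(mus, `[[`, numeric(1), "angle_deg")
      f_in <- vapply(mus, `[[`, numeric(1), "f_in")
      force <- tooth_force(in_l, out_lever, f_in, ang)
      stress <- tooth_stress(force, geo$surface_area)
      c(list(tooth = geo$tooth, label = mesh$label, ok = TRUE,
             jaw_id = jaw_id, side = side,
             jaw_length = jaw_length, position = position, out_lever = out_lever,
             height = geo$height, width = geo$width,
             aspect_ratio = geo$aspect_ratio, surface_area = geo$surface_area),
        setNames(as.list(in_l), paste0("in_lever_", seq_len(nm))),
        setNames(as.list(ang), paste0("insertion_angle_", seq_len(nm))),
        setNames(as.list(in_l / out_lever), paste0("mechanical_advantage_", seq_len(nm))),
        list(force = force, stress = stress,
             tip_x = geo$tip[1], tip_y = geo$tip[2], tip_z = geo$tip[3],
             base_x = geo$base[1], base_y = geo$base[2], base_z = geo$base[3],
             note = ""))
    }, error = function(e) {
      warning(sprintf("tooth '%s' failed: %s", tooth_name, conditionMessage(e)))
      c(list(tooth = tooth_name, label = NA_integer_, ok = FALSE,
             jaw_id = jaw_id, side = side,
             jaw_length = jaw_length, position = NA_real_, out_lever = NA_real_,
             height = NA_real_, width = NA_real_,
             aspect_ratio = NA_real_, surface_area = NA_real_),
        setNames(rep(list(NA_real_), nm), paste0("in_lever_", seq_len(nm))),
        setNames(rep(list(NA_real_), nm), paste0("insertion_angle_", seq_len(nm))),
        setNames(rep(list(NA_real_), nm), paste0("mechanical_advantage_", seq_len(nm))),
        list(force = NA_real_, stress = NA_real_,
             tip_x = NA_real_, tip_y = NA_real_, tip_z = NA_real_,
             base_x = NA_real_, base_y = NA_real_, base_z = NA_real_,
             note = conditionMessage(e)))
    })
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[, traits_columns(nm), drop = FALSE]
  rownames(out) <- NULL
  out
}
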