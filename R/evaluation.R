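#' Implant-intrinsic reference frame
#'
#' The implant positioning frame: an origin on the implant floor and
#' right-handed orthonormal axes following the aircraft convention — the
#' x-axis along the implant's long axis towards the dorsal tip, the y-axis
#' across the proximal extensions, the z-axis facing upwards. Placement
#' deviations are decomposed into roll (about x), pitch (about y) and yaw
#' (about z) in this frame.
#'
#' `frame_from_landmarks()` constructs the frame from three non-collinear
#' landmark points by Gram-Schmidt: `x = normalize(x_point - origin)`;
#' `z = normalize(x cross (y_hint - origin))`, flipped if needed so it has
#' a positive component along `up`; `y = z cross x`.
#'
#' @param origin world-mm point on the implant floor (frame origin).
#' @param x_point world-mm point defining the x direction (dorsal tip).
#' @param y_hint world-mm point on the positive-y side (proximal
#'   extensions); only its off-axis component matters.
#' @param side `"left"` or `"right"`.
#' @param up reference direction resolving the z sign (default `c(0,0,1)`).
#' @param key_points optional named list of world-mm points whose
#'   displacement is reported (e.g. `medial_ledge_top`, `dorsal_tip`).
#' @return An object of class `implant_frame`: origin, unit `x_axis`,
#'   `y_axis`, `z_axis` (right-handed), `side`, `key_points`.
#' @export
frame_from_landmarks <- function(origin, x_point, y_hint, side = c("left", "right"),
                                 up = c(0, 0, 1), key_points = list()) {
  side <- match.arg(side)
  origin <- as.numeric(origin); x_point <- as.numeric(x_point); y_hint <- as.numeric(y_hint)
  stopifnot(length(origin) == 3, length(x_point) == 3, length(y_hint) == 3)
  x <- x_point - origin
  if (sqrt(sum(x^2)) < 1e-12) stop("frame_from_landmarks: origin and x_point coincide")
  x <- x / sqrt(sum(x^2))
  v <- y_hint - origin
  z <- cross3(x, v)
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9) stop("frame_from_landmarks: landmarks are collinear (degenerate frame)")
  z <- z / nz
  if (sum(z * up) < 0) z <- -z
  y <- cross3(z, x)
  implant_frame(origin, x, y, z, side = side, key_points = key_points)
}

#' @rdname frame_from_landmarks
#' @param x_axis,y_axis,z_axis unit axis vectors (right-handed).
#' @export
implant_frame <- function(origin, x_axis, y_axis, z_axis, side = c("left", "right"),
                          key_points = list()) {
  side <- match.arg(side)
  origin <- as.numeric(origin)
  x_axis <- as.numeric(x_axis); y_axis <- as.numeric(y_axis); z_axis <- as.numeric(z_axis)
  A <- cbind(x_axis, y_axis, z_axis)
  if (max(abs(t(A) %*% A - diag(3))) > 1e-9) {
    stop("implant_frame: axes must be orthonormal")
  }
  if (max(abs(cross3(x_axis, y_axis) - z_axis)) > 1e-9) {
    stop("implant_frame: axes must be right-handed (x cross y = z)")
  }
  if (length(key_points) && is.null(names(key_points))) {
    stop("implant_frame: key_points must be named")
  }
  structure(list(origin = origin, x_axis = x_axis, y_axis = y_axis,
                 z_axis = z_axis, side = side, key_points = key_points,
                 mirrored = FALSE),
            class = "implant_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.implant_frame <- function(x, ...) {
  cat(sprintf("implant frame (%s side%s): origin (%.2f, %.2f, %.2f) mm\n",
              x$side, if (isTRUE(x$mirrored)) ", mirrored" else "",
              x$origin[1], x$origin[2], x$origin[3]))
  if (length(x$key_points)) {
    cat("  key points:", paste(names(x$key_points), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mirror a right-sided frame over the xz-plane
#'
#' Flips the y-axis of a right-sided frame so left and right implants are
#' reported in a common convention; as a consequence the reported yaw and
#' roll directions are sign-opposed relative to the unmirrored frame while
#' pitch and the x/z conventions are unchanged. Applying it twice restores
#' the original frame exactly (involution). Internally the same effect is
#' achieved by conjugating the deviation transform with `diag(1, -1, 1)`;
#' see [mirror_transform()].
#'
#' @param frame an `implant_frame` with `side = "right"`.
#' @return The mirrored frame (`mirrored` flag toggled).
#' @export
mirror_for_right_side <- function(frame) {
  stopifnot(inherits(frame, "implant_frame"))
  if (frame$side != "right") {
    stop("mirror_for_right_side: frame is not right-sided")
  }
  frame$y_axis <- -frame$y_axis
  frame$mirrored <- !isTRUE(frame$mirrored)
  frame
}

# 4x4 world-from-frame matrix (columns = axes, origin in last column).
frame_matrix <- function(frame) {
  m <- diag(4)
  m[1:3, 1:3] <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  m[1:3, 4] <- frame$origin
  m
}

#' Express a world deviation transform in the implant frame
#'
#' Conjugates a world-space rigid transform into frame coordinates,
#' `T_f = F^-1 T F`, and applies the xz-mirroring convention when the
#' frame is right-sided.
#'
#' @param transform a world-space `rigid_transform`.
#' @param frame an `implant_frame`.
#' @return A `rigid_transform` in frame coordinates.
#' @export
transform_in_frame <- function(transform, frame) {
  transform <- as_rigid_transform(transform)
  FM <- reporting_frame_matrix(frame)
  m <- solve(FM) %*% unclass(transform) %*% FM
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# Frame matrix including the xz-mirroring convention for right-sided
# frames. For a right frame that has not been explicitly mirrored the
# y-axis is negated here; an already mirrored frame stores the negated
# axis itself. Conjugation by this (possibly improper) matrix still yields
# a proper rigid transform.
reporting_frame_matrix <- function(frame) {
  FM <- frame_matrix(frame)
  if (frame$side == "right" && !isTRUE(frame$mirrored)) {
    FM <- FM %*% diag(c(1, -1, 1, 1))
  }
  FM
}

#' Align the planned implant onto the reference implant
#'
#' ICP-registers the planned implant model onto the reference implant
#' model, producing the local-to-global transform that carries the
#' planning coordinates into the reference frame. Both meshes must be the
#' same implant shape; a final RMS above `rms_warn` (default 0.5 mm)
#' triggers a shape-mismatch warning.
#'
#' @param planned,reference `triangle_mesh` objects (or point matrices /
#'   `surface_sample`s).
#' @param rms_warn RMS threshold (mm) for the mismatch warning.
#' @param ... further arguments passed to [icp_register()].
#' @return The `icp_result`; its `transform` is the local-to-global map.
#' @export
align_to_reference <- function(planned, reference, rms_warn = 0.5, ...) {
  res <- icp_register(planned, reference, ...)
  if (res$rms > rms_warn) {
    warning(sprintf("align_to_reference: RMS %.3f mm exceeds %.2f mm - planned and reference may be different implant shapes/sizes",
                    res$rms, rms_warn))
  }
  res
}

#' Key-point displacements under a deviation transform
#'
#' For each named key point `p` of the frame, reports the displacement
#' `d = (R p + t) - p` expressed in frame coordinates (mm), with the
#' y component mirrored for right-sided frames.
#'
#' @param transform world-space deviation `rigid_transform`.
#' @param frame an `implant_frame` with key points.
#' @return Named list of length-3 displacement vectors (mm); empty if the
#'   frame has no key points.
#' @export
keypoint_displacement <- function(transform, frame) {
  transform <- as_rigid_transform(transform)
  if (!length(frame$key_points)) return(list())
  A <- reporting_frame_matrix(frame)[1:3, 1:3]
  out <- lapply(frame$key_points, function(p) {
    d <- as.numeric(solve(A) %*% (apply_transform(transform, as.numeric(p)) - as.numeric(p)))
    names(d) <- c("x", "y", "z")
    d
  })
  out
}

#' Evaluate the achieved implant position against the plan
#'
#' The full placement-evaluation pipeline. First the planned implant model
#' is ICP-registered onto the reference implant, giving the
#' local-to-global transform; the same transform is applied to the
#' achieved implant surface, preserving the planned-to-achieved relation
#' while moving both into the reference coordinates. A second ICP then
#' registers the (globally mapped) planned implant onto the achieved one;
#' the resulting transform is the placement deviation. It is expressed in
#' the implant frame (mirrored for right-sided cases), decomposed into
#' roll, pitch and yaw (degrees, roll-first/pitch-second/yaw-third order)
#' and the frame-origin translations (mm), and key-point displacements are
#' derived from the same matrix.
#'
#' @param planned planned implant `triangle_mesh` (planning coordinates).
#' @param achieved achieved implant `triangle_mesh` (same coordinates as
#'   `planned`, e.g. segmented from the co-registered post-op CT).
#' @param reference reference implant `triangle_mesh` carrying the frame.
#' @param frame `implant_frame` defined on `reference`.
#' @param side `"left"` or `"right"`; must match `frame$side`.
#' @param n_sample surface sampling density of the moving (planned)
#'   surface in both ICPs (default 20000).
#' @param n_target sampling density of the fixed surfaces (reference and
#'   achieved; default `2 * n_sample`). A denser target smooths the
#'   nearest-neighbour field, which matters when the achieved surface
#'   comes from a voxelized segmentation.
#' @param seed sampling seed (default 1).
#' @param trim_fraction ICP trimming for partial overlap (default 0).
#' @param exclude_labels face labels excluded from the planned/achieved
#'   sampling (bent or adjusted regions).
#' @param id case identifier recorded in the report.
#' @param init ICP initialization for both stages (see [icp_register()]);
#'   the default `"principal"` (centroid + inertia axes) avoids the
#'   shallow local minima that a cold identity start can fall into when
#'   the achieved surface is a voxel-derived shell.
#' @param ... further arguments passed to [icp_register()].
#' @return An object of class `oipf_report`: list with `pose` (class
#'   `pose_parameters`), `transform` (the deviation `rigid_transform` in
#'   world coordinates), `transform_in_frame`, `alignment` and
#'   `registration` (`icp_result`s of the two stages), and `provenance`.
#' @export
evaluate_placement <- function(planned, achieved, reference, frame,
                               side = frame$side, n_sample = 20000,
                               n_target = 2 * n_sample, seed = 1L,
                               trim_fraction = 0, exclude_labels = NULL,
                               id = "case", init = "principal", ...) {
  stopifnot(inherits(frame, "implant_frame"))
  side <- match.arg(side, c("left", "right"))
  if (side != frame$side) {
    stop(sprintf("evaluate_placement: side '%s' does not match frame side '%s'", side, frame$side))
  }
  planned_s <- as_sample(planned, n_sample, seed, exclude_labels)
  reference_s <- as_sample(reference, n_target, seed + 1L, NULL)
  alignment <- withCallingHandlers(
    align_to_reference(planned_s, reference_s, init = init, ...),
    error = function(e) stop(sprintf("[alignment] %s", conditionMessage(e)), call. = FALSE)
  )
  T_lg <- alignment$transform
  achieved_s <- as_sample(achieved, n_target, seed + 2L, exclude_labels)
  planned_g <- apply_transform(T_lg, planned_s)
  achieved_g <- apply_transform(T_lg, achieved_s)
  registration <- tryCatch(
    icp_register(planned_g, achieved_g, trim_fraction = trim_fraction, init = init, ...),
    error = function(e) stop(sprintf("[registration] %s", conditionMessage(e)), call. = FALSE)
  )
  T_02 <- registration$transform
  T_f <- transform_in_frame(T_02, frame)
  dec <- decompose_transform(T_f)
  pose <- structure(list(
    roll = dec$roll, pitch = dec$pitch, yaw = dec$yaw,
    translation = dec$translation,
    key_point_displacements = keypoint_displacement(T_02, frame),
    side = side, gimbal_lock = dec$gimbal_lock
  ), class = "pose_parameters")
  structure(list(
    id = id, pose = pose, transform = T_02, transform_in_frame = T_f,
    alignment = alignment, registration = registration,
    provenance = list(n_sample = n_sample, n_target = n_target, seed = seed,
                      trim_fraction = trim_fraction,
                      exclude_labels = exclude_labels,
                      side = side,
                      version = as.character(utils::packageVersion("oipf")))
  ), class = "oipf_report")
}

as_sample <- function(x, n_sample, seed, exclude_labels) {
  if (inherits(x, "surface_sample")) return(x)
  if (inherits(x, "triangle_mesh")) {
    return(sample_surface(x, n = n_sample, seed = seed, exclude_labels = exclude_labels))
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  structure(list(points = x, face = rep(NA_integer_, nrow(x)), seed = seed),
            class = "surface_sample")
}

#' @export
print.pose_parameters <- function(x, ...) {
  cat(sprintf("pose (%s side%s): roll %.1f deg, pitch %.1f deg, yaw %.1f deg\n",
              x$side, if (isTRUE(x$gimbal_lock)) ", GIMBAL LOCK" else "",
              x$roll, x$pitch, x$yaw))
  cat(sprintf("  origin translation: (%.1f, %.1f, %.1f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  for (nm in names(x$key_point_displacements)) {
    d <- x$key_point_displacements[[nm]]
    cat(sprintf("  %s: (%.1f, %.1f, %.1f) mm, |d| = %.1f mm\n",
                nm, d[1], d[2], d[3], sqrt(sum(d^2))))
  }
  invisible(x)
}

#' @export
print.oipf_report <- function(x, ...) {
  cat(sprintf("implant placement report '%s'\n", x$id))
  print(x$pose)
  cat(sprintf("  alignment rms %.4f mm (%d it), registration rms %.4f mm (%d it)\n",
              x$alignment$rms, x$alignment$iterations,
              x$registration$rms, x$registration$iterations))
  invisible(x)
}

#' @export
as.data.frame.oipf_report <- function(x, ...) {
  data.frame(id = x$id,
             roll = x$pose$roll, pitch = x$pose$pitch, yaw = x$pose$yaw,
             t_x = unname(x$pose$translation[1]),
             t_y = unname(x$pose$translation[2]),
             t_z = unname(x$pose$translation[3]),
             stringsAsFactors = FALSE)
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (pose, matrices, ICP summaries, provenance) and
#' `report.csv` (one row: id, roll, pitch, yaw, t_x, t_y, t_z — angles in
#' degrees, translations in mm).
#'
#' @param report an `oipf_report`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "oipf_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    id = report$id,
    pose = list(
      roll = report$pose$roll, pitch = report$pose$pitch, yaw = report$pose$yaw,
      translation = as.list(report$pose$translation),
      key_point_displacements = lapply(report$pose$key_point_displacements, as.list),
      side = report$pose$side, gimbal_lock = report$pose$gimbal_lock
    ),
    transform = as.numeric(t(unclass(report$transform))),
    transform_in_frame = as.numeric(t(unclass(report$transform_in_frame))),
    units = list(angles = "degrees", translations = "mm"),
    alignment = icp_summary(report$alignment),
    registration = icp_summary(report$registration),
    provenance = report$provenance
  )
  jsonlite::write_json(obj, file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report), file.path(dir, "report.csv"), row.names = FALSE)
  invisible(dir)
}

icp_summary <- function(res) {
  list(transform = as.numeric(t(unclass(res$transform))), rms = res$rms,
       iterations = res$iterations, converged = res$converged)
}

#' Serialize an implant frame to JSON
#'
#' @param frame an `implant_frame`.
#' @param path file path; if `NULL` a JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
frame_to_json <- function(frame, path = NULL) {
  obj <- list(origin = frame$origin, x_axis = frame$x_axis, y_axis = frame$y_axis,
              z_axis = frame$z_axis, side = frame$side,
              key_points = lapply(frame$key_points, as.numeric), units = "mm")
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname frame_to_json
#' @param json path to a JSON file or a JSON string.
#' @export
frame_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  implant_frame(obj$origin, obj$x_axis, obj$y_axis, obj$z_axis, side = obj$side,
                key_points = lapply(obj$key_points, as.numeric))
}
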