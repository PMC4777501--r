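#' Rigid transform from rotation and translation
#'
#' Builds a 4x4 homogeneous rigid transform (millimetres) from a 3x3
#' rotation block and a translation vector. The rotation block is validated
#' to be a proper rotation: `R %*% t(R) = I` and `det(R) = +1`. Blocks that
#' are orthonormal only to about `1e-6` (as produced by chains of ICP fits
#' or mesh voxelization) are projected to the nearest rotation by polar
#' decomposition; anything farther from a rotation is an error.
#'
#' @param rotation 3x3 rotation matrix (unitless).
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`: a 4x4 matrix whose last
#'   row is exactly `c(0, 0, 0, 1)`.
#' @examples
#' rigid_transform(euler_to_rotation(roll = 10, pitch = 0, yaw = 0), c(1, 2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("rigid_transform: non-finite entries")
  }
  rotation <- check_rotation(rotation)
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  structure(m, class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (mm):\n")
  print(unclass(x))
  p <- decompose_transform(x)
  cat(sprintf("roll %.3f deg, pitch %.3f deg, yaw %.3f deg, t = (%.3f, %.3f, %.3f) mm\n",
              p$roll, p$pitch, p$yaw, p$translation[1], p$translation[2], p$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x object to test or coerce.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @rdname rigid_transform
#' @export
as_rigid_transform <- function(x) {
  if (is_rigid_transform(x)) return(x)
  x <- as.matrix(x)
  stopifnot(all(dim(x) == c(4, 4)))
  if (max(abs(x[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("as_rigid_transform: last row must be (0, 0, 0, 1)")
  }
  rigid_transform(x[1:3, 1:3], x[1:3, 4])
}

# Validate a rotation block; re-orthonormalize by polar projection when the
# deviation is small (<= tol_project per element), error beyond that.
check_rotation <- function(R, tol_exact = 1e-9, tol_project = 1e-6) {
  err <- max(abs(R %*% t(R) - diag(3)))
  d <- det(R)
  if (d < 0) stop("rotation block has negative determinant (reflection)")
  if (err <= tol_exact && abs(d - 1) <= tol_exact) return(R)
  if (err <= tol_project * 10 && abs(d - 1) <= tol_project * 10) {
    return(nearest_rotation(R))
  }
  stop(sprintf("matrix is not a rotation (orthonormality error %.3g, det %.6f)", err, d))
}

#' Nearest proper rotation (polar projection)
#'
#' Projects an approximately orthonormal 3x3 matrix onto SO(3) via SVD:
#' `R = U V'` with the sign of the smallest singular vector corrected so
#' `det(R) = +1`.
#'
#' @param R a 3x3 matrix close to a rotation.
#' @return A proper rotation matrix.
#' @export
nearest_rotation <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Compose a rotation from roll, pitch and yaw (ZYX order)
#'
#' Builds the rotation `Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`: roll is applied
#' first (about x), then pitch (about y), then yaw (about z) — the aircraft
#' convention used for implant pose angles. Element `[3, 1]` of the result
#' equals `-sin(pitch)`.
#'
#' @param roll,pitch,yaw rotation angles about the x, y and z axes.
#' @param degrees logical; if `TRUE` (default) angles are in degrees.
#' @return 3x3 rotation matrix.
#' @examples
#' euler_to_rotation(roll = -9.3, pitch = -0.4, yaw = 11.3)
#' @export
euler_to_rotation <- function(roll, pitch, yaw, degrees = TRUE) {
  if (!all(is.finite(c(roll, pitch, yaw)))) stop("euler_to_rotation: non-finite angle")
  if (degrees) {
    roll <- roll * pi / 180; pitch <- pitch * pi / 180; yaw <- yaw * pi / 180
  }
  ca <- cos(yaw);  sa <- sin(yaw)
  cb <- cos(pitch); sb <- sin(pitch)
  cg <- cos(roll); sg <- sin(roll)
  matrix(c(
    ca * cb, ca * sb * sg - sa * cg, ca * sb * cg + sa * sg,
    sa * cb, sa * sb * sg + ca * cg, sa * sb * cg - ca * sg,
    -sb,     cb * sg,                cb * cg
  ), nrow = 3, byrow = TRUE)
}

#' Decompose a rotation into roll, pitch and yaw (ZYX order)
#'
#' Inverts [euler_to_rotation()]: `pitch = asin(-R[3,1])`,
#' `yaw = atan2(R[2,1], R[1,1])`, `roll = atan2(R[3,2], R[3,3])`, with
#' pitch in `[-90, 90]` degrees and roll/yaw in `(-180, 180]`. At gimbal
#' lock (`|cos(pitch)| < 1e-8`, i.e. pitch at +/-90 degrees) roll and yaw
#' are not separately determined; the convention `roll := 0` is applied,
#' the remainder is folded into yaw, and `gimbal_lock` is flagged.
#'
#' @param R 3x3 rotation matrix (validated; near-rotations are projected).
#' @param degrees logical; return angles in degrees (default) or radians.
#' @return A list with `roll`, `pitch`, `yaw` and logical `gimbal_lock`.
#' @export
rotation_to_euler <- function(R, degrees = TRUE) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (!all(is.finite(R))) stop("rotation_to_euler: non-finite entries")
  R <- check_rotation(R)
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  pitch <- asin(sb)
  gimbal <- abs(cos(pitch)) < 1e-8
  if (!gimbal) {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  } else {
    # pitch = +/-90 deg: only yaw -/+ roll is determined; take roll = 0
    roll <- 0
    if (sb > 0) {
      yaw <- -atan2(R[1, 2], R[1, 3])
    } else {
      yaw <- atan2(-R[1, 2], -R[1, 3])
    }
  }
  k <- if (degrees) 180 / pi else 1
  list(roll = roll * k, pitch = pitch * k, yaw = yaw * k, gimbal_lock = gimbal)
}

#' Decompose a rigid transform into pose parameters
#'
#' Splits a 4x4 rigid transform into roll/pitch/yaw angles (degrees, ZYX
#' order, see [rotation_to_euler()]) and the translation triple (mm) read
#' from the translation block.
#'
#' @param transform a `rigid_transform` (or 4x4 matrix coercible to one).
#' @return A list with `roll`, `pitch`, `yaw` (degrees), `translation`
#'   (named numeric of length 3, mm) and `gimbal_lock`.
#' @export
decompose_transform <- function(transform) {
  transform <- as_rigid_transform(transform)
  e <- rotation_to_euler(transform[1:3, 1:3])
  t <- as.numeric(transform[1:3, 4])
  names(t) <- c("x", "y", "z")
  list(roll = e$roll, pitch = e$pitch, yaw = e$yaw,
       translation = t, gimbal_lock = e$gimbal_lock)
}

#' Build a rigid transform from pose parameters
#'
#' Inverse of [decompose_transform()]: rotation composed in roll-first,
#' pitch-second, yaw-third order, then translation.
#'
#' @param roll,pitch,yaw angles in degrees.
#' @param translation numeric length-3, mm.
#' @return A `rigid_transform`.
#' @export
transform_from_pose <- function(roll = 0, pitch = 0, yaw = 0, translation = c(0, 0, 0)) {
  rigid_transform(euler_to_rotation(roll, pitch, yaw), translation)
}

#' Compose and invert rigid transforms
#'
#' `transform_compose(a, b)` returns the transform applying `b` first and
#' `a` second (matrix product `a %*% b`); `transform_inverse(a)` returns the
#' inverse.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  a <- as_rigid_transform(a); b <- as_rigid_transform(b)
  m <- unclass(a) %*% unclass(b)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @rdname transform_compose
#' @export
transform_inverse <- function(a) {
  a <- as_rigid_transform(a)
  R <- t(a[1:3, 1:3])
  rigid_transform(R, -R %*% a[1:3, 4])
}

#' Apply a rigid transform to points or a mesh
#'
#' Maps every point `p` to `R p + t`. Pairwise distances are preserved to
#' numerical precision.
#'
#' @param transform a `rigid_transform`.
#' @param x an `n x 3` point matrix, a length-3 vector, a `triangle_mesh`
#'   or a `surface_sample`.
#' @return The transformed object, same type as `x`.
#' @export
apply_transform <- function(transform, x) {
  transform <- as_rigid_transform(transform)
  R <- transform[1:3, 1:3]
  tr <- transform[1:3, 4]
  map <- function(p) sweep(p %*% t(R), 2, -tr)
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- map(x$vertices)
    return(x)
  }
  if (inherits(x, "surface_sample")) {
    x$points <- map(x$points)
    return(x)
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    return(as.numeric(R %*% x + tr))
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  if (!all(is.finite(x))) stop("apply_transform: non-finite coordinates")
  map(x)
}

#' Mirror a transform over the xz-plane
#'
#' Conjugates a rigid transform by the reflection `diag(1, -1, 1)`:
#' `T' = M T M`. The result is again a proper rigid transform whose yaw and
#' roll (and y-translation) are sign-opposed while pitch and the x/z
#' translations are unchanged. This is how right-sided implant poses are
#' brought into the left-side reporting convention.
#'
#' @param transform a `rigid_transform`.
#' @return The conjugated `rigid_transform`.
#' @export
mirror_transform <- function(transform) {
  transform <- as_rigid_transform(transform)
  M <- diag(c(1, -1, 1, 1))
  m <- M %*% unclass(transform) %*% M
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Serialize a rigid transform to JSON
#'
#' Writes the 16 matrix entries row-major plus unit and convention
#' metadata; [transform_from_json()] reads it back.
#'
#' @param transform a `rigid_transform`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
transform_to_json <- function(transform, path = NULL) {
  transform <- as_rigid_transform(transform)
  obj <- list(
    matrix = as.numeric(t(unclass(transform))),
    units = "mm",
    convention = "ZYX-intrinsic-rPy-composition Rz*Ry*Rx"
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @param json a path to a JSON file or a JSON string.
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  m <- matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE)
  as_rigid_transform(m)
}
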