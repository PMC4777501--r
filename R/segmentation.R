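#' CT volume container
#'
#' A calibrated CT volume: a 3-D array of Hounsfield units plus the
#' geometry mapping voxel indices to world millimetres. The convention is
#' `world = origin + direction %*% ((index - 1) * spacing)` with 1-based
#' indices, i.e. `origin` is the world position of voxel `[1, 1, 1]`.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric length-3 voxel spacing in mm (all > 0).
#' @param origin numeric length-3 world position of the first voxel centre.
#' @param direction 3x3 orthonormal direction-cosine matrix (default
#'   identity).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  direction <- as.matrix(direction)
  stopifnot(all(dim(direction) == c(3, 3)))
  if (max(abs(direction %*% t(direction) - diag(3))) > 1e-6) {
    stop("ct_volume: direction matrix must be orthonormal")
  }
  if (!all(is.finite(voxels))) stop("ct_volume: non-finite HU values")
  rng <- range(voxels)
  if (rng[1] < -1024 - 1e-6 || rng[2] > 30000) {
    warning(sprintf("HU range [%.0f, %.0f] outside the plausible [-1024, 30000]",
                    rng[1], rng[2]))
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# World coordinates (n x 3) of 1-based voxel indices (n x 3 matrix).
voxel_to_world <- function(volume, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep((sweep(idx, 2, c(1, 1, 1)) %*% diag(volume$spacing)) %*% t(volume$direction),
        2, -volume$origin)
}

#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file (affine honoured) into a [ct_volume()].
#' Spacing and direction cosines are taken from the stored xform; voxel
#' values are assumed already calibrated to HU.
#'
#' @param path path to a NIfTI file.
#' @return A `ct_volume`.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("NIfTI file not found: %s", path))
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  A <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2, spacing, "/")
  ct_volume(array(as.numeric(img), dim = dim(img)[1:3]),
            spacing = spacing, origin = aff[1:3, 4], direction = direction)
}

#' Write a volume or mask as NIfTI
#'
#' Writes the voxel array with the geometry encoded in the sform affine.
#'
#' @param x a `ct_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    vol <- x$volume
    arr <- array(as.integer(x$mask), dim = dim(x$mask))
  } else {
    stopifnot(inherits(x, "ct_volume"))
    vol <- x
    arr <- x$voxels
  }
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Threshold segmentation of a CT volume
#'
#' Marks every voxel with HU greater than or equal to `threshold`
#' (inclusive semantics: a voxel at exactly the threshold is included).
#' The default of 1200 HU separates titanium implants (about 3000 HU) from
#' cortical bone (up to roughly 700-1000 HU in these scans). An empty
#' result raises a warning, not an error; downstream operations on an
#' empty mask do error.
#'
#' @param volume a `ct_volume`.
#' @param threshold HU cutoff (default 1200).
#' @return An object of class `binary_mask`: logical array `mask` aligned
#'   to `volume`, plus a `provenance` list (threshold, voxel count,
#'   filtering and exclusion steps applied).
#' @export
threshold_segment <- function(volume, threshold = 1200) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- volume$voxels >= threshold
  if (!any(m)) {
    warning(sprintf("threshold_segment: no voxels at or above %g HU", threshold))
  }
  structure(list(
    mask = m, volume = volume,
    provenance = list(threshold = threshold, n_voxels = sum(m),
                      components_removed = 0L, exclusions = list())
  ), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary mask: %d voxels (threshold %g HU, %d component(s) removed, %d exclusion(s))\n",
              sum(x$mask), x$provenance$threshold, x$provenance$components_removed,
              length(x$provenance$exclusions)))
  invisible(x)
}

#' Connected-component filtering of a segmentation mask
#'
#' Labels the mask with 26-connectivity (diagonal contacts count, which
#' matters for thin metallic shells) and removes small components: either
#' everything but the largest, or all components below `min_voxels`. This
#' is the automated stand-in for manually removing superfluously segmented
#' bone and detached fixation screws.
#'
#' @param mask a `binary_mask`.
#' @param min_voxels minimum component size kept when `keep = "all_above"`.
#' @param keep `"largest"` (default) or `"all_above"`.
#' @return The filtered `binary_mask` with provenance updated.
#' @export
filter_components <- function(mask, min_voxels = 1L, keep = c("largest", "all_above")) {
  stopifnot(inherits(mask, "binary_mask"))
  keep <- match.arg(keep)
  if (!any(mask$mask)) stop("filter_components: empty mask")
  lab <- cpp_label26(as.logical(mask$mask), dim(mask$mask))
  lab <- array(lab, dim = dim(mask$mask))
  n_comp <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  kept <- if (keep == "largest") 1L else which(sizes >= min_voxels)
  new_mask <- array(lab %in% kept, dim = dim(mask$mask))
  mask$provenance$components_removed <- mask$provenance$components_removed +
    (n_comp - length(kept))
  mask$provenance$n_voxels <- sum(new_mask)
  mask$mask <- new_mask
  mask
}

#' Clear world-space exclusion regions from a mask
#'
#' Removes voxels whose world coordinates fall inside any of the supplied
#' geometric regions — the reproducible equivalent of manually erasing
#' screw rings and fixation screws from a segmentation. Regions are lists
#' with `type = "sphere"` (`center`, `radius`, mm) or `type = "box"`
#' (`min`, `max`, mm, axis-aligned in world space).
#'
#' @param mask a `binary_mask`.
#' @param regions list of region descriptors (may be empty: identity).
#' @return The edited `binary_mask` with provenance updated.
#' @export
apply_exclusion <- function(mask, regions) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(regions) == 0) return(mask)
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    w <- voxel_to_world(mask$volume, idx)
    drop <- rep(FALSE, nrow(w))
    for (rg in regions) {
      if (is.null(rg$type)) stop("apply_exclusion: region without a 'type'")
      if (rg$type == "sphere") {
        if (length(rg$center) != 3 || !is.numeric(rg$radius) || rg$radius <= 0) {
          stop("apply_exclusion: sphere region needs 'center' (3) and positive 'radius'")
        }
        d2 <- (w[, 1] - rg$center[1])^2 + (w[, 2] - rg$center[2])^2 + (w[, 3] - rg$center[3])^2
        drop <- drop | d2 <= rg$radius^2
      } else if (rg$type == "box") {
        if (length(rg$min) != 3 || length(rg$max) != 3) {
          stop("apply_exclusion: box region needs 'min' and 'max' (3 each)")
        }
        drop <- drop | (w[, 1] >= rg$min[1] & w[, 1] <= rg$max[1] &
                          w[, 2] >= rg$min[2] & w[, 2] <= rg$max[2] &
                          w[, 3] >= rg$min[3] & w[, 3] <= rg$max[3])
      } else {
        stop(sprintf("apply_exclusion: unknown region type '%s'", rg$type))
      }
    }
    mask$mask[idx[drop, , drop = FALSE]] <- FALSE
  }
  mask$provenance$exclusions <- c(mask$provenance$exclusions, regions)
  mask$provenance$n_voxels <- sum(mask$mask)
  mask
}

#' Extract a surface mesh from a segmentation mask
#'
#' Converts a binary mask to a triangle mesh of its boundary: the exact
#' voxel cell boundary is extracted first (so the surface is consistent
#' with component filtering and exclusion edits and the enclosed volume
#' equals the voxel volume exactly), then Taubin lambda-mu smoothing with
#' per-component volume conservation relaxes the voxel staircase. The
#' result is watertight, deviates from the cell boundary by less than a
#' voxel diagonal, and preserves the segmented volume. Vertices are mapped
#' to world millimetres via the volume geometry.
#'
#' @param mask a non-empty `binary_mask`.
#' @param smooth_iterations Taubin iterations (default 25; 0 returns the
#'   raw blocky cell-boundary surface).
#' @param lambda,mu Taubin pass-band weights (defaults 0.5, -0.53).
#' @param fusion_transform optional `rigid_transform` applied to the
#'   extracted mesh, for volumes that still need an externally computed
#'   scan-to-scan alignment.
#' @return A `triangle_mesh` in world mm.
#' @export
mask_to_mesh <- function(mask, smooth_iterations = 25, lambda = 0.5, mu = -0.53,
                         fusion_transform = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$mask)) stop("mask_to_mesh: empty mask")
  cb <- cpp_cuberille(as.logical(mask$mask), dim(mask$mask))
  V <- cb$vertices
  if (smooth_iterations > 0) {
    V <- cpp_taubin(V, cb$faces, as.integer(smooth_iterations), lambda, mu, TRUE)
  }
  # index (0-based cell) coordinates -> world mm
  vol <- mask$volume
  W <- sweep((V %*% diag(vol$spacing)) %*% t(vol$direction), 2, -vol$origin)
  mesh <- triangle_mesh(W, cb$faces, weld_tol = 0)
  if (!is.null(fusion_transform)) mesh <- apply_transform(fusion_transform, mesh)
  mesh
}

#' One-call implant segmentation pipeline
#'
#' Chains [threshold_segment()], optional [apply_exclusion()],
#' [filter_components()] and [mask_to_mesh()]: the standard route from a
#' co-registered post-operative CT to an achieved-implant surface mesh.
#'
#' @param volume a `ct_volume`.
#' @param threshold HU cutoff (default 1200).
#' @param min_voxels smallest component kept (default: keep largest only).
#' @param exclusion_regions optional region list for [apply_exclusion()].
#' @param fusion_transform optional externally supplied scan-to-scan
#'   `rigid_transform` applied to the extracted mesh.
#' @param smooth_iterations passed to [mask_to_mesh()].
#' @return List with `mesh` (`triangle_mesh`) and `mask` (`binary_mask`).
#' @export
segment_implant <- function(volume, threshold = 1200, min_voxels = NULL,
                            exclusion_regions = list(), fusion_transform = NULL,
                            smooth_iterations = 25) {
  mask <- suppressWarnings(threshold_segment(volume, threshold))
  if (!any(mask$mask)) stop("segment_implant: segmentation is empty; check the HU threshold")
  if (length(exclusion_regions) > 0) mask <- apply_exclusion(mask, exclusion_regions)
  mask <- if (is.null(min_voxels)) {
    filter_components(mask, keep = "largest")
  } else {
    filter_components(mask, min_voxels = min_voxels, keep = "all_above")
  }
  list(mesh = mask_to_mesh(mask, smooth_iterations = smooth_iterations,
                           fusion_transform = fusion_transform),
       mask = mask)
}
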