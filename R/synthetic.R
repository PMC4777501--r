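#' Parameters of the synthetic surrogate implant
#'
#' The surrogate is a thin curved shell standing in for a preformed
#' orbital floor implant: a tapered floor plate with a saddle-like height
#' profile and a twist (so the shape has no rotational self-symmetry and
#' every pose is unambiguous), a lateral extension flap on the +y side,
#' and small proximal tabs emulating screw rings. All dimensions in mm.
#'
#' @param floor_length plate length along x (default 35).
#' @param width plate width along y (default 25).
#' @param thickness shell thickness (default 0.6).
#' @param dome_height height of the saddle profile (default 4).
#' @param transverse_curvature quadratic droop across y, 1/mm (default 0.01).
#' @param twist xy twist coefficient, 1/mm (default 0.008).
#' @param extension_size lateral extension flap size (default 8).
#' @param n_appendages number of proximal tabs (default 3).
#' @param appendage_size tab length/width (default 3).
#' @param resolution grid step of the generated mesh (default 1).
#' @return A list of class `surrogate_params`.
#' @export
surrogate_params <- function(floor_length = 35, width = 25, thickness = 0.6,
                             dome_height = 4, transverse_curvature = 0.01,
                             twist = 0.008, extension_size = 8,
                             n_appendages = 3, appendage_size = 3,
                             resolution = 1) {
  p <- list(floor_length = floor_length, width = width, thickness = thickness,
            dome_height = dome_height, transverse_curvature = transverse_curvature,
            twist = twist, extension_size = extension_size,
            n_appendages = n_appendages, appendage_size = appendage_size,
            resolution = resolution)
  if (any(unlist(p[c("floor_length", "width", "thickness", "extension_size",
                     "appendage_size", "resolution")]) <= 0)) {
    stop("surrogate_params: dimensions must be positive")
  }
  structure(p, class = "surrogate_params")
}

surrogate_height <- function(p, x, y) {
  xx <- pmin(pmax(x, 0), p$floor_length)
  p$dome_height * sin(pi * xx / p$floor_length) -
    p$transverse_curvature * y^2 + p$twist * xx * y
}

surrogate_halfwidth <- function(p, x) {
  (p$width / 2) * (1 - 0.5 * pmin(pmax(x / p$floor_length, 0), 1)^2)
}

#' Generate the synthetic surrogate implant
#'
#' Builds a watertight thin-shell triangle mesh of the surrogate implant
#' (see [surrogate_params()]) with per-face region labels (`"body"`,
#' `"extension"`, `"appendage"`), and the implant frame defined on it:
#' origin on the reinforced central floor, x-axis towards the dorsal tip,
#' y-axis across the proximal tabs, z upwards. Key points
#' `medial_ledge_top` and `dorsal_tip` are attached to the frame. The
#' construction is fully deterministic.
#'
#' @param params a `surrogate_params` list.
#' @param side `"left"` (canonical) or `"right"` (geometry mirrored over
#'   the xz-plane).
#' @return List with `mesh` (`triangle_mesh`) and `frame`
#'   (`implant_frame`).
#' @export
generate_surrogate <- function(params = surrogate_params(), side = c("left", "right")) {
  side <- match.arg(side)
  p <- params
  res <- p$resolution
  L <- p$floor_length; W <- p$width; E <- p$extension_size
  A <- p$appendage_size
  # cell grid covering appendages (x < 0), body and extension
  x_lo <- -A; x_hi <- L
  y_lo <- -(W / 2); y_hi <- W / 2 + E
  nxc <- max(2L, ceiling((x_hi - x_lo) / res))
  nyc <- max(2L, ceiling((y_hi - y_lo) / res))
  xc <- x_lo + (seq_len(nxc) - 0.5) * res
  yc <- y_lo + (seq_len(nyc) - 0.5) * res
  cx <- matrix(xc, nxc, nyc)
  cy <- matrix(yc, nxc, nyc, byrow = TRUE)
  hw <- surrogate_halfwidth(p, cx)
  body <- cx >= 0 & cx <= L & abs(cy) <= hw
  xe0 <- 0.2 * L
  ext <- cx >= xe0 & cx <= xe0 + E & cy > hw & cy <= W / 2 + E & cy > 0
  app <- matrix(FALSE, nxc, nyc)
  if (p$n_appendages > 0) {
    centers <- seq(-W / 4, W / 4, length.out = max(p$n_appendages, 1))
    for (ctr in centers) {
      app <- app | (cx < 0 & cx >= -A & abs(cy - ctr) <= A / 2)
    }
  }
  region <- matrix(NA_character_, nxc, nyc)
  region[app] <- "appendage"
  region[body] <- "body"
  region[ext] <- "extension"
  domain <- !is.na(region)
  mesh <- shell_mesh_from_cells(domain, region, x_lo, y_lo, res,
                                function(x, y) surrogate_height(p, x, y),
                                p$thickness)
  # frame landmarks (analytic surface positions)
  o <- c(0.3 * L, 0, surrogate_height(p, 0.3 * L, 0))
  xp <- c(L, 0, surrogate_height(p, L, 0))
  yh <- c(0, W / 4, surrogate_height(p, 0, W / 4))
  kp <- list(
    medial_ledge_top = c(0.3 * L, -surrogate_halfwidth(p, 0.3 * L),
                         surrogate_height(p, 0.3 * L, -surrogate_halfwidth(p, 0.3 * L)) +
                           p$thickness / 2),
    dorsal_tip = c(L, 0, surrogate_height(p, L, 0) + p$thickness / 2)
  )
  if (side == "right") {
    mesh <- mirror_mesh_xz(mesh)
    o[2] <- -o[2]; xp[2] <- -xp[2]; yh[2] <- -yh[2]
    kp <- lapply(kp, function(q) { q[2] <- -q[2]; q })
  }
  frame <- frame_from_landmarks(o, xp, yh, side = side, key_points = kp)
  list(mesh = mesh, frame = frame)
}

# Build a watertight prism shell over a boolean cell grid: top and bottom
# surfaces offset +/- thickness/2 from the height field, side walls along
# the domain boundary. Faces are labelled by the cell region.
shell_mesh_from_cells <- function(domain, region, x0, y0, res, zfun, thickness) {
  nxc <- nrow(domain); nyc <- ncol(domain)
  # node (i, j): corner position x0 + (i-1)*res, y0 + (j-1)*res
  node_id <- matrix(0L, nxc + 1, nyc + 1)
  used <- matrix(FALSE, nxc + 1, nyc + 1)
  for (i in seq_len(nxc)) {
    for (j in seq_len(nyc)) {
      if (domain[i, j]) {
        used[i, j] <- TRUE; used[i + 1, j] <- TRUE
        used[i, j + 1] <- TRUE; used[i + 1, j + 1] <- TRUE
      }
    }
  }
  ids <- which(used)
  node_id[ids] <- seq_along(ids)
  nn <- length(ids)
  rc <- arrayInd(ids, dim(used))
  nx_ <- x0 + (rc[, 1] - 1) * res
  ny_ <- y0 + (rc[, 2] - 1) * res
  nz_ <- zfun(nx_, ny_)
  verts <- rbind(cbind(nx_, ny_, nz_ + thickness / 2),
                 cbind(nx_, ny_, nz_ - thickness / 2))
  top <- function(i, j) node_id[i, j]
  bot <- function(i, j) node_id[i, j] + nn
  nmax <- 12L * sum(domain)  # 4 top/bottom + up to 8 wall faces per cell
  faces <- vector("list", nmax)
  fi <- 0L
  flab <- character(nmax)
  add <- function(a, b, c, lab) {
    fi <<- fi + 1L
    faces[[fi]] <<- c(a, b, c)
    flab[fi] <<- lab
  }
  in_dom <- function(i, j) i >= 1 && i <= nxc && j >= 1 && j <= nyc && domain[i, j]
  for (i in seq_len(nxc)) {
    for (j in seq_len(nyc)) {
      if (!domain[i, j]) next
      lab <- region[i, j]
      n00 <- c(i, j); n10 <- c(i + 1, j); n11 <- c(i + 1, j + 1); n01 <- c(i, j + 1)
      # top (outward +z), bottom (outward -z)
      add(top(i, j), top(i + 1, j), top(i + 1, j + 1), lab)
      add(top(i, j), top(i + 1, j + 1), top(i, j + 1), lab)
      add(bot(i, j), bot(i + 1, j + 1), bot(i + 1, j), lab)
      add(bot(i, j), bot(i, j + 1), bot(i + 1, j + 1), lab)
      # walls on boundary edges, CCW top loop: 00->10->11->01->00
      edges <- list(
        list(nb = c(i, j - 1), a = n00, b = n10),
        list(nb = c(i + 1, j), a = n10, b = n11),
        list(nb = c(i, j + 1), a = n11, b = n01),
        list(nb = c(i - 1, j), a = n01, b = n00)
      )
      for (e in edges) {
        if (in_dom(e$nb[1], e$nb[2])) next
        ta <- top(e$a[1], e$a[2]); tb <- top(e$b[1], e$b[2])
        ba <- bot(e$a[1], e$a[2]); bb <- bot(e$b[1], e$b[2])
        add(ta, tb, bb, lab)
        add(ta, bb, ba, lab)
      }
    }
  }
  triangle_mesh(verts, do.call(rbind, faces[seq_len(fi)]), labels = flab[seq_len(fi)],
                weld_tol = 0)
}

# Reflect a mesh over the xz-plane (y -> -y), flipping face winding to
# keep outward orientation.
mirror_mesh_xz <- function(mesh) {
  mesh$vertices[, 2] <- -mesh$vertices[, 2]
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Poses measured on the three cadaver-study specimens
#'
#' The printed placement-deviation parameters of the three specimen
#' reconstructions (angles in degrees, translations in mm), used as
#' ground-truth poses for synthetic validation cases.
#'
#' @param which specimen number, 1-3.
#' @return List with `roll`, `pitch`, `yaw`, `translation`.
#' @export
specimen_pose <- function(which) {
  stopifnot(which %in% 1:3)
  switch(which,
    list(roll = -9.3, pitch = -0.4, yaw = 11.3, translation = c(2.5, -2.7, -0.5)),
    list(roll = -11.2, pitch = -5.3, yaw = 0.1, translation = c(4.1, -2.9, -0.1)),
    list(roll = -1.1, pitch = 1.9, yaw = -7.1, translation = c(-0.3, 0.2, -0.4))
  )
}

#' Build a ground-truth synthetic placement case
#'
#' Constructs a complete evaluation fixture: the reference surrogate with
#' its frame, a planned implant placed in a seeded random "planning scan"
#' pose, and an achieved implant displaced from the plan by exactly the
#' requested pose (expressed in the implant frame, roll-first /
#' pitch-second / yaw-third), optionally perturbed by a hinge bend of the
#' lateral extension, contiguous surface occlusion, and Gaussian vertex
#' noise. The stored true transform reproduces the unperturbed achieved
#' mesh from the planned mesh exactly (verified on construction).
#'
#' @param pose list with `roll`, `pitch`, `yaw` (degrees) and
#'   `translation` (mm), e.g. [specimen_pose()].
#' @param side `"left"` or `"right"`. Right-sided cases are built from
#'   xz-mirrored geometry and their reported parameters follow the
#'   mirrored convention.
#' @param params `surrogate_params()` for the reference geometry.
#' @param noise_sd Gaussian vertex noise on the achieved mesh, mm.
#' @param occlusion_fraction fraction of achieved faces removed as one
#'   contiguous patch, in `[0, 1)`.
#' @param bend_angle hinge-bend angle (degrees) applied to the lateral
#'   extension of the achieved implant, about the extension's attachment
#'   line.
#' @param seed RNG seed driving the planning pose and all perturbations.
#' @return An object of class `oipf_case`: `reference`, `frame`,
#'   `planned`, `achieved` (`triangle_mesh`es), `truth` (pose, side,
#'   world/frame transforms, planning transform) and `perturbations`.
#' @export
make_case <- function(pose, side = c("left", "right"), params = surrogate_params(),
                      noise_sd = 0, occlusion_fraction = 0, bend_angle = 0,
                      seed = 1L) {
  side <- match.arg(side)
  stopifnot(occlusion_fraction >= 0)
  if (occlusion_fraction >= 1) stop("make_case: occlusion_fraction must be < 1")
  sur <- generate_surrogate(params, side = side)
  ref <- sur$mesh; frame <- sur$frame
  T_pose <- transform_from_pose(pose$roll, pose$pitch, pose$yaw, pose$translation)
  T_frame_coords <- if (side == "right") mirror_transform(T_pose) else T_pose
  FM <- frame_matrix(frame)
  m <- FM %*% unclass(T_frame_coords) %*% solve(FM)
  T_world <- rigid_transform(m[1:3, 1:3], m[1:3, 4])
  T_plan <- with_seed(seed, {
    transform_from_pose(stats::runif(1, -20, 20), stats::runif(1, -20, 20),
                        stats::runif(1, -20, 20), stats::runif(3, -25, 25))
  })
  planned <- apply_transform(T_plan, ref)
  T_total <- transform_compose(T_plan, T_world)
  achieved0 <- apply_transform(T_total, ref)
  # self-certification: true transform applied to planned must reproduce
  # the unperturbed achieved geometry
  chk <- apply_transform(transform_compose(
    transform_compose(T_plan, T_world), transform_inverse(T_plan)), planned)
  stopifnot(max(abs(chk$vertices - achieved0$vertices)) < 1e-9)
  achieved <- achieved0
  if (bend_angle != 0) {
    bent_ref <- bend_extension(ref, params, side, bend_angle)
    achieved <- apply_transform(T_total, bent_ref)
  }
  if (occlusion_fraction > 0) {
    achieved <- occlude_patch(achieved, occlusion_fraction, seed + 1L)
  }
  if (noise_sd > 0) {
    achieved$vertices <- achieved$vertices + with_seed(seed + 2L, {
      matrix(stats::rnorm(length(achieved$vertices), sd = noise_sd),
             ncol = 3)
    })
  }
  structure(list(
    reference = ref, frame = frame, planned = planned, achieved = achieved,
    truth = list(pose = pose, side = side,
                 transform_world = transform_compose(
                   transform_compose(T_plan, T_world), transform_inverse(T_plan)),
                 transform_frame = T_pose, planning_transform = T_plan),
    perturbations = list(noise_sd = noise_sd,
                         occlusion_fraction = occlusion_fraction,
                         bend_angle = bend_angle),
    params = params, seed = seed
  ), class = "oipf_case")
}

#' @export
print.oipf_case <- function(x, ...) {
  p <- x$truth$pose
  cat(sprintf("synthetic case (%s side, seed %d): roll %.1f, pitch %.1f, yaw %.1f deg; t = (%.1f, %.1f, %.1f) mm\n",
              x$truth$side, x$seed, p$roll, p$pitch, p$yaw,
              p$translation[1], p$translation[2], p$translation[3]))
  pert <- x$perturbations
  if (pert$noise_sd > 0 || pert$occlusion_fraction > 0 || pert$bend_angle != 0) {
    cat(sprintf("  perturbations: noise %.2f mm, occlusion %.0f%%, bend %.1f deg\n",
                pert$noise_sd, 100 * pert$occlusion_fraction, pert$bend_angle))
  }
  invisible(x)
}

# Rotate extension-labelled vertices about the extension attachment line
# (reference coordinates).
bend_extension <- function(ref, params, side, bend_angle) {
  if (is.null(ref$labels)) return(ref)
  ext_faces <- which(ref$labels == "extension")
  if (!length(ext_faces)) return(ref)
  vids <- unique(as.vector(ref$faces[ext_faces, ]))
  sgn <- if (side == "right") -1 else 1
  y_h <- sgn * min(sgn * ref$vertices[vids, 2])
  xs <- range(ref$vertices[vids, 1])
  ph <- c(mean(xs), y_h, surrogate_height(params, mean(xs), sgn * y_h))
  ang <- sgn * bend_angle * pi / 180
  Rx <- euler_to_rotation(roll = ang, pitch = 0, yaw = 0, degrees = FALSE)
  v <- ref$vertices[vids, , drop = FALSE]
  ref$vertices[vids, ] <- sweep(sweep(v, 2, ph) %*% t(Rx), 2, -ph)
  ref
}

# Remove a contiguous patch of faces covering `fraction` of the mesh.
occlude_patch <- function(mesh, fraction, seed) {
  nf <- nrow(mesh$faces)
  k <- round(fraction * nf)
  if (k < 1) return(mesh)
  cent <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  c0 <- with_seed(seed, cent[sample.int(nf, 1), ])
  d2 <- rowSums(sweep(cent, 2, c0)^2)
  drop <- order(d2)[seq_len(k)]
  mesh$faces <- mesh$faces[-drop, , drop = FALSE]
  if (!is.null(mesh$labels)) mesh$labels <- mesh$labels[-drop]
  mesh
}

#' Voxelize a synthetic case into a CT phantom
#'
#' Builds a calibrated HU phantom around the achieved implant of a
#' [make_case()] fixture: soft-tissue background, an air border, a bony
#' shelf touching the implant from below (exercising the threshold
#' separation between bone and metal), the implant shell itself, and
#' optionally a small detached fixation-screw sphere. The shell is marked
#' on voxels whose centre lies within `max(thickness/2, 0.6 * spacing)` of
#' the achieved surface, i.e. dilated to at least one voxel thickness.
#' Ground-truth voxel labels are returned alongside the volume.
#'
#' @param case an `oipf_case`.
#' @param spacing isotropic voxel spacing, mm (default 0.4, the overlap
#'   increment of the emulated scan protocol; 0.75 emulates the slice
#'   thickness).
#' @param hu named HU levels: `air`, `soft`, `bone`, `implant` (defaults
#'   -1000, 40, 700, 3000).
#' @param noise_sd Gaussian HU noise (default 0).
#' @param include_screw add the detached screw sphere (default `TRUE`).
#' @param dilation dilate the shell to at least one voxel (default
#'   `TRUE`); without it a warning flags spacing larger than the shell
#'   thickness.
#' @param margin background margin around the implant, mm (default 6).
#' @param seed seed for the HU noise.
#' @return An object of class `oipf_phantom`: `volume` (`ct_volume`),
#'   `labels` (integer array: 0 background, 1 implant, 2 bone, 3 screw),
#'   `case`, `spacing`, `hu`.
#' @export
voxelize_phantom <- function(case, spacing = 0.4,
                             hu = c(air = -1000, soft = 40, bone = 700, implant = 3000),
                             noise_sd = 0, include_screw = TRUE, dilation = TRUE,
                             margin = 6, seed = 1L) {
  stopifnot(inherits(case, "oipf_case"), spacing > 0)
  mesh <- case$achieved
  thick <- case$params$thickness
  if (!dilation && spacing > thick) {
    warning(sprintf("voxel spacing %.2f mm exceeds shell thickness %.2f mm without dilation; the shell may not be contiguous", spacing, thick))
  }
  r_mark <- if (dilation) max(thick / 2, 0.55 * spacing) else thick / 2
  lo <- apply(mesh$vertices, 2, min) - margin
  hi <- apply(mesh$vertices, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / spacing), 4)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * spacing)
  labels <- array(0L, dim = dims)
  # bony shelf below the implant, touching it
  z_sh <- min(mesh$vertices[, 3]) + 1.5
  shelf <- ax[[3]] <= z_sh & ax[[3]] >= z_sh - 6
  labels[, , shelf] <- 2L
  # implant shell: voxels within r_mark of a dense surface sampling
  n_dense <- max(20000, ceiling(mesh_area(mesh) / (0.3 * spacing)^2))
  dense <- sample_surface(mesh, n = n_dense, seed = 9001L)$points
  dlo <- apply(mesh$vertices, 2, min) - r_mark - spacing
  dhi <- apply(mesh$vertices, 2, max) + r_mark + spacing
  cand <- lapply(1:3, function(d) which(ax[[d]] >= dlo[d] & ax[[d]] <= dhi[d]))
  grid_idx <- as.matrix(expand.grid(cand[[1]], cand[[2]], cand[[3]]))
  centers <- cbind(ax[[1]][grid_idx[, 1]], ax[[2]][grid_idx[, 2]], ax[[3]][grid_idx[, 3]])
  nn <- cpp_nn(dense, centers)
  inside <- nn$distance <= r_mark
  labels[grid_idx[inside, , drop = FALSE]] <- 1L
  # detached fixation screw near the proximal tabs
  if (include_screw) {
    p <- case$params
    sgn <- if (case$truth$side == "right") -1 else 1
    local <- c(-p$appendage_size - 4, sgn * 0, surrogate_height(p, 0, 0))
    center <- apply_transform(transform_compose(case$truth$planning_transform,
                                                frame_deviation_world(case)), local)
    sid <- which(sqrt(outer((ax[[1]] - center[1])^2,
                            outer((ax[[2]] - center[2])^2, (ax[[3]] - center[3])^2, "+"),
                            "+")) <= 1.2)
    sel <- arrayInd(sid, dims)
    keep <- labels[sel] != 1L
    labels[sel[keep, , drop = FALSE]] <- 3L
  }
  vox <- array(hu[["soft"]], dim = dims)
  vox[labels == 2L] <- hu[["bone"]]
  vox[labels == 1L] <- hu[["implant"]]
  vox[labels == 3L] <- hu[["implant"]]
  # air border
  b <- max(1L, floor(1.5 / spacing))
  vox[c(seq_len(b), dims[1] - seq_len(b) + 1), , ] <- hu[["air"]]
  vox[, c(seq_len(b), dims[2] - seq_len(b) + 1), ] <- hu[["air"]]
  vox[, , c(seq_len(b), dims[3] - seq_len(b) + 1)] <- hu[["air"]]
  labels[vox == hu[["air"]]] <- 0L
  if (noise_sd > 0) {
    vox <- vox + with_seed(seed, array(stats::rnorm(length(vox), sd = noise_sd), dim = dims))
    vox <- pmax(vox, -1024)  # calibrated HU floor
  }
  volume <- ct_volume(vox, spacing = rep(spacing, 3), origin = lo + spacing / 2)
  structure(list(volume = volume, labels = labels, case = case,
                 spacing = spacing, hu = hu),
            class = "oipf_phantom")
}

# world-space deviation transform in planning coordinates is stored in the
# truth; this helper recovers the reference-coordinate deviation so points
# defined on the reference can be carried into the achieved position.
frame_deviation_world <- function(case) {
  FM <- frame_matrix(case$frame)
  Tf <- if (case$truth$side == "right") {
    mirror_transform(case$truth$transform_frame)
  } else {
    case$truth$transform_frame
  }
  m <- FM %*% unclass(Tf) %*% solve(FM)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @export
print.oipf_phantom <- function(x, ...) {
  d <- dim(x$volume$voxels)
  cat(sprintf("CT phantom: %d x %d x %d voxels at %.2f mm; %d implant, %d bone, %d screw voxels\n",
              d[1], d[2], d[3], x$spacing, sum(x$labels == 1L), sum(x$labels == 2L),
              sum(x$labels == 3L)))
  invisible(x)
}
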