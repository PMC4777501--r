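#' Closed-form rigid fit on known correspondences (Kabsch)
#'
#' Finds the rigid transform minimizing the (weighted) sum of squared
#' distances `sum w_i ||R s_i + t - d_i||^2` over proper rotations, via SVD
#' of the cross-covariance with the sign of the smallest singular vector
#' corrected so `det(R) = +1` (never a reflection).
#'
#' @param src,dst corresponding `n x 3` point matrices (n >= 3, not
#'   collinear).
#' @param weights optional non-negative weights of length `n`.
#' @return A `rigid_transform` mapping `src` onto `dst`.
#' @export
kabsch_fit <- function(src, dst, weights = NULL) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3, ncol(dst) == 3, nrow(src) == nrow(dst))
  n <- nrow(src)
  if (n < 3) stop("kabsch_fit: need at least 3 correspondences")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cs <- colSums(src * w)
  cd <- colSums(dst * w)
  s0 <- sweep(src, 2, cs)
  d0 <- sweep(dst, 2, cd)
  H <- t(s0 * w) %*% d0
  sv <- svd(H)
  # rank check: collinear/degenerate sources make the fit non-unique
  if (sv$d[2] < max(sv$d[1], 1e-300) * 1e-9) {
    stop("kabsch_fit: degenerate (collinear) point configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cd - R %*% cs)
}

#' Iterative Closest Point rigid registration
#'
#' Point-to-point ICP: alternate nearest-neighbour correspondence (kd-tree),
#' optional rejection of the worst `trim_fraction` of matches (for partial
#' overlap, e.g. bent or occluded implant regions), and a closed-form
#' [kabsch_fit()] update, until the relative change in trimmed RMS falls
#' below `tol` or `max_iterations` is reached. With a fixed trim count the
#' trimmed RMS objective is non-increasing across iterations.
#'
#' @param source points registered onto the target: an `n x 3` matrix, a
#'   `surface_sample`, or a `triangle_mesh` (sampled with `n_sample`/`seed`).
#' @param target the fixed shape: matrix, `surface_sample` or
#'   `triangle_mesh`.
#' @param init initial alignment: a `rigid_transform`, `"identity"`
#'   (default; inputs are assumed pre-aligned to within the clinical pose
#'   range) or `"centroid"` (translate the source centroid onto the target
#'   centroid first — a cheap cold-start guard when the shapes are far
#'   apart).
#' @param max_iterations maximum number of iterations (default 500;
#'   point-to-point ICP converges linearly and the weakly constrained
#'   tangential components need the tail iterations, so the cap should
#'   only ever stop runaway cases).
#' @param tol relative RMS change convergence threshold (default 1e-6).
#' @param trim_fraction fraction in `[0, 1)` of worst correspondences
#'   discarded each iteration (default 0, full overlap).
#' @param n_sample points to sample when a mesh is supplied (default 20000).
#' @param seed seed for mesh sampling.
#' @return An object of class `icp_result`: list with `transform`
#'   (cumulative source-to-target `rigid_transform`), `rms` (final trimmed
#'   RMS residual, mm), `iterations`, `converged` and `residual_history`.
#' @export
icp_register <- function(source, target, init = "identity",
                         max_iterations = 500, tol = 1e-6,
                         trim_fraction = 0, n_sample = 20000, seed = 1L) {
  stopifnot(max_iterations >= 1, trim_fraction >= 0, trim_fraction < 1)
  src <- registration_points(source, n_sample, seed)
  dst <- registration_points(target, n_sample, seed + 1L)
  if (nrow(src) == 0 || nrow(dst) == 0) stop("icp_register: empty point set")
  keep_n <- max(3L, ceiling((1 - trim_fraction) * nrow(src)))
  if (is.character(init)) {
    init <- match.arg(init, c("identity", "centroid", "principal"))
    init <- switch(init,
      identity = rigid_transform(),
      centroid = rigid_transform(diag(3), colMeans(dst) - colMeans(src)),
      principal = principal_axes_init(src, dst))
  }
  T_cur <- as_rigid_transform(init)
  p <- apply_transform(T_cur, src)
  history <- numeric(0)
  rms_prev <- Inf
  converged <- FALSE
  iters <- 0L
  warm <- NULL
  for (it in seq_len(max_iterations)) {
    iters <- it
    nn <- cpp_nn(dst, p, warm)
    warm <- nn$index
    ord <- order(nn$distance)[seq_len(keep_n)]
    if (length(ord) == 0) stop("icp_register: no correspondences after trimming")
    step <- kabsch_fit(p[ord, , drop = FALSE], dst[nn$index[ord], , drop = FALSE])
    T_cur <- transform_compose(step, T_cur)
    p <- apply_transform(T_cur, src)
    # trimmed RMS under the updated pose, against the same correspondences
    d2 <- rowSums((p[ord, , drop = FALSE] - dst[nn$index[ord], , drop = FALSE])^2)
    rms <- sqrt(mean(d2))
    history <- c(history, rms)
    if (rms < 1e-10) {  # numerically exact fit
      converged <- TRUE
      break
    }
    if (is.finite(rms_prev)) {
      if (abs(rms_prev - rms) <= tol * max(rms_prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    rms_prev <- rms
  }
  structure(list(transform = T_cur, rms = history[length(history)],
                 iterations = iters, converged = converged,
                 residual_history = history),
            class = "icp_result")
}

# Cold-start pose estimate from centroids + inertia (covariance) axes.
# The four proper sign combinations of the eigenvector pairing are
# disambiguated by the nearest-neighbour RMS of a source subsample.
principal_axes_init <- function(src, dst, n_check = 1000L) {
  cs <- colMeans(src); cd <- colMeans(dst)
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  ed <- eigen(stats::cov(dst), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(ed) < 0) ed[, 3] <- -ed[, 3]
  sub <- src[seq(1, nrow(src), length.out = min(n_check, nrow(src))), , drop = FALSE]
  best <- NULL; best_rms <- Inf
  for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R <- ed %*% diag(s) %*% t(es)
    tr <- cd - R %*% cs
    p <- sweep(sub %*% t(R), 2, -as.numeric(tr))
    rms <- sqrt(mean(cpp_nn(dst, p)$distance^2))
    if (rms < best_rms) { best_rms <- rms; best <- rigid_transform(R, tr) }
  }
  best
}

registration_points <- function(x, n_sample, seed) {
  if (inherits(x, "surface_sample")) return(x$points)
  if (inherits(x, "triangle_mesh")) return(sample_surface(x, n = n_sample, seed = seed)$points)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  if (!all(is.finite(x))) stop("registration: non-finite coordinates")
  x
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("ICP: rms %.5f mm after %d iteration%s (%s)\n",
              x$rms, x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "converged" else "not converged"))
  p <- decompose_transform(x$transform)
  cat(sprintf("  roll %.3f deg, pitch %.3f deg, yaw %.3f deg, t = (%.3f, %.3f, %.3f) mm\n",
              p$roll, p$pitch, p$yaw, p$translation[1], p$translation[2], p$translation[3]))
  invisible(x)
}

#' Residual history of an ICP run
#'
#' Convenience plot of the trimmed RMS residual per iteration.
#'
#' @param x an `icp_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.icp_result <- function(x, ...) {
  graphics::plot(seq_along(x$residual_history), x$residual_history,
                 type = "b", xlab = "iteration", ylab = "trimmed RMS residual (mm)", ...)
  invisible(x)
}
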