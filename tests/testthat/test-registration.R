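test_that("kabsch_fit recovers exact correspondences and rejects degeneracy", {
  set.seed(31)
  src <- matrix(stats::runif(30, -20, 20), ncol = 3)
  # identity on src = dst
  T0 <- kabsch_fit(src, src)
  expect_lt(max(abs(unclass(T0) - diag(4))), 1e-12)
  # exact recovery of a known transform
  for (i in 1:10) {
    Tt <- transform_from_pose(stats::runif(1, -170, 170), stats::runif(1, -85, 85),
                              stats::runif(1, -170, 170), stats::rnorm(3, sd = 8))
    fit <- kabsch_fit(src, apply_transform(Tt, src))
    expect_lt(max(abs(unclass(fit) - unclass(Tt))), 1e-9)
  }
  # collinear configuration
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_fit(line, line + 1), "degenerate|collinear")
  expect_error(kabsch_fit(src[1:2, ], src[1:2, ]), "at least 3")
})

test_that("kabsch_fit returns a proper rotation even for mirrored correspondences", {
  set.seed(5)
  src <- matrix(stats::rnorm(24, sd = 10), ncol = 3)
  dst <- src %*% diag(c(1, -1, 1))  # reflection, not attainable rigidly
  fit <- kabsch_fit(src, dst)
  R <- unclass(fit)[1:3, 1:3]
  expect_equal(det(R), 1, tolerance = 1e-9)
  resid <- apply_transform(fit, src) - dst
  expect_gt(sqrt(mean(resid^2)), 0.1)
})

test_that("kabsch_fit matches a coarse brute-force pose search on 5-point instances", {
  # oracle: exhaustive grid over euler angles; translation closed-form per
  # rotation (centroid match is optimal for fixed R)
  objective <- function(R, src, dst) {
    tr <- colMeans(dst) - as.numeric(R %*% colMeans(src))
    sum((sweep(src %*% t(R), 2, -tr) - dst)^2)
  }
  grid <- seq(-12, 12, by = 3)
  set.seed(8)
  for (rep in 1:3) {
    src <- matrix(stats::runif(15, -15, 15), ncol = 3)
    Tt <- transform_from_pose(stats::runif(1, -10, 10), stats::runif(1, -10, 10),
                              stats::runif(1, -10, 10), stats::rnorm(3))
    dst <- apply_transform(Tt, src)
    best <- Inf; best_ang <- NULL
    for (r in grid) for (p in grid) for (y in grid) {
      o <- objective(euler_to_rotation(r, p, y), src, dst)
      if (o < best) { best <- o; best_ang <- c(r, p, y) }
    }
    fit <- kabsch_fit(src, dst)
    d <- decompose_transform(fit)
    # closed form is at least as good as the best grid point, and the grid
    # argmin lies within one grid step of it
    expect_lte(objective(unclass(fit)[1:3, 1:3], src, dst), best + 1e-12)
    expect_lt(max(abs(c(d$roll, d$pitch, d$yaw) - best_ang)), 3 + 1e-9)
    # noise-free recovery is exact
    expect_lt(max(abs(unclass(fit) - unclass(Tt))), 1e-9)
  }
})

test_that("ICP on identical point sets stops immediately at zero residual", {
  set.seed(2)
  pts <- matrix(stats::runif(900, -10, 10), ncol = 3)
  res <- icp_register(pts, pts)
  expect_equal(res$iterations, 1)
  expect_equal(res$rms, 0)
  expect_true(res$converged)
  expect_lt(max(abs(unclass(res$transform) - diag(4))), 1e-12)
})

test_that("ICP recovers the specimen-1 displacement on surrogate samplings", {
  sur <- small_surrogate()$mesh
  true <- specimen_pose(1)
  Tt <- transform_from_pose(true$roll, true$pitch, true$yaw, true$translation)
  src <- sample_surface(sur, n = 8000, seed = 1)
  dst <- sample_surface(apply_transform(Tt, sur), n = 16000, seed = 2)
  res <- icp_register(src, dst)
  d <- decompose_transform(res$transform)
  expect_lt(max(abs(c(d$roll - true$roll, d$pitch - true$pitch, d$yaw - true$yaw))), 0.5)
  expect_lt(max(abs(d$translation - true$translation)), 0.2)
  expect_true(res$converged)
})

test_that("registration survives deletion of 30% of the source surface", {
  sur <- generate_surrogate()$mesh
  true <- specimen_pose(1)
  Tt <- transform_from_pose(true$roll, true$pitch, true$yaw, true$translation)
  src <- sample_surface(sur, n = 8000, seed = 3)
  # delete a contiguous 30% patch of source points (screw-ring exclusion)
  c0 <- src$points[17, ]
  d2 <- rowSums(sweep(src$points, 2, c0)^2)
  keep <- order(d2, decreasing = TRUE)[seq_len(round(0.7 * nrow(src$points)))]
  src$points <- src$points[keep, , drop = FALSE]
  dst <- sample_surface(apply_transform(Tt, sur), n = 16000, seed = 4)
  # every remaining source point has a true match, so untrimmed ICP from a
  # cold start recovers the pose
  res0 <- icp_register(src, dst)
  d0 <- decompose_transform(res0$transform)
  expect_lt(max(abs(c(d0$roll - true$roll, d0$pitch - true$pitch, d0$yaw - true$yaw))), 1.0)
  expect_lt(max(abs(d0$translation - true$translation)), 0.5)
  # trimmed refinement of a coarse prior alignment (within ~2 degrees, as
  # the chained pipeline provides) stays anchored at the true pose; on this
  # tangentially weak shell trimming needs that prior — from a cold start
  # the trimmed objective admits displaced minima
  prior <- transform_compose(transform_from_pose(2, -2, 2, c(0.6, -0.6, 0.4)), Tt)
  rest <- icp_register(src, dst, trim_fraction = 0.2, init = prior)
  dt <- decompose_transform(rest$transform)
  expect_lt(max(abs(c(dt$roll - true$roll, dt$pitch - true$pitch, dt$yaw - true$yaw))), 1.0)
  expect_lt(max(abs(dt$translation - true$translation)), 0.5)
})

test_that("the trimmed RMS objective is non-increasing across iterations", {
  sur <- small_surrogate()$mesh
  Tt <- transform_from_pose(8, -5, 10, c(3, -2, 1))
  src <- sample_surface(sur, n = 4000, seed = 5)
  dst <- sample_surface(apply_transform(Tt, sur), n = 8000, seed = 6)
  for (tf in c(0, 0.15)) {
    res <- icp_register(src, dst, trim_fraction = tf)
    h <- res$residual_history
    expect_true(all(diff(h) <= 1e-9))
  }
})

test_that("ICP is equivariant under a common rigid motion of both shapes", {
  sur <- small_surrogate()$mesh
  Tt <- transform_from_pose(6, 3, -9, c(2, 1, -3))
  src <- sample_surface(sur, n = 4000, seed = 7)
  dst <- sample_surface(apply_transform(Tt, sur), n = 8000, seed = 8)
  base <- icp_register(src, dst)
  W <- transform_from_pose(30, -20, 45, c(15, -8, 22))
  moved <- icp_register(apply_transform(W, src), apply_transform(W, dst))
  conj <- transform_compose(W, transform_compose(base$transform, transform_inverse(W)))
  expect_lt(max(abs(unclass(moved$transform) - unclass(conj))), 5e-3)
})

test_that("principal-axes initialization lands near the true pose", {
  sur <- small_surrogate()$mesh
  Tt <- transform_from_pose(12, -8, 14, c(4, -3, 5))
  src <- sample_surface(sur, n = 4000, seed = 9)$points
  dst <- apply_transform(Tt, sample_surface(sur, n = 4000, seed = 10))$points
  init <- oipf:::principal_axes_init(src, dst)
  d <- decompose_transform(transform_compose(transform_inverse(Tt), init))
  expect_lt(max(abs(c(d$roll, d$pitch, d$yaw))), 5)
  expect_lt(max(abs(d$translation)), 2)
})
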