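# Shared fixtures and independent oracles for the test suite.

# random proper rotation via unit quaternion (independent of the package's
# Euler composition)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# unit cube ASCII STL text (12 triangles, un-welded corner coordinates)
cube_ascii_stl <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tri <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # x = 0 / x = 1 handled by index sets below
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6)
  )
  lines <- c("solid cube")
  for (i in seq_len(nrow(tri))) {
    p <- v[tri[i, ], , drop = FALSE]
    lines <- c(lines,
               "  facet normal 0 0 0",
               "    outer loop",
               sprintf("      vertex %g %g %g", p[1, 1], p[1, 2], p[1, 3]),
               sprintf("      vertex %g %g %g", p[2, 1], p[2, 2], p[2, 3]),
               sprintf("      vertex %g %g %g", p[3, 1], p[3, 2], p[3, 3]),
               "    endloop",
               "  endfacet")
  }
  c(lines, "endsolid cube")
}

# small surrogate for fast registration tests
small_surrogate <- function(side = "left") {
  generate_surrogate(surrogate_params(resolution = 1.5), side = side)
}

# maximum absolute angular difference (degrees) and translation difference
# (mm) between a recovered pose and a true pose list
pose_error <- function(pose, true) {
  c(angle = max(abs(c(pose$roll - true$roll, pose$pitch - true$pitch,
                      pose$yaw - true$yaw))),
    trans = max(abs(pose$translation - true$translation)))
}
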