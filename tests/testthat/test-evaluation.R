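test_that("frame_from_landmarks builds the canonical frame and is equivariant", {
  fr <- frame_from_landmarks(c(0, 0, 0), c(10, 0, 0), c(0, 5, 0), side = "left")
  expect_equal(fr$x_axis, c(1, 0, 0))
  expect_equal(fr$y_axis, c(0, 1, 0))
  expect_equal(fr$z_axis, c(0, 0, 1))
  # equivariance: transformed landmarks give transformed axes
  Tt <- transform_from_pose(20, -10, 35, c(5, -2, 7))
  R <- unclass(Tt)[1:3, 1:3]
  fr2 <- frame_from_landmarks(apply_transform(Tt, c(0, 0, 0)),
                              apply_transform(Tt, c(10, 0, 0)),
                              apply_transform(Tt, c(0, 5, 0)),
                              side = "left", up = as.numeric(R %*% c(0, 0, 1)))
  expect_equal(fr2$x_axis, as.numeric(R %*% c(1, 0, 0)), tolerance = 1e-12)
  expect_equal(fr2$y_axis, as.numeric(R %*% c(0, 1, 0)), tolerance = 1e-12)
  expect_equal(fr2$z_axis, as.numeric(R %*% c(0, 0, 1)), tolerance = 1e-12)
  # collinear landmarks are rejected
  expect_error(frame_from_landmarks(c(0, 0, 0), c(10, 0, 0), c(5, 0, 0)),
               "collinear|degenerate")
  expect_error(implant_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
               "right-handed")
})

test_that("mirroring a right frame is an involution restricted to right sides", {
  sur <- small_surrogate(side = "right")
  fr <- sur$frame
  m1 <- mirror_for_right_side(fr)
  expect_equal(m1$y_axis, -fr$y_axis)
  expect_true(m1$mirrored)
  m2 <- mirror_for_right_side(m1)
  expect_equal(m2[names(m2) != "mirrored"], fr[names(fr) != "mirrored"])
  expect_false(m2$mirrored)
  left <- small_surrogate(side = "left")$frame
  expect_error(mirror_for_right_side(left), "not right-sided")
})

test_that("keypoint displacements follow the closed forms", {
  fr <- frame_from_landmarks(c(0, 0, 0), c(10, 0, 0), c(0, 5, 0), side = "left",
                             key_points = list(dorsal_tip = c(30, 0, 0),
                                               medial_ledge_top = c(8, -6, 1)))
  expect_equal(keypoint_displacement(rigid_transform(), fr)$dorsal_tip,
               c(x = 0, y = 0, z = 0))
  tr <- rigid_transform(diag(3), c(1.5, -2, 0.5))
  kd <- keypoint_displacement(tr, fr)
  expect_equal(kd$dorsal_tip, c(x = 1.5, y = -2, z = 0.5))
  expect_equal(kd$medial_ledge_top, c(x = 1.5, y = -2, z = 0.5))
  # pure 10 degree yaw about the origin: tip at (30,0,0) moves along a
  # chord of length 2 * 30 * sin(5 deg)
  yaw10 <- transform_from_pose(yaw = 10)
  d <- keypoint_displacement(yaw10, fr)$dorsal_tip
  expect_equal(sqrt(sum(d^2)), 2 * 30 * sin(5 * pi / 180), tolerance = 1e-12)
  # a frame without key points reports an empty list
  fr0 <- frame_from_landmarks(c(0, 0, 0), c(10, 0, 0), c(0, 5, 0))
  expect_length(keypoint_displacement(yaw10, fr0), 0)
})

test_that("align_to_reference recovers a known displacement and warns on mismatch", {
  sur <- small_surrogate()
  # same-shape alignment from a cold start: planned equals the reference
  # under a known rigid motion; the sample itself is noise-free
  ref_s <- sample_surface(sur$mesh, n = 8000, seed = 2)
  Tt <- transform_from_pose(7, 12, -9, c(10, -15, 6))
  moved <- ref_s$points[sample(nrow(ref_s$points)), ]
  res <- align_to_reference(apply_transform(Tt, moved), ref_s, init = "principal")
  err <- decompose_transform(transform_compose(Tt, res$transform))
  expect_lt(max(abs(c(err$roll, err$pitch, err$yaw))), 0.1)
  expect_lt(max(abs(err$translation)), 0.05)
  expect_lt(res$rms, 0.01)
  # mismatched shape (different implant size) trips the heuristic warning
  big <- generate_surrogate(surrogate_params(floor_length = 45, width = 32,
                                             resolution = 1.5))$mesh
  expect_warning(
    align_to_reference(sample_surface(big, n = 4000, seed = 5),
                       sample_surface(sur$mesh, n = 6000, seed = 6),
                       init = "principal"),
    "different implant shapes|exceeds")
})

test_that("evaluate_placement reports near-zero pose when achieved equals planned", {
  sur <- small_surrogate()
  case <- make_case(list(roll = 0, pitch = 0, yaw = 0, translation = c(0, 0, 0)),
                    seed = 3)
  rep <- evaluate_placement(case$planned, case$planned, case$reference, case$frame,
                            n_sample = 20000, seed = 2)
  expect_lt(max(abs(c(rep$pose$roll, rep$pose$pitch, rep$pose$yaw))), 0.05)
  expect_lt(max(abs(rep$pose$translation)), 0.02)
})

test_that("pose parameters are invariant to a common translation of both meshes", {
  case <- make_case(specimen_pose(3), seed = 9,
                    params = surrogate_params(resolution = 1.5))
  r1 <- evaluate_placement(case$planned, case$achieved, case$reference, case$frame,
                           n_sample = 5000, seed = 2)
  shift <- rigid_transform(diag(3), c(12, -7, 31))
  r2 <- evaluate_placement(apply_transform(shift, case$planned),
                           apply_transform(shift, case$achieved),
                           case$reference, case$frame, n_sample = 5000, seed = 2)
  expect_equal(c(r2$pose$roll, r2$pose$pitch, r2$pose$yaw),
               c(r1$pose$roll, r1$pose$pitch, r1$pose$yaw), tolerance = 1e-4)
  expect_equal(r2$pose$translation, r1$pose$translation, tolerance = 1e-4)
})

test_that("the decomposition audit reconstructs the deviation matrix", {
  case <- make_case(specimen_pose(2), seed = 4,
                    params = surrogate_params(resolution = 1.5))
  rep <- evaluate_placement(case$planned, case$achieved, case$reference, case$frame,
                            n_sample = 5000, seed = 2)
  # rebuild T_0->2 from the six reported parameters via the frame
  Tf <- transform_from_pose(rep$pose$roll, rep$pose$pitch, rep$pose$yaw,
                            rep$pose$translation)
  G <- oipf:::reporting_frame_matrix(case$frame)
  rebuilt <- G %*% unclass(Tf) %*% solve(G)
  expect_lt(max(abs(rebuilt - unclass(rep$transform))), 1e-9)
  # key-point displacements are consistent with the transform
  kd <- rep$pose$key_point_displacements
  expect_equal(kd, keypoint_displacement(rep$transform, case$frame), tolerance = 1e-12)
})

test_that("reports are reproducible, serializable and carry provenance", {
  case <- make_case(specimen_pose(3), seed = 10,
                    params = surrogate_params(resolution = 1.5))
  r1 <- evaluate_placement(case$planned, case$achieved, case$reference, case$frame,
                           n_sample = 4000, seed = 6, id = "spec3")
  r2 <- evaluate_placement(case$planned, case$achieved, case$reference, case$frame,
                           n_sample = 4000, seed = 6, id = "spec3")
  expect_identical(r1$pose, r2$pose)
  expect_identical(unclass(r1$transform), unclass(r2$transform))
  dir <- withr::local_tempdir()
  write_report(r1, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  csv <- utils::read.csv(file.path(dir, "report.csv"))
  expect_identical(names(csv), c("id", "roll", "pitch", "yaw", "t_x", "t_y", "t_z"))
  expect_equal(csv$roll, r1$pose$roll)
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(js$pose$side, "left")
  expect_length(js$transform, 16)
  expect_equal(js$provenance$seed, 6)
})

test_that("side mismatches and stage failures are reported with stage tags", {
  case <- make_case(specimen_pose(1), seed = 2,
                    params = surrogate_params(resolution = 1.5))
  expect_error(
    evaluate_placement(case$planned, case$achieved, case$reference, case$frame,
                       side = "right"),
    "side")
  # an unusable planned input fails in the alignment stage with its tag
  expect_error(
    evaluate_placement(matrix(0, 2, 3), case$achieved, case$reference, case$frame,
                       n_sample = 1000, seed = 1),
    "\\[alignment\\]")
})

test_that("frames serialize to JSON and back", {
  fr <- small_surrogate()$frame
  f <- withr::local_tempfile(fileext = ".json")
  frame_to_json(fr, f)
  back <- frame_from_json(f)
  expect_equal(back$origin, fr$origin, tolerance = 1e-12)
  expect_equal(back$x_axis, fr$x_axis, tolerance = 1e-12)
  expect_equal(back$key_points, fr$key_points, tolerance = 1e-12)
  expect_equal(back$side, fr$side)
})
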