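# small phantom shared across segmentation tests (coarse surrogate keeps
# voxel counts low)
local_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) {
      case <- make_case(specimen_pose(3), seed = 2,
                        params = surrogate_params(resolution = 1.5))
      ph <<- voxelize_phantom(case, spacing = 0.75)
    }
    ph
  }
})

test_that("threshold >= 1200 HU recovers exactly the metal voxel set of a phantom", {
  ph <- local_phantom()
  mask <- threshold_segment(ph$volume, 1200)
  expect_identical(unname(mask$mask), unname(ph$labels == 1L | ph$labels == 3L))
  expect_equal(mask$provenance$threshold, 1200)
})

test_that("threshold semantics are inclusive and empty results warn", {
  vox <- array(c(1199.999, 1200, 1200.001, -1000), c(4, 1, 1))
  vol <- ct_volume(array(vox, c(4, 1, 1)), spacing = c(1, 1, 1))
  m <- suppressWarnings(threshold_segment(vol, 1200))
  expect_identical(as.vector(m$mask), c(FALSE, TRUE, TRUE, FALSE))
  air <- ct_volume(array(-1000, c(3, 3, 3)), spacing = c(1, 1, 1))
  expect_warning(m0 <- threshold_segment(air, 1200), "no voxels")
  expect_false(any(m0$mask))
  expect_error(filter_components(m0), "empty")
  expect_error(mask_to_mesh(m0), "empty")
})

test_that("thresholding is monotone in the threshold", {
  ph <- local_phantom()
  m1 <- threshold_segment(ph$volume, 600)
  m2 <- threshold_segment(ph$volume, 1200)
  expect_true(all(m2$mask <= m1$mask))
  expect_true(suppressWarnings(all(threshold_segment(ph$volume, 3500)$mask <= m2$mask)))
  expect_gt(sum(m1$mask), sum(m2$mask))  # bone crosses 600 but not 1200
})

test_that("component filtering drops the detached screw and is idempotent", {
  ph <- local_phantom()
  mask <- threshold_segment(ph$volume, 1200)
  expect_gt(sum(ph$labels == 3L), 0)  # screw present in the fixture
  largest <- filter_components(mask, keep = "largest")
  expect_identical(unname(largest$mask), unname(ph$labels == 1L))
  # all-above with a small cutoff keeps both; with a large one keeps implant
  both <- filter_components(mask, min_voxels = 1L, keep = "all_above")
  expect_identical(unname(both$mask), unname(mask$mask))
  big <- filter_components(mask, min_voxels = sum(ph$labels == 3L) + 1L,
                           keep = "all_above")
  expect_identical(unname(big$mask), unname(ph$labels == 1L))
  # idempotence
  again <- filter_components(big, min_voxels = sum(ph$labels == 3L) + 1L,
                             keep = "all_above")
  expect_identical(again$mask, big$mask)
  expect_gte(big$provenance$components_removed, 1)
})

test_that("26-connectivity joins diagonal voxels into one component", {
  vox <- array(-1000, c(4, 4, 4))
  vox[1, 1, 1] <- 3000
  vox[2, 2, 2] <- 3000  # diagonal neighbour
  vox[4, 4, 4] <- 3000  # detached
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  lab <- oipf:::cpp_label26(as.logical(vol$voxels >= 1200), c(4L, 4L, 4L))
  expect_equal(max(lab), 2)
})

test_that("world-space exclusion regions clear voxels and validate input", {
  ph <- local_phantom()
  mask <- filter_components(threshold_segment(ph$volume, 1200), keep = "largest")
  expect_identical(apply_exclusion(mask, list())$mask, mask$mask)
  # a sphere around an implant-voxel world position clears it
  idx <- which(mask$mask, arr.ind = TRUE)[1, , drop = FALSE]
  w <- oipf:::voxel_to_world(ph$volume, idx)
  sph <- list(list(type = "sphere", center = as.numeric(w), radius = 1.0))
  cleared <- apply_exclusion(mask, sph)
  expect_false(cleared$mask[idx])
  expect_lt(sum(cleared$mask), sum(mask$mask))
  expect_length(cleared$provenance$exclusions, 1)
  # box covering everything empties the mask
  lo <- apply(oipf:::voxel_to_world(ph$volume, which(mask$mask, arr.ind = TRUE)), 2, min)
  hi <- apply(oipf:::voxel_to_world(ph$volume, which(mask$mask, arr.ind = TRUE)), 2, max)
  all_gone <- apply_exclusion(mask, list(list(type = "box", min = lo - 1, max = hi + 1)))
  expect_false(any(all_gone$mask))
  expect_error(mask_to_mesh(all_gone), "empty")
  expect_error(apply_exclusion(mask, list(list(type = "cone"))), "unknown region")
  expect_error(apply_exclusion(mask, list(list(type = "sphere", center = 1, radius = 2))),
               "center")
})

test_that("mask_to_mesh encloses a single voxel with its exact voxel volume", {
  vox <- array(-1000, c(5, 5, 5)); vox[3, 3, 3] <- 3000
  vol <- ct_volume(vox, spacing = c(1, 1, 1), origin = c(10, 20, 30))
  mesh <- mask_to_mesh(threshold_segment(vol, 1200))
  expect_equal(mesh_volume(mesh), 1, tolerance = 0.15)
  # centred on the voxel's world position
  expect_equal(colMeans(mesh$vertices), c(10 + 2, 20 + 2, 30 + 2), tolerance = 0.2,
               ignore_attr = TRUE)
})

test_that("mask_to_mesh reproduces a sphere's area within 5%", {
  sp <- 0.5
  n <- as.integer(26 / sp)
  ax <- (seq_len(n) - 0.5) * sp - 13
  d <- sqrt(outer(ax^2, outer(ax^2, ax^2, "+"), "+"))
  vox <- array(-1000, c(n, n, n)); vox[d <= 10] <- 3000
  vol <- ct_volume(vox, spacing = rep(sp, 3))
  mesh <- mask_to_mesh(threshold_segment(vol, 1200))
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("the phantom implant surface is within a voxel diagonal of ground truth", {
  ph <- local_phantom()
  seg <- segment_implant(ph$volume)
  truth_mesh <- ph$case$achieved
  a <- sample_surface(seg$mesh, n = 4000, seed = 1)$points
  b <- sample_surface(truth_mesh, n = 4000, seed = 2)$points
  h_ab <- max(oipf:::cpp_nn(b, a)$distance)
  h_ba <- max(oipf:::cpp_nn(a, b)$distance)
  expect_lt(max(h_ab, h_ba), ph$spacing * sqrt(3))
})

test_that("a fusion transform hook moves the extracted mesh", {
  vox <- array(-1000, c(5, 5, 5)); vox[3, 3, 3] <- 3000
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  tr <- rigid_transform(diag(3), c(5, 0, 0))
  m0 <- mask_to_mesh(threshold_segment(vol, 1200))
  m1 <- mask_to_mesh(threshold_segment(vol, 1200), fusion_transform = tr)
  expect_equal(m1$vertices, sweep(m0$vertices, 2, c(-5, 0, 0)))
})

test_that("NIfTI write/read round trips voxels and geometry", {
  ph <- local_phantom()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(ph$volume, f)
  back <- read_nifti_volume(f)
  expect_equal(back$voxels, ph$volume$voxels, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-6)
  expect_equal(back$origin, ph$volume$origin, tolerance = 1e-5)
  # mask round trip preserves the voxel set
  mask <- filter_components(threshold_segment(ph$volume, 1200), keep = "largest")
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(mask, fm)
  mb <- read_nifti_volume(fm)
  expect_identical(unname(mb$voxels == 1), unname(mask$mask))
  expect_error(read_nifti_volume(file.path(tempdir(), "nope.nii")), "not found")
})
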