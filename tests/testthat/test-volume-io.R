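test_that("NIfTI and raw-text volumes round-trip losslessly", {
  vol <- fix$gen$volume
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, modality = vol$modality, origin = vol$origin)
  expect_equal(max(abs(back$voxels - vol$voxels)), 0)
  # NIfTI stores pixdim as float32
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)

  small <- image_volume(array(rnorm(60), c(3, 4, 5)), c(0.7, 0.4, 0.4),
                        "MRI_T1VIBE", origin = c(1, 2, 3))
  g <- withr::local_tempfile(fileext = ".txt.gz")
  write_volume(small, g, format = "npz-raw")
  back2 <- read_volume(g, format = "npz-raw", modality = "MRI_T1VIBE")
  expect_equal(back2$voxels, small$voxels, tolerance = 1e-12)
  expect_equal(back2$origin, small$origin)
})

test_that("malformed volumes are rejected", {
  expect_error(read_volume(tempfile()), "not found")
  # 4D data
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3D")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(image_volume(array(c(NA, rep(0, 7)), c(2, 2, 2)), c(1, 1, 1)),
               "finite")
})

test_that("cropping preserves spacing and mm coordinates", {
  vol <- image_volume(array(seq_len(1000), c(10, 10, 10)),
                      c(0.7, 0.4, 0.4), origin = c(1, -2, 3))
  full <- crop_volume(vol, crop_region(1, 10, 1, 10, 1, 10))
  expect_identical(full$voxels, vol$voxels)
  expect_equal(full$origin, vol$origin)

  sub <- crop_volume(vol, crop_region(2, 4, 3, 8, 5, 9))
  expect_equal(dim(sub$voxels), c(3L, 6L, 5L))
  expect_equal(sub$spacing, vol$spacing)
  # same voxel, same physical point
  expect_equal(voxel_to_mm(sub, 1, 1, 1), voxel_to_mm(vol, 2, 3, 5))
  expect_equal(voxel_to_mm(sub, 2, 4, 3), voxel_to_mm(vol, 3, 6, 7))
  expect_error(crop_volume(vol, crop_region(2, 11, 1, 5, 1, 5)), "exceeds")
})

test_that("voxel-to-mm mapping follows the fixed axis convention", {
  vol <- image_volume(array(0, c(5, 6, 7)), c(0.7, 0.4, 0.4))
  expect_equal(as.numeric(voxel_to_mm(vol, 1, 1, 1)), c(0, 0, 0))
  # slice 2, row 3, col 4 -> x = 2*0.4, y = 3*0.4, z = 1*0.7
  expect_equal(as.numeric(voxel_to_mm(vol, 2, 3, 4)), c(0.8, 1.2, 0.7))
  # x strictly increases with row
  xs <- voxel_to_mm(vol, rep(1, 6), 1:6, rep(1, 6))[, "x"]
  expect_true(all(diff(xs) > 0))
  expect_error(voxel_to_mm(vol, 6, 1, 1), "out of range")
})

test_that("XYZ and PLY geometry files round-trip", {
  pts <- matrix(rnorm(30), ncol = 3)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(pts, f)
  expect_equal(unname(read_xyz(f)), pts, tolerance = 1e-12)

  mesh <- plane_mesh()
  for (bin in c(TRUE, FALSE)) {
    g <- withr::local_tempfile(fileext = ".ply")
    write_ply(mesh, g, binary = bin)
    back <- read_ply(g)
    expect_equal(unname(back$vertices), unname(mesh$vertices),
                 tolerance = 1e-6)
    expect_identical(back$faces, mesh$faces)
  }
})
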