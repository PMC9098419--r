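test_that("noiseless rendering equals nominal tissue intensities", {
  gen <- fix$gen0
  ints <- small_spec()$profiles$MRI_T1VIBE$intensities
  expect_true(all(gen$volume$voxels[gen$truth$bone_mask] == ints[["bone"]]))
  expect_true(all(gen$volume$voxels[gen$truth$cartilage_mask] ==
                    ints[["cartilage"]]))
  bg <- !(gen$truth$bone_mask | gen$truth$cartilage_mask)
  expect_true(all(gen$volume$voxels[bg] == ints[["background"]]))
})

test_that("generation is deterministic and masks are noise-invariant", {
  a <- generate_phantom(small_spec(seed = 3L), "MRI_T1VIBE")
  b <- generate_phantom(small_spec(seed = 3L), "MRI_T1VIBE")
  expect_identical(a$volume$voxels, b$volume$voxels)
  # different seed or noise level: intensities change, truth does not
  c1 <- generate_phantom(small_spec(seed = 4L), "MRI_T1VIBE")
  expect_false(identical(a$volume$voxels, c1$volume$voxels))
  expect_identical(a$truth, c1$truth)
  loud <- small_spec(seed = 3L)
  loud$profiles$MRI_T1VIBE$noise_sd <- 20
  c2 <- generate_phantom(loud, "MRI_T1VIBE")
  expect_identical(a$truth, c2$truth)
  expect_error(generate_phantom(small_spec(), "SPECT"), "unknown modality")
})

test_that("rasterized bone volume matches the analytic superellipsoid", {
  # numerical-integration oracle for the superellipsoid volume
  sa <- small_spec()$bone_semiaxes
  e <- small_spec()$exponent
  f <- function(u, v) pmax(0, 1 - abs(u)^e - abs(v)^e)^(1 / e)
  grid <- expand.grid(u = seq(-1, 1, by = 0.005), v = seq(-1, 1, by = 0.005))
  vol_analytic <- prod(sa) * 2 * mean(f(grid$u, grid$v)) * 4
  gen <- fix$gen0
  vol_raster <- sum(gen$truth$bone_mask) * prod(gen$volume$spacing)
  expect_lt(abs(vol_raster - vol_analytic) / vol_analytic, 0.05)
})

test_that("ground-truth masks satisfy their structural invariants", {
  t <- fix$gen$truth
  expect_false(any(t$bone_mask & t$cartilage_mask))
  expect_true(all(t$bone_mask[t$cartilage_adjacent_bone]))
  expect_gt(sum(t$cartilage_adjacent_bone), 0)
  # cartilage-adjacent bone lies on the +x half of the bone
  vol <- fix$gen$volume
  idx <- which(t$cartilage_adjacent_bone, arr.ind = TRUE)
  pts <- voxel_to_mm(vol, idx[, 1], idx[, 2], idx[, 3])
  expect_true(all(pts[, "x"] > 0))
})

test_that("default spec reproduces the modality contrasts and resolutions", {
  spec <- default_phantom_spec()
  for (m in names(spec$profiles))
    expect_true(all(spec$profiles[[m]]$spacing > 0))
  iv <- spec$profiles$MRI_T1VIBE$intensities
  expect_equal(compute_contrast(iv[["bone"]], iv[["cartilage"]])$contrast,
               0.95)
  id <- spec$profiles$MRI_DESS$intensities
  expect_equal(compute_contrast(id[["bone"]], id[["cartilage"]])$contrast,
               0.72)
})

test_that("rigid transforms behave as a group on point clouds", {
  pts <- matrix(rnorm(300), ncol = 3)
  expect_equal(apply_rigid(pts, rigid_transform()), pts,
               ignore_attr = TRUE)
  tr <- rigid_transform(diag(3), c(1, 2, 3))
  expect_equal(unname(apply_rigid(pts, tr) - pts),
               matrix(rep(c(1, 2, 3), each = 100), ncol = 3))
  set.seed(11)
  T1 <- random_rigid()
  back <- apply_rigid(apply_rigid(pts, T1), invert_rigid(T1))
  expect_lt(max(abs(back - pts)), 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "det")
  expect_error(rigid_transform(matrix(rnorm(9), 3)), "orthonormal")
})
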