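test_that("contrast evaluates its definition exactly", {
  expect_equal(compute_contrast(5, 100)$contrast, 0.95)
  expect_equal(compute_contrast(28, 100)$contrast, 0.72)
  expect_equal(compute_contrast(100, 100)$contrast, 0)
  expect_error(compute_contrast(5, 0), "non-zero")
})

test_that("dice handles the canonical overlap cases and is symmetric", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:3] <- TRUE    # |X| = 6
  b <- matrix(FALSE, 4, 4); b[2:3, 1:3] <- TRUE    # |Y| = 6, overlap 3
  disj <- matrix(FALSE, 4, 4); disj[3:4, 1:3] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(a, matrix(FALSE, 5, 5)), "differ")
})

test_that("slice weighting averages dice by per-slice pixel mass", {
  # two slices engineered to dscs 1.0 and 0.5 with weights 300 and 100
  m1 <- array(FALSE, c(2, 20, 20))
  m2 <- array(FALSE, c(2, 20, 20))
  m1[1, 1:10, 1:15] <- TRUE; m2[1, 1:10, 1:15] <- TRUE   # 150/150, dsc 1
  m1[2, 1:5, 1:10] <- TRUE                               # |X| = 50
  m2[2, 1:5, 6:15] <- TRUE                               # |Y| = 50, ovl 25
  rep <- weighted_dice(m1, m2)
  expect_equal(rep$per_slice$dsc, c(1, 0.5))
  expect_equal(rep$per_slice$weight, c(300, 100))
  expect_equal(rep$weighted_mean, 0.875)

  expect_equal(weighted_dice(m1, m1)$weighted_mean, 1)
  expect_error(weighted_dice(array(FALSE, c(2, 4, 4)),
                             array(FALSE, c(2, 4, 4))), "no slices")
})

test_that("perimeter reduction scales a circular region exactly", {
  # flat disc mesh flagged everywhere: retained points must fall inside
  # the 0.75-scaled circle
  mesh <- plane_mesh(x0 = 0, ny = 41, nz = 41, spacing = 0.25)
  r <- sqrt(mesh$vertices[, "y"]^2 + mesh$vertices[, "z"]^2)
  mesh$cartilage_flags <- r <= 4
  expect_identical(perimeter_reduce(mesh, 0), mesh$cartilage_flags)
  red <- perimeter_reduce(mesh, 0.25)
  expect_true(all(mesh$cartilage_flags[red]))      # containment
  # retained boundary radius = 0.75 * original (perimeter scales linearly)
  r_max_orig <- max(r[mesh$cartilage_flags])
  r_max_red <- max(r[red])
  expect_equal(r_max_red / r_max_orig, 0.75, tolerance = 0.05)
  expect_error(perimeter_reduce(mesh, 1), "fraction")
})

test_that("surface distance is exact on identity and pure translation", {
  gen <- fix$gen0
  seg <- segment_volume(gen$volume, gen$truth, 0.05)
  mesh <- build_mesh(seg$bset, gen$volume)
  mesh <- flag_cartilage_region(mesh, gen$truth, gen$volume)

  same <- surface_distance(mesh, mesh)
  expect_equal(same$mean_mm, 0, tolerance = 1e-12)
  expect_equal(same$sd_mm, 0, tolerance = 1e-12)
  expect_equal(same$unmatched_count, 0)

  # exact on a flat articular model: an x-translation is recovered fully
  pm <- plane_mesh(x0 = 3, ny = 31, nz = 31, spacing = 0.4)
  pm_b <- pm
  pm_b$vertices[, "x"] <- pm_b$vertices[, "x"] - 0.5
  tr <- surface_distance(pm, pm_b)
  expect_equal(tr$mean_mm, 0.5, tolerance = 1e-9)
  expect_equal(tr$sd_mm, 0, tolerance = 1e-9)

  # on the curved facet the x-projection attenuates the shift where the
  # surface tilts away from the x axis (locally by cos^2 of the tilt), so
  # the mean lies between 0 and the full 0.5 mm
  shifted <- mesh
  shifted$vertices[, "x"] <- shifted$vertices[, "x"] - 0.5
  trc <- surface_distance(mesh, shifted)
  expect_gt(trc$mean_mm, 0.2)
  expect_lte(trc$mean_mm, 0.5 + 1e-9)
})

test_that("surface distance is antisymmetric between near-identical models", {
  gen <- fix$gen0
  seg1 <- segment_volume(gen$volume, gen$truth, 0.05, phase = 1)
  seg2 <- segment_volume(gen$volume, gen$truth, 0.05, phase = 2)
  m1 <- flag_cartilage_region(build_mesh(seg1$bset, gen$volume),
                              gen$truth, gen$volume)
  m2 <- flag_cartilage_region(build_mesh(seg2$bset, gen$volume),
                              gen$truth, gen$volume)
  ab <- surface_distance(m1, m2)
  ba <- surface_distance(m2, m1)
  expect_lt(abs(ab$mean_mm + ba$mean_mm), 0.02)
  expect_lt(abs(ab$mean_mm), 0.05)  # same geometry, independent meshes
})

test_that("shrinking the match radius only loses matches", {
  gen <- fix$gen0
  seg <- segment_volume(gen$volume, gen$truth, 0.05)
  mesh <- build_mesh(seg$bset, gen$volume)
  mesh <- flag_cartilage_region(mesh, gen$truth, gen$volume)
  shifted <- mesh
  shifted$vertices[, "x"] <- shifted$vertices[, "x"] - 0.3
  radii <- c(2.5, 0.5, 0.31, 0.301)
  unmatched <- vapply(radii, function(r)
    surface_distance(mesh, shifted, radius_mm = r)$unmatched_count,
    numeric(1))
  expect_true(all(diff(unmatched) >= 0))
})
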