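test_that("point clouds map boundary pixels to mm one-to-one", {
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE
  em <- edge_map_from_slices(list(m))
  bset <- new_boundary_set(em)
  bset <- initialize_slice(bset, em, 1, seeds = rbind(c(1L, 1L)))
  vol <- image_volume(array(0, c(1, 8, 8)), c(0.7, 0.4, 0.4))
  pc <- boundary_to_pointcloud(bset, vol)
  expect_equal(unname(pc$points), matrix(0, 1, 3))

  seg <- segment_volume(fix$gen$volume, fix$gen$truth, 0.05)
  pc2 <- boundary_to_pointcloud(seg$bset, fix$gen$volume)
  n_px <- sum(vapply(seg$bset$boundary,
                     function(b) if (is.null(b)) 0L else nrow(b),
                     integer(1)))
  expect_equal(nrow(pc2$points), n_px)
  # z values live on the slice lattice
  z_rel <- (pc2$points[, "z"] - fix$gen$volume$origin[3]) /
    fix$gen$volume$spacing[1]
  expect_equal(z_rel, round(z_rel), tolerance = 1e-9)
})

test_that("contour ordering recovers simple shapes and rejects split rings", {
  sq <- rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1))
  poly <- order_contour(sq)
  expect_equal(nrow(poly), 4)
  expect_equal(poly[1, ], c(row = 1L, col = 1L))

  ring <- circle_pixels(20, c(30, 30))
  poly2 <- order_contour(ring)
  # shoelace area within 3% of the analytic disc
  x <- poly2[, 1]; y <- poly2[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  expect_lt(abs(area - pi * 400) / (pi * 400), 0.03)

  two <- rbind(circle_pixels(5, c(10, 10)), circle_pixels(5, c(40, 40)))
  expect_error(order_contour(two), "more than one")
})

test_that("sphere meshes match closed-form area and volume within 2%", {
  h <- 0.5; r <- 10
  n <- ceiling(2 * (r + 3) / h)
  xs <- (seq_len(n) - (n + 1) / 2) * h
  mask <- array(FALSE, c(n, n, n))
  mask[] <- outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= r^2
  mesh <- mask_to_mesh(mask, c(h, h, h), smoothing_iters = 0)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * r^2) / (4 * pi * r^2), 0.02)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
            0.02)
  # closed surface: every edge shared by exactly two faces
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # Laplacian smoothing only ever shrinks the sphere's area
  areas <- vapply(c(2, 5, 10), function(it)
    mesh_area(mask_to_mesh(mask, c(h, h, h), smoothing_iters = it)),
    numeric(1))
  expect_true(all(diff(c(mesh_area(mesh), areas)) < 0))
})

test_that("phantom meshes stay within the boundary cloud's bounding box", {
  gen <- fix$gen0
  seg <- segment_volume(gen$volume, gen$truth, 0.05)
  mesh <- build_mesh(seg$bset, gen$volume)
  pc <- boundary_to_pointcloud(seg$bset, gen$volume)
  diag_mm <- sqrt(sum(gen$volume$spacing^2))
  for (d in 1:3) {
    expect_gte(min(mesh$vertices[, d]), min(pc$points[, d]) - diag_mm)
    expect_lte(max(mesh$vertices[, d]), max(pc$points[, d]) + diag_mm)
  }
  # no gross drift: mesh vertices stay near the boundary cloud
  nn <- boneseg:::.nn1_cpp(mesh$vertices, pc$points)
  expect_lt(mean(nn$dist), diag_mm)
})

test_that("cartilage flags sit on the +x facet and respect isometry", {
  gen <- fix$gen0
  seg <- segment_volume(gen$volume, gen$truth, 0.05)
  mesh <- build_mesh(seg$bset, gen$volume)
  mesh <- flag_cartilage_region(mesh, gen$truth, gen$volume)
  expect_gt(sum(mesh$cartilage_flags), 0)
  expect_true(all(mesh$vertices[mesh$cartilage_flags, "x"] > 0))

  # vanishing radius flags nothing
  m0 <- flag_cartilage_region(mesh, gen$truth, gen$volume,
                              adjacency_radius_mm = 1e-9)
  expect_equal(sum(m0$cartilage_flags), 0)

  # flags are invariant under a joint rigid motion
  idx <- which(gen$truth$cartilage_mask, arr.ind = TRUE)
  cart_pts <- voxel_to_mm(gen$volume, idx[, 1], idx[, 2], idx[, 3])
  set.seed(5)
  tr <- random_rigid()
  moved <- mesh
  moved$vertices <- apply_rigid(mesh$vertices, tr)
  moved <- flag_cartilage_region(moved, apply_rigid(cart_pts, tr))
  base <- flag_cartilage_region(mesh, cart_pts)
  expect_identical(moved$cartilage_flags, base$cartilage_flags)

  expect_error(flag_cartilage_region(mesh, matrix(numeric(0), 0, 3)),
               "empty")
})
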