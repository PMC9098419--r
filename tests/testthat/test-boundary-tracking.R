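test_that("8-connectivity matches its definition on hand cases", {
  expect_length(connected_components_8(rbind(c(1, 1), c(2, 2))), 1)
  comps <- connected_components_8(rbind(c(1, 1), c(1, 2), c(6, 6)))
  expect_length(comps, 2)
  expect_equal(nrow(comps[[1]]), 2)   # ordered by smallest member
  expect_equal(comps[[2]], cbind(row = 6L, col = 6L), ignore_attr = TRUE)
})

test_that("component labeling agrees with a union-find oracle", {
  set.seed(42)
  for (rep in 1:5) {
    px <- unique(cbind(sample.int(50, 200, replace = TRUE),
                       sample.int(50, 200, replace = TRUE)))
    comps <- connected_components_8(px)
    oracle <- union_find_components(px)
    oracle_comps <- lapply(oracle, function(i) px[i, , drop = FALSE])
    expect_identical(canon_partition(comps), canon_partition(oracle_comps))
  }
})

test_that("seeding keeps exactly the chosen components", {
  ring <- circle_pixels(10, c(20, 20))
  blob <- rbind(c(40, 40), c(40, 41), c(41, 40))
  em <- edge_map_from_slices(list({
    m <- matrix(FALSE, 48, 48); m[rbind(ring, blob)] <- TRUE; m
  }))
  bset <- new_boundary_set(em)
  bset <- initialize_slice(bset, em, 1, seeds = ring[1, , drop = FALSE])
  expect_equal(nrow(bset$boundary[[1]]), nrow(ring))
  got <- bset$boundary[[1]]
  expect_setequal(paste(got[, 1], got[, 2]), paste(ring[, 1], ring[, 2]))

  # removing a bridge pixel isolates the spur
  bridge <- rbind(ring[which.max(ring[, 1]), ] + c(1, 0))
  spur <- rbind(bridge + c(1, 0), bridge + c(2, 0))
  m2 <- matrix(FALSE, 48, 48)
  m2[rbind(ring, bridge, spur)] <- TRUE
  em2 <- edge_map_from_slices(list(m2))
  b2 <- new_boundary_set(em2)
  b2 <- initialize_slice(b2, em2, 1, seeds = ring[1, , drop = FALSE],
                         remove = bridge)
  got2 <- b2$boundary[[1]]
  expect_false(any(paste(got2[, 1], got2[, 2]) %in%
                     paste(spur[, 1], spur[, 2])))

  expect_error(initialize_slice(new_boundary_set(em), em, 1,
                                seeds = matrix(integer(0), 0, 2)), "seed")
  expect_error(initialize_slice(new_boundary_set(em), em, 1,
                                seeds = rbind(c(2, 2))), "not an edge")
})

test_that("propagation reproduces identical and shifted rings exactly", {
  ring <- circle_pixels(12, c(24, 24))
  m <- matrix(FALSE, 48, 48); m[ring] <- TRUE
  em <- edge_map_from_slices(list(m, m))
  bset <- new_boundary_set(em)
  bset <- initialize_slice(bset, em, 1, seeds = ring[1, , drop = FALSE])
  bset <- propagate_boundary(bset, em)
  expect_identical(unname(bset$boundary[[2]]), unname(bset$boundary[[1]]))

  shifted <- ring; shifted[, 1] <- shifted[, 1] + 1L
  m2 <- matrix(FALSE, 48, 48); m2[shifted] <- TRUE
  em2 <- edge_map_from_slices(list(m, m2))
  # exhaustive oracle: every source pixel's nearest target lies on the
  # shifted ring, so the recovered boundary must be exactly that ring
  b2 <- new_boundary_set(em2)
  b2 <- initialize_slice(b2, em2, 1, seeds = ring[1, , drop = FALSE])
  b2 <- propagate_boundary(b2, em2, radius_px = 3)
  got <- b2$boundary[[2]]
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(shifted[, 1], shifted[, 2]))
})

test_that("an unreachable slice gets an empty boundary and a warning", {
  ring <- circle_pixels(12, c(24, 24))
  m <- matrix(FALSE, 48, 48); m[ring] <- TRUE
  em <- edge_map_from_slices(list(m, matrix(FALSE, 48, 48)))
  bset <- new_boundary_set(em)
  bset <- initialize_slice(bset, em, 1, seeds = ring[1, , drop = FALSE])
  expect_warning(bset <- propagate_boundary(bset, em), "empty boundary")
  expect_equal(nrow(bset$boundary[[2]]), 0)
})

test_that("propagation is idempotent and stays on edge pixels", {
  edges <- detect_edges(fix$gen$volume, 0.05)
  script <- auto_seed_from_mask(edges, fix$gen$truth)
  bset <- apply_edit_script(new_boundary_set(edges), edges, script)
  rng <- range(which(apply(fix$gen$truth$bone_mask, 1, any)))
  b1 <- propagate_boundary(bset, edges, script = script, slice_range = rng)
  b2 <- propagate_boundary(b1, edges, script = script, slice_range = rng)
  expect_identical(b1$boundary, b2$boundary)
  for (s in seq(rng[1], rng[2])) {
    b <- b1$boundary[[s]]
    if (is.null(b) || nrow(b) == 0) next
    expect_true(all(edges$edges[cbind(s, b[, 1], b[, 2])]))
  }
})

test_that("auto-seeding follows the operator pattern and is self-consistent", {
  edges <- detect_edges(fix$gen$volume, 0.05)
  bone_slices <- which(apply(fix$gen$truth$bone_mask, 1, any))
  script <- auto_seed_from_mask(edges, fix$gen$truth, every_n = 5)
  pattern <- bone_slices[seq(1, length(bone_slices), by = 5)]
  expect_true(all(as.character(pattern) %in% names(script$slices)))
  # first and last bone slices are always initialized
  expect_true(all(as.character(range(bone_slices)) %in%
                    names(script$slices)))
  # scripts satisfy the initialize_slice preconditions everywhere
  bset <- new_boundary_set(edges)
  expect_no_error(apply_edit_script(bset, edges, script))

  # every_n = 1 initializes every bone slice; propagation is then a no-op
  all_script <- auto_seed_from_mask(edges, fix$gen$truth, every_n = 1)
  expect_setequal(as.integer(names(all_script$slices)), bone_slices)
  b_all <- apply_edit_script(new_boundary_set(edges), edges, all_script)
  b_prop <- propagate_boundary(b_all, edges, slice_range = range(bone_slices))
  expect_identical(b_all$boundary, b_prop$boundary)
})

test_that("tracked boundaries stay close to the ground-truth boundary", {
  gen <- fix$gen0
  seg <- segment_volume(gen$volume, gen$truth, 0.05)
  bone_slices <- which(apply(gen$truth$bone_mask, 1, any))
  ok <- vapply(bone_slices, function(s) {
    b <- seg$bset$boundary[[s]]
    if (is.null(b) || nrow(b) == 0) return(FALSE)
    ring <- which(boneseg:::.mask_boundary_2d(gen$truth$bone_mask[s, , ]),
                  arr.ind = TRUE)
    # average symmetric surface distance between the tracked boundary and
    # the ground-truth ring, in pixels
    nb <- boneseg:::.prop_nn_cpp(b, ring, 50)
    nr <- boneseg:::.prop_nn_cpp(ring, b, 50)
    if (anyNA(nb) || anyNA(nr)) return(FALSE)
    d_b <- sqrt(rowSums((b - ring[nb, , drop = FALSE])^2))
    d_r <- sqrt(rowSums((ring - b[nr, , drop = FALSE])^2))
    mean(c(d_b, d_r)) <= 2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("edit scripts survive a JSON round trip", {
  script <- edit_script(list(`3` = list(seeds = rbind(c(4L, 5L)),
                                        remove = rbind(c(1L, 2L), c(2L, 2L))),
                             `7` = list(seeds = rbind(c(9L, 9L)))))
  f <- withr::local_tempfile(fileext = ".json")
  write_edit_script(script, f)
  back <- read_edit_script(f)
  expect_equal(back$slices$`3`$seeds, script$slices$`3`$seeds)
  expect_equal(back$slices$`3`$remove, script$slices$`3`$remove)
  expect_equal(nrow(back$slices$`7`$remove), 0)
})
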