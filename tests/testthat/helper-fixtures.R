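# Shared fixtures: a down-scaled phantom (half-size anatomy) keeps the unit
# suite fast while exercising the same geometry; the acceptance tests use
# the full default spec.

small_spec <- function(seed = 7L, noise = TRUE, pose = rigid_transform()) {
  sp <- phantom_spec(bone_semiaxes = c(11, 9, 7), cartilage_thickness = 2,
                     pose = pose, seed = seed)
  if (!noise)
    for (m in names(sp$profiles)) sp$profiles[[m]]$noise_sd <- 0
  sp
}

# generated once per test run
fix <- local({
  gen <- generate_phantom(small_spec(), "MRI_T1VIBE")
  gen0 <- generate_phantom(small_spec(noise = FALSE), "MRI_T1VIBE")
  list(gen = gen, gen0 = gen0)
})

# a synthetic circular edge ring (pixel set) of given radius/center
circle_pixels <- function(radius, center = c(0, 0), n = 720) {
  th <- seq(0, 2 * pi, length.out = n)
  px <- unique(cbind(round(center[1] + radius * cos(th)),
                     round(center[2] + radius * sin(th))))
  px[order(px[, 1], px[, 2]), , drop = FALSE]
}

# hand-built edge_map from a list of logical slice matrices
edge_map_from_slices <- function(slices) {
  d <- c(length(slices), nrow(slices[[1]]), ncol(slices[[1]]))
  arr <- array(FALSE, d)
  for (s in seq_along(slices)) arr[s, , ] <- slices[[s]]
  structure(list(edges = arr,
                 params = list(high_threshold = NA, sigma = NA,
                               low_ratio = NA)),
            class = "edge_map")
}

# brute-force union-find partition of a pixel set under 8-connectivity;
# independent oracle for connected_components_8
union_find_components <- function(pixels) {
  n <- nrow(pixels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (max(abs(pixels[i, ] - pixels[j, ])) <= 1L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# canonical form of a component partition for comparison
canon_partition <- function(comps) {
  keys <- vapply(comps, function(px) {
    px <- matrix(px, ncol = 2)
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    paste(px[, 1], px[, 2], collapse = ";")
  }, character(1))
  unname(sort(keys))
}

# axis-aligned rectangular grid mesh on a plane x = x0 (for exact-distance
# metric tests): vertices on a ny x nz lattice, two triangles per cell
plane_mesh <- function(x0 = 0, ny = 21, nz = 21, spacing = 0.5) {
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing
  zs <- (seq_len(nz) - (nz + 1) / 2) * spacing
  verts <- cbind(x = x0, y = rep(ys, times = nz), z = rep(zs, each = ny))
  faces <- NULL
  idx <- function(i, j) (j - 1L) * ny + i
  for (j in seq_len(nz - 1)) for (i in seq_len(ny - 1)) {
    faces <- rbind(faces,
                   c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                   c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  surface_mesh(verts, faces, cartilage_flags = rep(TRUE, nrow(verts)))
}

random_rigid <- function(max_angle_deg = 10, max_shift_mm = 5) {
  ax <- rnorm(3)
  rigid_transform(
    rotation_axis_angle(ax, stats::runif(1, -max_angle_deg, max_angle_deg)),
    stats::runif(3, -max_shift_mm, max_shift_mm) / sqrt(3))
}
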