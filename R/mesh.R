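# From per-slice boundaries to 3D point clouds and closed triangulated
# surfaces. Meshing route: ordered contours -> filled per-slice masks ->
# stacked binary volume -> Gaussian anti-aliasing (sigma = 1 voxel per
# axis) -> 0.5-level isosurface -> uniform Laplacian smoothing. The
# anti-aliasing step is what lets the piecewise-linear isosurface track the
# true boundary instead of the voxel staircase.

#' Convert a boundary set to a 3D point cloud
#'
#' One point per boundary pixel, mapped to mm via [voxel_to_mm].
#'
#' @param bset a `boundary_set` with at least one non-empty slice.
#' @param volume the [image_volume] the boundaries live on.
#' @return An object of class `point_cloud`: list with `points` (N x 3 mm)
#'   and `provenance`.
#' @export
boundary_to_pointcloud <- function(bset, volume) {
  stopifnot(inherits(bset, "boundary_set"), inherits(volume, "image_volume"))
  slices <- which(vapply(bset$boundary,
                         function(b) !is.null(b) && nrow(b) > 0,
                         logical(1)))
  if (length(slices) == 0L)
    stop("boundary set is empty", call. = FALSE)
  pts <- do.call(rbind, lapply(slices, function(s) {
    b <- bset$boundary[[s]]
    voxel_to_mm(volume, rep(s, nrow(b)), b[, 1], b[, 2])
  }))
  structure(list(points = pts,
                 provenance = list(modality = volume$modality,
                                   spacing = volume$spacing,
                                   n_slices = length(slices))),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$points), "points over",
      x$provenance$n_slices, "slices (", x$provenance$modality, ")\n")
  invisible(x)
}

#' Order a ring of pixels into a closed polygon
#'
#' Greedy traversal by repeated nearest-unvisited-neighbor starting from the
#' smallest (row, col) pixel; the polygon closes back to the start.
#'
#' @param pixels integer matrix (row, col) forming a single 8-connected
#'   ring-like component.
#' @param check_crossing test for self-intersections and warn (O(n^2);
#'   off by default in internal pipelines).
#' @return An ordered matrix of (row, col) vertices.
#' @export
order_contour <- function(pixels, check_crossing = FALSE) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  if (nrow(pixels) < 3L)
    stop("need at least 3 pixels to order", call. = FALSE)
  if (length(connected_components_8(pixels)) != 1L)
    stop("pixels form more than one 8-connected component", call. = FALSE)
  poly <- .order_pixels(pixels)
  if (check_crossing && .polygon_self_crosses(poly))
    warning("ordered contour crosses itself; proceeding")
  poly
}

# greedy nearest-unvisited traversal from the smallest (row, col) pixel;
# tolerant of small gaps (no connectivity requirement)
.order_pixels <- function(pixels) {
  n <- nrow(pixels)
  ord <- order(pixels[, 1], pixels[, 2])
  pixels <- pixels[ord, , drop = FALSE]
  visited <- logical(n)
  path <- integer(n)
  cur <- 1L
  visited[1L] <- TRUE
  path[1L] <- 1L
  for (i in seq_len(n)[-1]) {
    rest <- which(!visited)
    d2 <- (pixels[rest, 1] - pixels[cur, 1])^2 +
      (pixels[rest, 2] - pixels[cur, 2])^2
    nxt <- rest[which.min(d2)]
    visited[nxt] <- TRUE
    path[i] <- nxt
    cur <- nxt
  }
  poly <- pixels[path, , drop = FALSE]
  colnames(poly) <- c("row", "col")
  poly
}

# segment pair crossing test (proper intersections only)
.polygon_self_crosses <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[js != n | i != 1]  # skip segments sharing a vertex with i
    if (length(js) == 0) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Filled per-slice masks from a boundary set
#'
#' Orders each slice's boundary into a polygon and rasterizes its interior
#' (even-odd rule at pixel centers, union with the boundary pixels
#' themselves). This is the pixel representation used for Dice overlap.
#' Stray pixels disconnected from the main boundary component (the stray
#' edge points an operator would delete) are dropped before ordering, and
#' ordering tolerates small gaps in the remaining ring.
#'
#' @param bset a `boundary_set`.
#' @param dims grid dimensions (defaults to the boundary set's).
#' @return A logical array `[slice, row, col]`.
#' @export
boundary_to_masks <- function(bset, dims = bset$dims) {
  stopifnot(inherits(bset, "boundary_set"))
  out <- array(FALSE, dims)
  for (s in seq_len(dims[1])) {
    b <- bset$boundary[[s]]
    if (is.null(b) || nrow(b) < 3L) next
    comps <- connected_components_8(b)
    sizes <- vapply(comps, nrow, integer(1))
    # keep the dominant ring plus any comparably sized arcs of it;
    # drop isolated specks (< 10% of the largest component)
    keep <- sizes >= max(3, 0.1 * max(sizes))
    b <- do.call(rbind, comps[keep])
    if (nrow(b) < 3L) next
    ring <- matrix(FALSE, dims[2], dims[3])
    ring[b] <- TRUE
    filled <- .fill_ring_cpp(ring)
    if (sum(filled) < 2L * nrow(b)) {
      # ring leaked (a gap wider than a diagonal): fall back to the
      # ordered-polygon rasterization
      poly <- .order_pixels(b)
      filled <- .fill_polygon_cpp(poly * 1.0, dims[2], dims[3])
      filled[b] <- TRUE
    }
    out[s, , ] <- filled
  }
  out
}

#' Surface meshes
#'
#' Triangulated closed surfaces in mm with an optional per-vertex flag
#' marking the cartilage-adjacent region.
#'
#' @param vertices V x 3 matrix (x, y, z mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param cartilage_flags optional logical vector of length V.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, cartilage_flags = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3L, all(is.finite(vertices)))
  if (nrow(faces) > 0) {
    stopifnot(min(faces) >= 1L, max(faces) <= nrow(vertices))
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("faces must reference three distinct vertices", call. = FALSE)
  }
  if (!is.null(cartilage_flags))
    stopifnot(length(cartilage_flags) == nrow(vertices))
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  structure(list(vertices = vertices, faces = faces,
                 cartilage_flags = cartilage_flags),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces")
  if (!is.null(x$cartilage_flags))
    cat(";", sum(x$cartilage_flags), "cartilage-adjacent vertices")
  cat("\n")
  invisible(x)
}

#' Mesh surface area and enclosed volume
#'
#' Area sums triangle areas; volume uses the divergence theorem on the
#' (outward-oriented) closed surface.
#'
#' @param mesh a [surface_mesh].
#' @return Scalar mm^2 (area) or mm^3 (volume).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], ]; p2 <- v[f[, 2], ]; p3 <- v[f[, 3], ]
  det <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det)) / 6
}

# separable Gaussian blur of a 3D array, sigma in voxels per axis
.gauss3d <- function(a, sigma = 1) {
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-0.5 * ((-radius):radius)^2 / sigma^2)
  w <- w / sum(w)
  d <- dim(a)
  blur_axis <- function(x, axis) {
    out <- array(0, d)
    n <- d[axis]
    for (k in (-radius):radius) {
      idx_src <- pmin(pmax(seq_len(n) + k, 1L), n)  # clamp at borders
      perm <- switch(axis,
                     x[idx_src, , , drop = FALSE],
                     x[, idx_src, , drop = FALSE],
                     x[, , idx_src, drop = FALSE])
      out <- out + w[k + radius + 1] * perm
    }
    out
  }
  blur_axis(blur_axis(blur_axis(a, 1L), 2L), 3L)
}

#' Build a closed surface mesh from a boundary set
#'
#' Rasterizes the per-slice contours to filled masks, stacks them into a
#' volume, anti-aliases with a 1-voxel Gaussian, extracts the 0.5-level
#' isosurface in mm coordinates, and applies uniform Laplacian smoothing.
#' The same operators (and iteration count) should be applied to every mesh
#' that will be compared.
#'
#' @param bset a `boundary_set` with >= 3 orderable slices.
#' @param volume the source [image_volume] (for spacing/origin).
#' @param smoothing_iters Laplacian iterations (default 10, factor 0.5).
#' @param smoothing_factor step factor per iteration.
#' @return A [surface_mesh] (closed: every edge shared by exactly 2 faces).
#' @export
build_mesh <- function(bset, volume, smoothing_iters = 10L,
                       smoothing_factor = 0.5) {
  stopifnot(inherits(bset, "boundary_set"), inherits(volume, "image_volume"))
  n_ok <- sum(vapply(bset$boundary,
                     function(b) !is.null(b) && nrow(b) >= 3L, logical(1)))
  if (n_ok < 3L)
    stop("need at least 3 slices with orderable boundaries", call. = FALSE)
  masks <- boundary_to_masks(bset)
  mesh <- mask_to_mesh(masks, volume$spacing, volume$origin,
                       smoothing_iters = smoothing_iters,
                       smoothing_factor = smoothing_factor)
  mesh
}

#' Isosurface mesh from a binary mask volume
#'
#' The meshing core shared by [build_mesh] and the test oracles: pads the
#' mask, Gaussian anti-aliases it (sigma = 1 voxel), extracts the 0.5-level
#' isosurface, and smooths.
#'
#' @param mask logical/numeric array `[slice, row, col]`.
#' @param spacing (ds, dr, dc) mm.
#' @param origin mm position (x, y, z) of voxel `[1, 1, 1]`.
#' @param antialias_sigma Gaussian sigma in voxels (0 disables).
#' @inheritParams build_mesh
#' @return A [surface_mesh].
#' @export
mask_to_mesh <- function(mask, spacing, origin = c(0, 0, 0),
                         smoothing_iters = 10L, smoothing_factor = 0.5,
                         antialias_sigma = 1) {
  d <- dim(mask)
  pad <- 2L
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  if (antialias_sigma > 0) field <- .gauss3d(field, antialias_sigma)
  origin_pad <- c(origin[1] - pad * spacing[2],
                  origin[2] - pad * spacing[3],
                  origin[3] - pad * spacing[1])
  iso <- .mtet_isosurface_cpp(as.numeric(field), dim(field), 0.5,
                              as.numeric(spacing), origin_pad)
  verts <- iso$vertices
  if (smoothing_iters > 0L)
    verts <- .laplacian_smooth_cpp(verts, iso$faces,
                                   as.integer(smoothing_iters),
                                   smoothing_factor)
  surface_mesh(verts, iso$faces)
}

#' Flag the cartilage-adjacent region on a mesh
#'
#' Marks mesh vertices lying within `adjacency_radius_mm` of any cartilage
#' voxel center (from a `ground_truth`) or cartilage cloud point.
#'
#' @param mesh a [surface_mesh].
#' @param cartilage a `ground_truth` plus its volume, or an N x 3 matrix of
#'   cartilage points (mm).
#' @param volume the [image_volume] the truth masks align to (required when
#'   `cartilage` is a `ground_truth`).
#' @param adjacency_radius_mm flag radius (default 1.0).
#' @return The mesh with `cartilage_flags` set.
#' @export
flag_cartilage_region <- function(mesh, cartilage, volume = NULL,
                                  adjacency_radius_mm = 1.0) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (adjacency_radius_mm <= 0)
    stop("`adjacency_radius_mm` must be positive", call. = FALSE)
  if (inherits(cartilage, "ground_truth")) {
    if (is.null(volume))
      stop("`volume` is required with a ground_truth input", call. = FALSE)
    idx <- which(cartilage$cartilage_mask, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      stop("cartilage mask is empty", call. = FALSE)
    pts <- voxel_to_mm(volume, idx[, 1], idx[, 2], idx[, 3])
  } else {
    pts <- as.matrix(cartilage)
    if (nrow(pts) == 0L)
      stop("cartilage point set is empty", call. = FALSE)
  }
  res <- .radius_mean_cpp(mesh$vertices, pts, adjacency_radius_mm)
  mesh$cartilage_flags <- res$count > 0L
  mesh
}
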