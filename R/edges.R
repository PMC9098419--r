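# Per-slice Canny edge detection with hysteresis thresholds on a
# normalized 0-1 scale: the high threshold is a fraction of the slice's
# maximum gradient magnitude, so a single threshold range works across
# slices of varying brightness; low = 0.4 * high (the conventional
# hysteresis ratio when only one threshold is named).

#' Canny edge detection on one slice
#'
#' Standard Canny pipeline: Gaussian smoothing (`sigma` in pixels), Sobel
#' gradients, non-maximum suppression, and two-threshold hysteresis with
#' `high = high_threshold * max(gradient magnitude)` and
#' `low = low_ratio * high`.
#'
#' @param image 2D numeric matrix (rows x cols), at least 5 x 5.
#' @param high_threshold fraction in (0, 1) of the maximum gradient
#'   magnitude.
#' @param sigma Gaussian smoothing standard deviation in pixels. The
#'   upstream tool's quoted default is 0.10, which performs almost no
#'   smoothing; 1.0 is this package's recommended working value.
#' @param low_ratio hysteresis low/high ratio (default 0.4).
#' @return Logical matrix of edge pixels, same dimensions as `image`.
#' @export
canny_slice <- function(image, high_threshold, sigma = 1.0,
                        low_ratio = 0.4) {
  image <- as.matrix(image)
  if (nrow(image) < 5L || ncol(image) < 5L)
    stop("image must be at least 5 x 5", call. = FALSE)
  if (!is.numeric(high_threshold) || high_threshold <= 0 ||
      high_threshold >= 1)
    stop("`high_threshold` must lie in (0, 1)", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (diff(range(image)) == 0) {
    warning("constant image: no gradients, returning empty edge map")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  .canny_slice_cpp(image, high_threshold, sigma, low_ratio)
}

#' Detect edges slice-wise over a volume
#'
#' Applies [canny_slice] to every slice, producing an `edge_map` whose grid
#' matches the source volume. Parameters are recorded for provenance.
#'
#' @param volume an [image_volume].
#' @inheritParams canny_slice
#' @return An object of class `edge_map`: list with `edges` (logical array
#'   aligned to the volume) and `params`.
#' @export
detect_edges <- function(volume, high_threshold, sigma = 1.0,
                         low_ratio = 0.4) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$voxels)
  edges <- array(FALSE, d)
  for (s in seq_len(d[1])) {
    img <- volume$voxels[s, , ]
    if (diff(range(img)) == 0) next  # uniform slice: no edges
    edges[s, , ] <- .canny_slice_cpp(img, high_threshold, sigma, low_ratio)
  }
  structure(list(edges = edges,
                 params = list(high_threshold = high_threshold,
                               sigma = sigma, low_ratio = low_ratio)),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  d <- dim(x$edges)
  cat("edge_map:", d[1], "slices x", d[2], "x", d[3], ";",
      sum(x$edges), "edge pixels\n")
  cat("  high_threshold:", x$params$high_threshold,
      " sigma:", x$params$sigma, "px  low_ratio:", x$params$low_ratio, "\n")
  invisible(x)
}

# edge pixels of slice s as an n x 2 integer matrix (row, col), 1-based
.slice_pixels <- function(edges, s) {
  which(edges[s, , ], arr.ind = TRUE)
}
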