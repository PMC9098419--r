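#' Image volumes
#'
#' An `image_volume` is a 3D scalar voxel grid indexed `[slice, row, col]`
#' with per-axis spacing in mm, a modality tag, and an origin giving the mm
#' position of voxel `[1, 1, 1]`.
#'
#' @param voxels 3D numeric array indexed `[slice, row, col]`.
#' @param spacing numeric length-3, mm per step along (slice, row, col);
#'   all strictly positive and finite.
#' @param modality one of `"MRI_T1VIBE"`, `"MRI_DESS"`, `"CT"`, `"OTHER"`.
#' @param origin numeric length-3 `(x0, y0, z0)` mm position of voxel
#'   `[1, 1, 1]`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, modality = "OTHER",
                         origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 1L))
    stop("grid dimensions must all be >= 1", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("all voxel intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)",
         call. = FALSE)
  modality <- match.arg(modality, c("MRI_T1VIBE", "MRI_DESS", "CT", "OTHER"))
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, modality = modality,
         origin = origin),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("image_volume:", d[1], "slices x", d[2], "rows x", d[3], "cols\n")
  cat("  spacing (slice,row,col):", paste(x$spacing, collapse = " x "),
      "mm;  modality:", x$modality, "\n")
  cat("  origin (x,y,z):", paste(signif(x$origin, 6), collapse = ", "),
      "mm;  intensity range:",
      paste(signif(range(x$voxels), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' Crop region
#'
#' Inclusive index bounds describing a sub-grid of an [image_volume]:
#' the slab of slices and the in-plane rectangle retained around the bone
#' of interest.
#'
#' @param slice_first,slice_last inclusive slice bounds.
#' @param row_min,row_max,col_min,col_max inclusive in-plane bounds.
#' @return An object of class `crop_region`.
#' @export
crop_region <- function(slice_first, slice_last, row_min, row_max,
                        col_min, col_max) {
  v <- vapply(list(slice_first, slice_last, row_min, row_max, col_min,
                   col_max), as.integer, integer(1))
  if (anyNA(v)) stop("crop bounds must be integers", call. = FALSE)
  if (v[1] > v[2] || v[3] > v[4] || v[5] > v[6])
    stop("crop bounds must satisfy first <= last on every axis",
         call. = FALSE)
  if (any(v < 1L))
    stop("crop bounds must be >= 1", call. = FALSE)
  structure(list(slice_first = v[1], slice_last = v[2], row_min = v[3],
                 row_max = v[4], col_min = v[5], col_max = v[6]),
            class = "crop_region")
}

#' Crop a volume around a region of interest
#'
#' Returns the sub-volume spanned by `region`. Spacing is preserved and the
#' origin is shifted so that every retained voxel keeps its mm coordinates.
#'
#' @param volume an [image_volume].
#' @param region a [crop_region] lying within the volume's grid.
#' @return An [image_volume] with the region's extents.
#' @export
crop_volume <- function(volume, region) {
  stopifnot(inherits(volume, "image_volume"), inherits(region, "crop_region"))
  d <- dim(volume$voxels)
  if (region$slice_last > d[1] || region$row_max > d[2] ||
      region$col_max > d[3])
    stop("crop region exceeds the volume's grid", call. = FALSE)
  vox <- volume$voxels[region$slice_first:region$slice_last,
                       region$row_min:region$row_max,
                       region$col_min:region$col_max, drop = FALSE]
  sp <- volume$spacing
  origin <- volume$origin + c((region$row_min - 1L) * sp[2],
                              (region$col_min - 1L) * sp[3],
                              (region$slice_first - 1L) * sp[1])
  image_volume(vox, sp, volume$modality, origin)
}

#' Voxel indices to mm coordinates
#'
#' Maps 1-based `(slice, row, col)` indices to physical `(x, y, z)` mm using
#' the package convention: x along rows (perpendicular to the articular
#' face), y along columns, z along slices.
#'
#' @param volume an [image_volume].
#' @param slice,row,col equal-length index vectors (1-based).
#' @return A numeric matrix with columns `x`, `y`, `z` (mm).
#' @export
voxel_to_mm <- function(volume, slice, row, col) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$voxels)
  slice <- as.numeric(slice); row <- as.numeric(row); col <- as.numeric(col)
  if (any(slice < 1 | slice > d[1]) || any(row < 1 | row > d[2]) ||
      any(col < 1 | col > d[3]))
    stop("voxel indices out of range", call. = FALSE)
  sp <- volume$spacing
  cbind(x = volume$origin[1] + (row - 1) * sp[2],
        y = volume$origin[2] + (col - 1) * sp[3],
        z = volume$origin[3] + (slice - 1) * sp[1])
}

#' Read an image volume
#'
#' Reads a NIfTI-1 file (spacing from the header `pixdim`) or an `.rds`-free
#' plain container written by [write_volume]. The NIfTI data array is stored
#' in the package's `[slice, row, col]` order.
#'
#' @param path file path.
#' @param format `"nifti"` (default, `.nii`/`.nii.gz`) or `"npz-raw"`
#'   (a gzipped whitespace text container, used for small fixtures).
#' @param modality modality tag to attach (NIfTI carries none).
#' @param origin origin override; defaults to (0,0,0).
#' @return An [image_volume].
#' @export
read_volume <- function(path, format = c("nifti", "npz-raw"),
                        modality = "OTHER", origin = c(0, 0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      stop("expected a 3D NIfTI volume, got ", length(dim(a)), "D",
           call. = FALSE)
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("non-positive voxel spacing in NIfTI header", call. = FALSE)
    image_volume(a, sp, modality, origin)
  } else {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    hdr <- as.numeric(strsplit(readLines(con, n = 1L), " ")[[1]])
    if (length(hdr) != 9L) stop("malformed raw volume header", call. = FALSE)
    d <- as.integer(hdr[1:3])
    vals <- scan(con, what = numeric(), quiet = TRUE)
    if (length(vals) != prod(d))
      stop("raw volume payload does not match header dimensions",
           call. = FALSE)
    image_volume(array(vals, d), hdr[4:6], modality, hdr[7:9])
  }
}

#' Write an image volume
#'
#' @param volume an [image_volume].
#' @param path output path (`.nii`/`.nii.gz` for NIfTI).
#' @param format `"nifti"` or `"npz-raw"` (gzipped text, fixture use).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("nifti", "npz-raw")) {
  stopifnot(inherits(volume, "image_volume"))
  format <- match.arg(format)
  if (format == "nifti") {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else {
    con <- gzfile(path, "wt")
    on.exit(close(con))
    writeLines(paste(c(dim(volume$voxels), volume$spacing, volume$origin),
                     collapse = " "), con)
    write(format(volume$voxels, digits = 17), con, ncolumns = 8)
  }
  invisible(path)
}
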