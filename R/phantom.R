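# Synthetic patella-like phantom: a superellipsoid bone body with a
# uniform-thickness cartilage layer on its +x (articular) face, rasterized
# at modality-specific resolutions with modality-specific tissue intensities
# and additive Gaussian noise. Ground-truth masks come from the same
# analytic geometry and are noise-free by construction.

#' Phantom specification
#'
#' Describes the analytic anatomy and the per-modality imaging profiles of
#' the synthetic phantom. The defaults are the package's canonical study
#' conditions: a patella-scale superellipsoid bone (semiaxes 22 x 18 x 14 mm,
#' exponent 2.5, giving a flattened articular facet), a 3 mm cartilage layer
#' on the +x facet, T1-VIBE-like spacing 0.7 x 0.4 x 0.4 mm
#' (slice, row, col), DESS-like spacing 1.0 x 0.3 x 0.3 mm, CT-like spacing
#' 0.6 x 0.3 x 0.3 mm, and nominal intensities chosen so the bone/cartilage
#' contrast is 0.95 (T1-VIBE-like) and 0.72 (DESS-like).
#'
#' @param bone_semiaxes length-3, mm semiaxes (a, b, c) of the bone body
#'   along (x, y, z).
#' @param cartilage_thickness mm thickness (measured along x) of the
#'   cartilage shell on the +x facet.
#' @param exponent superellipsoid exponent (2 = ellipsoid; larger = boxier).
#' @param profiles named list per modality with elements `spacing`
#'   (slice, row, col mm), `intensities` (named: bone, cartilage,
#'   background), `noise_sd` (additive Gaussian, same units as intensity).
#' @param pose [rigid_transform] applied to the anatomy before
#'   rasterization.
#' @param seed integer RNG seed for the noise draw.
#' @param margin_mm empty margin around the posed anatomy.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(bone_semiaxes = c(22, 18, 14),
                         cartilage_thickness = 3,
                         exponent = 2.5,
                         profiles = list(
                           MRI_T1VIBE = list(
                             spacing = c(0.7, 0.4, 0.4),
                             intensities = c(bone = 5, cartilage = 100,
                                             background = 40),
                             noise_sd = 2),
                           MRI_DESS = list(
                             spacing = c(1.0, 0.3, 0.3),
                             intensities = c(bone = 28, cartilage = 100,
                                             background = 40),
                             noise_sd = 2),
                           CT = list(
                             spacing = c(0.6, 0.3, 0.3),
                             intensities = c(bone = 1000, cartilage = 100,
                                             background = 0),
                             noise_sd = 10)),
                         pose = rigid_transform(),
                         seed = 42L,
                         margin_mm = 6) {
  bone_semiaxes <- as.numeric(bone_semiaxes)
  if (length(bone_semiaxes) != 3L || any(bone_semiaxes <= 0))
    stop("`bone_semiaxes` must be 3 positive values (mm)", call. = FALSE)
  if (cartilage_thickness <= 0)
    stop("`cartilage_thickness` must be positive", call. = FALSE)
  if (exponent <= 0) stop("`exponent` must be positive", call. = FALSE)
  for (m in names(profiles)) {
    p <- profiles[[m]]
    if (any(p$spacing <= 0))
      stop("spacing for ", m, " must be positive", call. = FALSE)
    if (p$noise_sd < 0)
      stop("noise_sd for ", m, " must be >= 0", call. = FALSE)
    if (p$intensities[["bone"]] == p$intensities[["cartilage"]])
      stop("bone and cartilage intensities for ", m,
           " must differ (contrast would be zero)", call. = FALSE)
  }
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(bone_semiaxes = bone_semiaxes,
                 cartilage_thickness = cartilage_thickness,
                 exponent = exponent, profiles = profiles, pose = pose,
                 seed = as.integer(seed), margin_mm = margin_mm),
            class = "phantom_spec")
}

#' Canonical phantom specification
#'
#' @return The default [phantom_spec].
#' @export
default_phantom_spec <- function() phantom_spec()

# superellipsoid implicit function at canonical-frame points (N x 3)
.superellipsoid_f <- function(q, semiaxes, exponent) {
  abs(q[, 1] / semiaxes[1])^exponent +
    abs(q[, 2] / semiaxes[2])^exponent +
    abs(q[, 3] / semiaxes[3])^exponent
}

# run code with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a phantom rendering
#'
#' Rasterizes the posed analytic anatomy onto the modality's voxel grid:
#' each voxel takes the nominal intensity of the tissue at its center plus
#' additive Gaussian noise drawn from the seeded RNG. Ground-truth bone and
#' cartilage masks are rasterized from the same geometry and are independent
#' of the noise level and seed.
#'
#' @param spec a [phantom_spec].
#' @param modality one of the spec's profile names
#'   (`"MRI_T1VIBE"`, `"MRI_DESS"`, `"CT"`).
#' @return A list with `volume` (an [image_volume]) and `truth`
#'   (class `ground_truth`: logical arrays `bone_mask`, `cartilage_mask`,
#'   `cartilage_adjacent_bone` aligned to the volume).
#' @export
generate_phantom <- function(spec, modality = "MRI_T1VIBE") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!modality %in% names(spec$profiles))
    stop("unknown modality: ", modality, call. = FALSE)
  prof <- spec$profiles[[modality]]
  sa <- spec$bone_semiaxes
  ct <- spec$cartilage_thickness

  # grid extents: posed bounding box of the anatomy plus margin
  box <- as.matrix(expand.grid(x = c(-sa[1], sa[1] + ct),
                               y = c(-sa[2], sa[2]),
                               z = c(-sa[3], sa[3])))
  posed <- apply_rigid(box, spec$pose)
  lo <- apply(posed, 2, min) - spec$margin_mm
  hi <- apply(posed, 2, max) + spec$margin_mm
  sp <- prof$spacing  # (ds, dr, dc) along (z, x, y)
  nr <- ceiling((hi[1] - lo[1]) / sp[2]) + 1L
  nc <- ceiling((hi[2] - lo[2]) / sp[3]) + 1L
  ns <- ceiling((hi[3] - lo[3]) / sp[1]) + 1L
  origin <- lo

  # voxel centers in mm, then pulled back to the canonical anatomy frame
  xs <- origin[1] + (seq_len(nr) - 1) * sp[2]
  ys <- origin[2] + (seq_len(nc) - 1) * sp[3]
  zs <- origin[3] + (seq_len(ns) - 1) * sp[1]
  pts <- cbind(
    x = rep(xs, each = ns, times = nc),
    y = rep(ys, each = ns * nr),
    z = rep(zs, times = nr * nc))
  inv <- invert_rigid(spec$pose)
  q <- apply_rigid(pts, inv)

  f_bone <- .superellipsoid_f(q, sa, spec$exponent)
  bone <- f_bone <= 1
  qs <- q
  qs[, 1] <- qs[, 1] - ct
  cart <- !bone & q[, 1] > 0 &
    .superellipsoid_f(qs, sa, spec$exponent) <= 1

  dims <- c(ns, nr, nc)
  bone_mask <- array(bone, dims)
  cart_mask <- array(cart, dims)

  ints <- prof$intensities
  vox <- array(ints[["background"]], dims)
  vox[bone_mask] <- ints[["bone"]]
  vox[cart_mask] <- ints[["cartilage"]]
  if (prof$noise_sd > 0) {
    noise <- .with_seed(spec$seed,
                        rnorm(prod(dims), 0, prof$noise_sd))
    vox <- vox + array(noise, dims)
  }

  truth <- structure(
    list(bone_mask = bone_mask, cartilage_mask = cart_mask,
         cartilage_adjacent_bone = .adjacent_to(bone_mask, cart_mask)),
    class = "ground_truth")
  list(volume = image_volume(vox, sp, modality, origin), truth = truth)
}

# bone voxels having a 6-connected neighbor inside the cartilage mask
.adjacent_to <- function(bone_mask, cart_mask) {
  d <- dim(bone_mask)
  out <- array(FALSE, d)
  shift <- function(m, axis, by) {
    res <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) {
      idx_src[[axis]] <- 2:n; idx_dst[[axis]] <- 1:(n - 1)
    } else {
      idx_src[[axis]] <- 1:(n - 1); idx_dst[[axis]] <- 2:n
    }
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    out <- out | shift(cart_mask, axis, by)
  out & bone_mask
}
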