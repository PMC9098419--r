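# End-to-end validation experiments on the synthetic phantom: the
# same-scan repeatability, scan/re-scan, and MRI-vs-CT comparisons, each
# chaining phantom generation, edge detection, auto-seeded boundary
# tracking, meshing, registration, and the agreement metrics.

#' Segment a phantom volume
#'
#' The full semi-automatic pipeline with the scripted (auto-seeded) stand-in
#' for operator interaction: Canny edges, seeds on every `every_n`-th bone
#' slice, propagation to the remaining slices.
#'
#' @param volume an [image_volume].
#' @param truth the matching `ground_truth` (drives auto-seeding).
#' @param high_threshold Canny high threshold (normalized 0-1).
#' @param sigma Canny Gaussian sigma in pixels.
#' @param every_n,phase auto-seed slice pattern (see [auto_seed_from_mask]).
#' @param radius_px propagation search radius in pixels.
#' @return List with `bset` (the `boundary_set`), `edges`, `script`.
#' @export
segment_volume <- function(volume, truth, high_threshold, sigma = 1.0,
                           every_n = 5L, phase = 1L, radius_px = 3) {
  edges <- detect_edges(volume, high_threshold, sigma)
  script <- auto_seed_from_mask(edges, truth, every_n, phase)
  bset <- new_boundary_set(edges)
  bset <- apply_edit_script(bset, edges, script)
  bone_slices <- which(apply(truth$bone_mask, 1, any))
  bset <- propagate_boundary(bset, edges, radius_px, script,
                             slice_range = range(bone_slices))
  list(bset = bset, edges = edges, script = script)
}

#' Experiment configuration
#'
#' All randomness and every tunable of a validation experiment in one
#' object; a config fully determines the experiment's outputs.
#'
#' @param experiment one of `"same_scan_repeatability"`, `"scan_rescan"`,
#'   `"mri_vs_ct"`.
#' @param spec the [phantom_spec] (defaults to the canonical phantom).
#' @param seeds length-2 integer seeds (noise realizations; must differ for
#'   `scan_rescan`).
#' @param thresholds named Canny high thresholds per modality.
#' @param sigma Canny Gaussian sigma (pixels).
#' @param every_n auto-seed stride.
#' @param phases length-2 auto-seed phases for the two segmentations
#'   (`same_scan_repeatability` uses both; others use the first).
#' @param radius_px propagation radius.
#' @param smoothing_iters Laplacian smoothing iterations for every mesh.
#' @param surface_radius_mm matching radius for [surface_distance].
#' @param perimeter_fraction perimeter-reduction fraction.
#' @param pose_angle_deg,pose_shift_mm rigid pose perturbation applied to
#'   the second acquisition in `scan_rescan` (rotation about z; shift
#'   split evenly across axes).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("same_scan_repeatability",
                                             "scan_rescan", "mri_vs_ct"),
                              spec = default_phantom_spec(),
                              seeds = c(1L, 2L),
                              thresholds = c(MRI_T1VIBE = 0.05, CT = 0.20),
                              sigma = 1.0,
                              every_n = 5L,
                              phases = c(1L, 2L),
                              radius_px = 3,
                              smoothing_iters = 10L,
                              surface_radius_mm = 2.5,
                              perimeter_fraction = 0.25,
                              pose_angle_deg = 1,
                              pose_shift_mm = 0.5) {
  experiment <- match.arg(experiment)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  seeds <- as.integer(seeds)
  if (experiment == "scan_rescan" && seeds[1] == seeds[2])
    stop("scan_rescan requires two distinct seeds", call. = FALSE)
  structure(list(experiment = experiment, spec = spec, seeds = seeds,
                 thresholds = thresholds, sigma = sigma,
                 every_n = as.integer(every_n), phases = as.integer(phases),
                 radius_px = radius_px,
                 smoothing_iters = as.integer(smoothing_iters),
                 surface_radius_mm = surface_radius_mm,
                 perimeter_fraction = perimeter_fraction,
                 pose_angle_deg = pose_angle_deg,
                 pose_shift_mm = pose_shift_mm),
            class = "experiment_config")
}

# mesh + flags + cloud for one segmentation
.model_from_segmentation <- function(seg, volume, truth, config) {
  mesh <- build_mesh(seg$bset, volume,
                     smoothing_iters = config$smoothing_iters)
  mesh <- flag_cartilage_region(mesh, truth, volume)
  cloud <- boundary_to_pointcloud(seg$bset, volume)
  list(mesh = mesh, cloud = cloud)
}

.transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_rigid(mesh$vertices, transform)
  mesh
}

#' Run a validation experiment
#'
#' Generates the phantom volume(s), auto-seeds, segments, meshes, registers
#' and compares, entirely determined by the config:
#' * `same_scan_repeatability` - one rendering segmented twice with the
#'   auto-seed phase offset between `phases`; reports slice-weighted Dice
#'   and the signed surface distance.
#' * `scan_rescan` - two noise realizations of the same anatomy, the second
#'   with a small rigid pose perturbation, ICP-registered; reports surface
#'   distance.
#' * `mri_vs_ct` - the same anatomy rendered at MRI-like and CT-like
#'   resolution/intensities with modality-appropriate thresholds,
#'   ICP-registered; reports surface distance.
#'
#' @param config an [experiment_config].
#' @return An object of class `experiment_report` with elements among
#'   `dice` (a `dice_report`), `distance` (a `surface_distance_report`),
#'   `icp` (an `icp_result`), plus `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list(config = config)

  if (config$experiment == "same_scan_repeatability") {
    spec <- config$spec
    spec$seed <- config$seeds[1]
    gen <- generate_phantom(spec, "MRI_T1VIBE")
    thr <- config$thresholds[["MRI_T1VIBE"]]
    seg_a <- segment_volume(gen$volume, gen$truth, thr, config$sigma,
                            config$every_n, config$phases[1],
                            config$radius_px)
    seg_b <- segment_volume(gen$volume, gen$truth, thr, config$sigma,
                            config$every_n, config$phases[2],
                            config$radius_px)
    out$dice <- weighted_dice(boundary_to_masks(seg_a$bset),
                              boundary_to_masks(seg_b$bset))
    mod_a <- .model_from_segmentation(seg_a, gen$volume, gen$truth, config)
    mod_b <- .model_from_segmentation(seg_b, gen$volume, gen$truth, config)
    out$icp <- register_models(mod_b$mesh, mod_a$mesh)
    mesh_b <- .transform_mesh(mod_b$mesh, out$icp$transform)
    out$distance <- surface_distance(mod_a$mesh, mesh_b,
                                     config$surface_radius_mm,
                                     config$perimeter_fraction)
  } else if (config$experiment == "scan_rescan") {
    spec_a <- config$spec
    spec_a$seed <- config$seeds[1]
    spec_b <- config$spec
    spec_b$seed <- config$seeds[2]
    spec_b$pose <- rigid_transform(
      rotation_axis_angle(c(0, 0, 1), config$pose_angle_deg),
      rep(config$pose_shift_mm / sqrt(3), 3))
    gen_a <- generate_phantom(spec_a, "MRI_T1VIBE")
    gen_b <- generate_phantom(spec_b, "MRI_T1VIBE")
    thr <- config$thresholds[["MRI_T1VIBE"]]
    seg_a <- segment_volume(gen_a$volume, gen_a$truth, thr, config$sigma,
                            config$every_n, config$phases[1],
                            config$radius_px)
    seg_b <- segment_volume(gen_b$volume, gen_b$truth, thr, config$sigma,
                            config$every_n, config$phases[1],
                            config$radius_px)
    mod_a <- .model_from_segmentation(seg_a, gen_a$volume, gen_a$truth,
                                      config)
    mod_b <- .model_from_segmentation(seg_b, gen_b$volume, gen_b$truth,
                                      config)
    out$icp <- register_models(mod_b$mesh, mod_a$mesh)
    mesh_b <- .transform_mesh(mod_b$mesh, out$icp$transform)
    out$distance <- surface_distance(mod_a$mesh, mesh_b,
                                     config$surface_radius_mm,
                                     config$perimeter_fraction)
  } else {  # mri_vs_ct
    spec_a <- config$spec
    spec_a$seed <- config$seeds[1]
    spec_b <- config$spec
    spec_b$seed <- config$seeds[2]
    gen_a <- generate_phantom(spec_a, "MRI_T1VIBE")
    gen_b <- generate_phantom(spec_b, "CT")
    seg_a <- segment_volume(gen_a$volume, gen_a$truth,
                            config$thresholds[["MRI_T1VIBE"]], config$sigma,
                            config$every_n, config$phases[1],
                            config$radius_px)
    seg_b <- segment_volume(gen_b$volume, gen_b$truth,
                            config$thresholds[["CT"]], config$sigma,
                            config$every_n, config$phases[1],
                            config$radius_px)
    mod_a <- .model_from_segmentation(seg_a, gen_a$volume, gen_a$truth,
                                      config)
    mod_b <- .model_from_segmentation(seg_b, gen_b$volume, gen_b$truth,
                                      config)
    out$icp <- register_models(mod_b$mesh, mod_a$mesh)
    mesh_b <- .transform_mesh(mod_b$mesh, out$icp$transform)
    out$distance <- surface_distance(mod_a$mesh, mesh_b,
                                     config$surface_radius_mm,
                                     config$perimeter_fraction)
  }
  class(out) <- "experiment_report"
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", x$config$experiment, "\n")
  if (!is.null(x$dice))
    cat("  weighted DSC:", signif(x$dice$weighted_mean, 6), "\n")
  if (!is.null(x$distance))
    cat("  surface distance:", signif(x$distance$mean_mm, 4), "+/-",
        signif(x$distance$sd_mm, 4), "mm (",
        nrow(x$distance$matched), "matched )\n")
  if (!is.null(x$icp))
    cat("  ICP rms:", signif(x$icp$rms_residual, 6), "mm in",
        x$icp$iterations, "iterations\n")
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Writes the scalar summaries (no per-vertex tables) deterministically:
#' identical configs produce byte-identical files.
#'
#' @param report an `experiment_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  payload <- list(experiment = report$config$experiment,
                  seeds = report$config$seeds)
  if (!is.null(report$dice))
    payload$weighted_dsc <- report$dice$weighted_mean
  if (!is.null(report$distance))
    payload$surface_distance <- list(
      mean_mm = report$distance$mean_mm,
      sd_mm = report$distance$sd_mm,
      matched = nrow(report$distance$matched),
      unmatched = report$distance$unmatched_count,
      region = report$distance$region)
  if (!is.null(report$icp))
    payload$icp <- list(rms_mm = report$icp$rms_residual,
                        iterations = report$icp$iterations,
                        converged = report$icp$converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
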