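# Seeded selection of bone-boundary edge components and slice-to-slice
# propagation. Scripted edit lists (seeds + removals per slice) replace the
# interactive picking a human operator would do.

#' 8-connected components of a pixel set
#'
#' Partitions a set of (row, col) pixels into maximal 8-connected components
#' (the four axial neighbors and the four diagonals). Components are ordered
#' by their lexicographically smallest (row, col) member.
#'
#' @param pixels integer matrix with columns (row, col).
#' @return A list of pixel matrices, one per component.
#' @export
connected_components_8 <- function(pixels) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  if (nrow(pixels) == 0L) return(list())
  r0 <- min(pixels[, 1]); c0 <- min(pixels[, 2])
  nr <- max(pixels[, 1]) - r0 + 1L
  nc <- max(pixels[, 2]) - c0 + 1L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pixels[, 1] - r0 + 1L, pixels[, 2] - c0 + 1L)] <- TRUE
  lab <- .label8_cpp(m)
  n <- max(lab)
  out <- vector("list", n)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[idx]
  for (k in seq_len(n)) {
    px <- idx[labs == k, , drop = FALSE]
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    out[[k]] <- cbind(row = px[, 1] + r0 - 1L, col = px[, 2] + c0 - 1L)
  }
  out
}

#' Edit scripts
#'
#' Per-slice scripted interactions standing in for the GUI: `remove` pixels
#' break 8-connectivity between the bone boundary and stray edges, and
#' `seeds` identify the edge components to keep.
#'
#' @param slices named list; names are slice indices (as characters), each
#'   element a list with integer matrices `seeds` and `remove`
#'   (columns row, col; either may be absent/empty).
#' @return An object of class `edit_script`.
#' @export
edit_script <- function(slices = list()) {
  for (nm in names(slices)) {
    el <- slices[[nm]]
    for (f in c("seeds", "remove")) {
      if (is.null(el[[f]])) el[[f]] <- matrix(integer(0), 0, 2)
      el[[f]] <- matrix(as.integer(el[[f]]), ncol = 2)
    }
    slices[[nm]] <- el
  }
  structure(list(slices = slices), class = "edit_script")
}

#' Read or write an edit script as JSON
#'
#' Format: `{"slices": {"12": {"seeds": [[r,c],...], "remove": [[r,c],...]}}}`.
#'
#' @param script an [edit_script].
#' @param path file path.
#' @return `read_edit_script`: an [edit_script]; `write_edit_script`:
#'   `path`, invisibly.
#' @export
write_edit_script <- function(script, path) {
  stopifnot(inherits(script, "edit_script"))
  payload <- list(slices = lapply(script$slices, function(el) {
    list(seeds = unname(apply(el$seeds, 1, identity, simplify = FALSE)),
         remove = unname(apply(el$remove, 1, identity, simplify = FALSE)))
  }))
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  slices <- lapply(raw$slices, function(el) {
    list(seeds = matrix(as.integer(unlist(el$seeds)), ncol = 2,
                        byrow = is.list(el$seeds)),
         remove = matrix(as.integer(unlist(el$remove)), ncol = 2,
                         byrow = is.list(el$remove)))
  })
  edit_script(slices)
}

#' Boundary sets
#'
#' The algorithm's evolving state: per-slice sets of pixels designated as
#' bone boundary, plus which slices were initialized by seeding and an
#' ordered log of scripted edits.
#'
#' @param edge_map an `edge_map` (see [detect_edges]) fixing the grid.
#' @return An empty `boundary_set`.
#' @export
new_boundary_set <- function(edge_map) {
  stopifnot(inherits(edge_map, "edge_map"))
  d <- dim(edge_map$edges)
  structure(list(boundary = vector("list", d[1]),
                 initialized = integer(0),
                 edits = list(), dims = d),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  filled <- which(!vapply(x$boundary, is.null, logical(1)))
  cat("boundary_set:", length(filled), "of", x$dims[1], "slices assigned;",
      "initialized at", paste(x$initialized, collapse = ", "), "\n")
  invisible(x)
}

#' Initialize a slice from seeds
#'
#' Applies scripted removals first, then keeps the union of the 8-connected
#' edge components containing any seed pixel; marks the slice initialized.
#'
#' @param bset a [new_boundary_set] result.
#' @param edge_map the source `edge_map`.
#' @param slice slice index.
#' @param seeds integer matrix (row, col) of seed pixels; each must lie on
#'   an edge pixel that survives the removals.
#' @param remove optional integer matrix (row, col) of pixels to delete
#'   before component selection.
#' @return The updated `boundary_set`.
#' @export
initialize_slice <- function(bset, edge_map, slice, seeds, remove = NULL) {
  stopifnot(inherits(bset, "boundary_set"), inherits(edge_map, "edge_map"))
  seeds <- matrix(as.integer(seeds), ncol = 2)
  if (nrow(seeds) == 0L)
    stop("no seed pixels supplied for slice ", slice, call. = FALSE)
  em <- edge_map$edges[slice, , ]
  if (!is.null(remove) && nrow(remove <- matrix(as.integer(remove),
                                                ncol = 2)) > 0)
    em[remove] <- FALSE
  on_edge <- em[seeds]
  if (!all(on_edge)) {
    bad <- seeds[!on_edge, , drop = FALSE][1, ]
    stop("seed pixel (", bad[1], ", ", bad[2], ") on slice ", slice,
         " is not an edge pixel", call. = FALSE)
  }
  lab <- .label8_cpp(em)
  keep_labels <- unique(lab[seeds])
  kept <- which(matrix(lab %in% keep_labels, nrow(lab), ncol(lab)),
                arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), , drop = FALSE]
  colnames(kept) <- c("row", "col")
  bset$boundary[[slice]] <- kept
  bset$initialized <- sort(unique(c(bset$initialized, as.integer(slice))))
  bset$edits <- c(bset$edits,
                  list(list(slice = slice, seeds = seeds,
                            remove = if (is.null(remove))
                              matrix(integer(0), 0, 2) else remove)))
  bset
}

#' Propagate boundaries to adjacent slices
#'
#' Processes slices outward from each initialized slice in both directions
#' (nearest initializer wins; ties go to the lower-indexed initializer).
#' Each source boundary pixel pulls its nearest edge pixel in the target
#' slice (Euclidean pixel distance, capped at `radius_px`; distance ties
#' broken by smallest (row, col)). Scripted per-slice removals are applied
#' after assignment. A target slice with no candidates gets an empty
#' boundary with a warning, and propagation continues using the last
#' non-empty slice as source.
#'
#' @param bset a `boundary_set` with at least one initialized slice.
#' @param edge_map the source `edge_map`.
#' @param radius_px search radius in pixels (default 3).
#' @param script optional [edit_script] whose `remove` entries are applied
#'   to propagated slices.
#' @param slice_range optional length-2 inclusive slice range to process
#'   (defaults to the full stack).
#' @return The updated `boundary_set`.
#' @export
propagate_boundary <- function(bset, edge_map, radius_px = 3,
                               script = NULL, slice_range = NULL) {
  stopifnot(inherits(bset, "boundary_set"), inherits(edge_map, "edge_map"))
  if (length(bset$initialized) == 0L)
    stop("no initialized slices to propagate from", call. = FALSE)
  if (radius_px <= 0) stop("`radius_px` must be positive", call. = FALSE)
  ns <- bset$dims[1]
  rng <- if (is.null(slice_range)) c(1L, ns) else as.integer(slice_range)
  init <- bset$initialized
  todo <- setdiff(seq(rng[1], rng[2]), init)
  if (length(todo) == 0L) return(bset)

  dist_to_init <- vapply(todo, function(s) min(abs(s - init)), numeric(1))
  nearest_init <- vapply(todo, function(s) {
    cand <- init[abs(s - init) == min(abs(s - init))]
    min(cand)
  }, numeric(1))
  ord <- order(dist_to_init, todo)

  removals <- list()
  if (!is.null(script)) removals <- script$slices

  for (i in ord) {
    s <- todo[i]
    step <- if (nearest_init[i] < s) -1L else 1L
    # walk toward the initializer until a non-empty source is found
    src_slice <- s + step
    while (src_slice != nearest_init[i] &&
           (is.null(bset$boundary[[src_slice]]) ||
            nrow(bset$boundary[[src_slice]]) == 0L))
      src_slice <- src_slice + step
    src <- bset$boundary[[src_slice]]
    tgt <- .slice_pixels(edge_map$edges, s)
    assigned <- NULL
    if (!is.null(src) && nrow(src) > 0L && nrow(tgt) > 0L) {
      nn <- .prop_nn_cpp(src, tgt, radius_px)
      hit <- nn[!is.na(nn)]
      if (length(hit) > 0L) {
        pulled <- tgt[sort(unique(hit)), , drop = FALSE]
        # grow from the pulled pixels along their 8-connected edge
        # components, but stay within radius_px of the source boundary:
        # this recovers the full boundary ring (the plural "nearest edge
        # pixels") without jumping to distant structures
        lab <- .label8_cpp(edge_map$edges[s, , ])
        cand <- tgt[lab[tgt] %in% unique(lab[pulled]), , drop = FALSE]
        near_src <- !is.na(.prop_nn_cpp(cand, src, radius_px))
        assigned <- cand[near_src, , drop = FALSE]
        # the bone boundary is a closed curve: open-ended chains picked up
        # near junctions with other structures are stray points the
        # operator would delete
        assigned <- .prune_tails(assigned, iters = ceiling(radius_px))
      }
    }
    if (is.null(assigned) || nrow(assigned) == 0L) {
      warning("slice ", s, ": no edge pixels within ", radius_px,
              " px of the source boundary; empty boundary assigned")
      bset$boundary[[s]] <- matrix(integer(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col")))
      next
    }
    rem <- removals[[as.character(s)]]$remove
    if (!is.null(rem) && nrow(rem) > 0L) {
      keyed <- paste(assigned[, 1], assigned[, 2])
      rkey <- paste(rem[, 1], rem[, 2])
      assigned <- assigned[!keyed %in% rkey, , drop = FALSE]
    }
    assigned <- assigned[order(assigned[, 1], assigned[, 2]), ,
                         drop = FALSE]
    colnames(assigned) <- c("row", "col")
    bset$boundary[[s]] <- assigned
  }
  bset
}

#' Apply an edit script's seeds
#'
#' Initializes every slice named in the script via [initialize_slice].
#'
#' @param bset a `boundary_set`.
#' @param edge_map the source `edge_map`.
#' @param script an [edit_script].
#' @return The updated `boundary_set`.
#' @export
apply_edit_script <- function(bset, edge_map, script) {
  stopifnot(inherits(script, "edit_script"))
  for (nm in names(script$slices)) {
    el <- script$slices[[nm]]
    if (nrow(el$seeds) > 0L)
      bset <- initialize_slice(bset, edge_map, as.integer(nm), el$seeds,
                               el$remove)
  }
  bset
}

# iteratively strip pixels with at most one 8-neighbor in the set
# (endpoints of open chains); closed rings are left untouched
.prune_tails <- function(pixels, iters = 3L) {
  for (it in seq_len(iters)) {
    n <- nrow(pixels)
    if (n <= 3L) return(pixels)
    key <- paste(pixels[, 1], pixels[, 2])
    deg <- integer(n)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      deg <- deg + (paste(pixels[, 1] + dr, pixels[, 2] + dc) %in% key)
    }
    keep <- deg >= 2L
    if (all(keep)) return(pixels)
    pixels <- pixels[keep, , drop = FALSE]
  }
  pixels
}

# 2D helpers on logical matrices ---------------------------------------------

.mask_boundary_2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  inner <- m
  pad <- function(dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc]
    res
  }
  all4 <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  m & !all4
}

.dilate_chebyshev <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rs_dst <- max(1, 1 + dr):min(nr, nr + dr)
    cs_dst <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs_dst, cs_dst] <- out[rs_dst, cs_dst] |
      m[rs_dst - dr, cs_dst - dc]
  }
  out
}

#' Auto-seed an edit script from ground truth
#'
#' Test-time stand-in for the human operator: on every `every_n`-th slice
#' intersecting the bone mask (the operator initialized roughly one in five
#' slices), emits one seed per edge component overlapping the 2-px-dilated
#' ground-truth bone boundary, plus removals that prune those components'
#' pixels falling outside the dilated boundary (severing bridges to stray
#' structures).
#'
#' In addition to the periodic pattern, the first and last bone slices are
#' always initialized (the operator identifies them explicitly before
#' cropping), as is any slice whose ground-truth boundary lies farther than
#' `max_shift_px` from its neighbor's: near the poles of the bone the
#' cross-section grows faster per slice than any safe propagation radius,
#' and these are exactly the slices where the operator would step in and
#' correct before proceeding.
#'
#' @param edge_map an `edge_map`.
#' @param truth a `ground_truth` (see [generate_phantom]).
#' @param every_n initialize every n-th bone slice (default 5).
#' @param phase which slice of each group of `every_n` to start at
#'   (1-based; shifting it offsets the initialized slice pattern).
#' @param max_shift_px initialize both slices of any adjacent pair whose
#'   truth boundaries are farther apart than this (default 3, matching the
#'   default propagation radius).
#' @return An [edit_script].
#' @export
auto_seed_from_mask <- function(edge_map, truth, every_n = 5L, phase = 1L,
                                max_shift_px = 3) {
  stopifnot(inherits(edge_map, "edge_map"), inherits(truth, "ground_truth"))
  every_n <- as.integer(every_n)
  if (every_n < 1L) stop("`every_n` must be >= 1", call. = FALSE)
  bone_slices <- which(apply(truth$bone_mask, 1, any))
  start <- ((as.integer(phase) - 1L) %% every_n) + 1L
  chosen <- bone_slices[seq(start, length(bone_slices), by = every_n)]
  chosen <- union(chosen, range(bone_slices))
  # correction slices: adjacent pairs whose truth boundary shifts too far
  rings <- lapply(bone_slices, function(s)
    which(.mask_boundary_2d(truth$bone_mask[s, , ]), arr.ind = TRUE))
  for (k in seq_len(length(bone_slices) - 1L)) {
    a <- rings[[k]]; b <- rings[[k + 1L]]
    gap_ab <- anyNA(.prop_nn_cpp(a, b, max_shift_px))
    gap_ba <- anyNA(.prop_nn_cpp(b, a, max_shift_px))
    if (gap_ab || gap_ba)
      chosen <- union(chosen, bone_slices[c(k, k + 1L)])
  }
  chosen <- sort(chosen)
  slices <- list()
  for (s in chosen) {
    em <- edge_map$edges[s, , ]
    ring <- .dilate_chebyshev(.mask_boundary_2d(truth$bone_mask[s, , ]), 2L)
    lab <- .label8_cpp(em)
    overlap_labels <- setdiff(unique(lab[ring & em]), 0L)
    if (length(overlap_labels) == 0L)
      stop("slice ", s, ": no edge component overlaps the ground-truth ",
           "bone boundary (threshold/phantom mismatch)", call. = FALSE)
    in_overlap <- matrix(lab %in% overlap_labels, nrow(lab), ncol(lab))
    remove_px <- which(in_overlap & !ring, arr.ind = TRUE)
    kept <- em & in_overlap & ring
    lab2 <- .label8_cpp(kept)
    seeds <- t(vapply(seq_len(max(lab2)), function(k) {
      px <- which(lab2 == k, arr.ind = TRUE)
      px[order(px[, 1], px[, 2])[1], ]
    }, integer(2)))
    slices[[as.character(s)]] <- list(
      seeds = matrix(as.integer(seeds), ncol = 2),
      remove = matrix(as.integer(remove_px), ncol = 2))
  }
  edit_script(slices)
}
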