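# independent re-implementation of the smoothed Sobel gradient magnitude,
# used as the oracle for edge localization
.oracle_gradmag <- function(img, sigma = 1.0) {
  reflect <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  radius <- max(1, ceiling(3 * sigma))
  w <- exp(-0.5 * ((-radius):radius)^2 / sigma^2)
  w <- w / sum(w)
  nr <- nrow(img); nc <- ncol(img)
  sm <- img
  for (pass in 1:2) {
    out <- sm * 0
    for (k in (-radius):radius) {
      if (pass == 1) out <- out + w[k + radius + 1] *
          sm[reflect(seq_len(nr) + k, nr), ]
      else out <- out + w[k + radius + 1] *
          sm[, reflect(seq_len(nc) + k, nc)]
    }
    sm <- out
  }
  gx <- gy <- sm * 0
  for (r in 1:nr) for (c in 1:nc) {
    rm <- reflect(r - 1, nr); rp <- reflect(r + 1, nr)
    cm <- reflect(c - 1, nc); cp <- reflect(c + 1, nc)
    gx[r, c] <- (sm[rp, cm] + 2 * sm[rp, c] + sm[rp, cp]) -
      (sm[rm, cm] + 2 * sm[rm, c] + sm[rm, cp])
    gy[r, c] <- (sm[rm, cp] + 2 * sm[r, cp] + sm[rp, cp]) -
      (sm[rm, cm] + 2 * sm[r, cm] + sm[rp, cm])
  }
  sqrt(gx^2 + gy^2)
}

test_that("constant images produce no edges, with a warning", {
  expect_warning(e <- canny_slice(matrix(5, 10, 10), 0.05), "constant")
  expect_equal(sum(e), 0)
  expect_error(canny_slice(matrix(rnorm(100), 10), 1.5), "0, 1")
  expect_error(canny_slice(matrix(rnorm(12), 3), 0.05), "5 x 5")
})

test_that("a vertical intensity step yields a single line at the step", {
  img <- matrix(0, 30, 30)
  img[, 16:30] <- 100
  e <- canny_slice(img, 0.05, sigma = 1.0)
  gm <- .oracle_gradmag(img, 1.0)
  for (r in 5:25) {
    cols <- which(e[r, ])
    expect_length(cols, 1)            # a single line
    expect_lte(abs(cols - which.max(gm[r, ])), 1)  # at the gradient argmax
  }
})

test_that("raising the threshold never adds edge pixels", {
  img <- fix$gen$volume$voxels[ceiling(dim(fix$gen$volume$voxels)[1] / 2), , ]
  lo <- canny_slice(img, 0.02)
  hi <- canny_slice(img, 0.07)
  expect_true(all(lo[hi]))   # edges at 0.07 are a subset of those at 0.02
  expect_lt(sum(hi), sum(lo))
})

test_that("edge maps are reproducible and align with the volume grid", {
  e1 <- detect_edges(fix$gen$volume, 0.05)
  e2 <- detect_edges(fix$gen$volume, 0.05)
  expect_identical(e1$edges, e2$edges)
  expect_equal(dim(e1$edges), dim(fix$gen$volume$voxels))
  expect_equal(e1$params$high_threshold, 0.05)
})

test_that("the phantom bone boundary is detected across the MRI range", {
  # containment oracle: every edge-boundary arc must stay within 2 px of
  # the dilated ground-truth bone boundary on the mid-slice
  gen <- fix$gen0
  mid <- round(mean(which(apply(gen$truth$bone_mask, 1, any))))
  truth_ring <- which(boneseg:::.mask_boundary_2d(gen$truth$bone_mask[mid, , ]),
                      arr.ind = TRUE)
  for (thr in c(0.02, 0.05, 0.07)) {
    e <- canny_slice(gen$volume$voxels[mid, , ], thr)
    ring_px <- which(e, arr.ind = TRUE)
    expect_gt(nrow(ring_px), 0)
    # at least one component encircles the bone: the truth ring is fully
    # within 2 px of detected edges
    nn <- boneseg:::.prop_nn_cpp(truth_ring, ring_px, 2.9)
    expect_true(all(!is.na(nn)))
  }
})

test_that("slices without structure contribute no edges", {
  gen <- fix$gen0
  empty_slice <- which(!apply(gen$truth$bone_mask, 1, any))[1]
  e <- detect_edges(gen$volume, 0.05)
  expect_equal(sum(e$edges[empty_slice, , ]), 0)
})
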