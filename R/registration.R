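# Rigid point-cloud alignment: closed-form least-squares fit over known
# correspondences (cross-covariance SVD) and point-to-point iterative
# closest point with centroid pre-alignment.

#' Best rigid fit over known correspondences
#'
#' The rigid transform minimizing `sum || R s_i + t - g_i ||^2` over the
#' given pairs, via SVD of the cross-covariance matrix. Reflection
#' solutions are rejected (det = +1 enforced).
#'
#' @param source,target matrices of corresponding points (rows pair up;
#'   both N x 3, N >= 3, non-collinear).
#' @return A [rigid_transform] mapping source onto target.
#' @export
best_rigid_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3L, ncol(target) == 3L,
            nrow(source) == nrow(target))
  if (nrow(source) < 3L)
    stop("need at least 3 correspondence pairs", call. = FALSE)
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) correspondences", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cs)
  rigid_transform(R, t)
}

#' Iterative closest point registration
#'
#' Point-to-point ICP: after centroid pre-alignment, alternates
#' nearest-neighbor correspondence (kd-tree) with [best_rigid_fit] until
#' the rms residual changes by less than `tol_mm` or `max_iterations` is
#' reached. Returns the cumulative transform mapping the source cloud onto
#' the target.
#'
#' @param source,target point matrices (N x 3, N >= 3) or `point_cloud`
#'   objects.
#' @param max_iterations iteration cap (default 100).
#' @param tol_mm convergence tolerance on the rms change (default 1e-6).
#' @return An object of class `icp_result`: list with `transform`
#'   ([rigid_transform]), `rms_residual` (mm), `iterations`, `converged`,
#'   and `rms_history`.
#' @export
icp <- function(source, target, max_iterations = 100L, tol_mm = 1e-6) {
  if (inherits(source, "point_cloud")) source <- source$points
  if (inherits(target, "point_cloud")) target <- target$points
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3L, ncol(target) == 3L)
  if (nrow(source) < 3L || nrow(target) < 3L)
    stop("both clouds need at least 3 points", call. = FALSE)
  if (!all(is.finite(source)) || !all(is.finite(target)))
    stop("clouds contain non-finite points", call. = FALSE)
  if (tol_mm <= 0) stop("`tol_mm` must be positive", call. = FALSE)

  # centroid pre-alignment
  t0 <- colMeans(target) - colMeans(source)
  cur <- sweep(source, 2, t0, "+")
  total <- rigid_transform(diag(3), t0)

  rms_prev <- Inf
  rms_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    nn <- .nn1_cpp(cur, target)
    rms <- sqrt(mean(nn$dist^2))
    rms_hist <- c(rms_hist, rms)
    if (abs(rms_prev - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    inc <- best_rigid_fit(cur, target[nn$index, , drop = FALSE])
    cur <- apply_rigid(cur, inc)
    total <- compose_rigid(inc, total)
  }
  structure(list(transform = total, rms_residual = rms_hist[length(rms_hist)],
                 iterations = iter, converged = converged,
                 rms_history = rms_hist),
            class = "icp_result")
}

#' Area-weighted vertex normals of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return An N x 3 matrix of unit outward normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, f[, k])
    n[as.integer(rownames(acc)), ] <- n[as.integer(rownames(acc)), ] + acc
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Register one surface model onto another
#'
#' Registration used before every surface-distance comparison: a
#' point-to-point ICP over the mesh vertices for the convergence basin,
#' followed by a point-to-plane refinement against the target's vertex
#' normals. On smooth, near-symmetric bone surfaces reconstructed from a
#' voxel lattice, point-to-point correspondences alone can trade a small
#' rotation against a translation (tangential sliding) and settle up to
#' ~0.1 mm away from the true pose; constraining residuals along the
#' target normals removes that sliding mode.
#'
#' @param source_mesh,target_mesh `surface_mesh` objects (source is moved
#'   onto target).
#' @param max_iterations cap for each phase.
#' @param tol_mm convergence tolerance on the rms change.
#' @return An `icp_result` whose transform maps source onto target.
#' @export
register_models <- function(source_mesh, target_mesh,
                            max_iterations = 100L, tol_mm = 1e-9) {
  stopifnot(inherits(source_mesh, "surface_mesh"),
            inherits(target_mesh, "surface_mesh"))
  init <- icp(source_mesh$vertices, target_mesh$vertices,
              max_iterations = max_iterations, tol_mm = max(tol_mm, 1e-8))
  cur <- apply_rigid(source_mesh$vertices, init$transform)
  tgt <- target_mesh$vertices
  normals <- mesh_vertex_normals(target_mesh)
  total <- init$transform
  prev <- Inf
  rms <- init$rms_residual
  iter <- 0L
  converged <- FALSE
  while (iter < max_iterations) {
    iter <- iter + 1L
    nn <- .nn1_cpp(cur, tgt)
    q <- tgt[nn$index, , drop = FALSE]
    n <- normals[nn$index, , drop = FALSE]
    r <- rowSums((cur - q) * n)
    rms <- sqrt(mean(r^2))
    if (abs(prev - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    prev <- rms
    # linearized rigid update minimizing sum((R p + t - q) . n)^2
    cxn <- cbind(cur[, 2] * n[, 3] - cur[, 3] * n[, 2],
                 cur[, 3] * n[, 1] - cur[, 1] * n[, 3],
                 cur[, 1] * n[, 2] - cur[, 2] * n[, 1])
    A <- cbind(cxn, n)
    x <- tryCatch(solve(crossprod(A), -crossprod(A, r)),
                  error = function(e) rep(0, 6))
    w <- x[1:3]
    angle <- sqrt(sum(w^2))
    R <- if (angle > 0)
      rotation_axis_angle(w / angle, angle * 180 / pi) else diag(3)
    inc <- rigid_transform(R, x[4:6])
    cur <- apply_rigid(cur, inc)
    total <- compose_rigid(inc, total)
  }
  structure(list(transform = total, rms_residual = rms,
                 iterations = init$iterations + iter,
                 converged = init$converged && converged,
                 rms_history = c(init$rms_history, rms)),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat("icp_result:", x$iterations, "iterations, rms",
      signif(x$rms_residual, 6), "mm,",
      if (x$converged) "converged" else "not converged", "\n")
  print(x$transform)
  invisible(x)
}
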