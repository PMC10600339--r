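#' Rigid iterative-closest-point alignment of a mesh to a point cloud
#'
#' Classical ICP: alternate nearest-neighbour correspondence with the
#' least-squares rigid fit (Kabsch/SVD) until the relative RMS change drops
#' below `tol` or `max_iters` is reached. Connectivity, `component_id` and
#' `vertex_uid` are untouched, and being rigid, the transform leaves the set
#' of self-intersecting faces exactly invariant.
#'
#' @param source a [trimesh()].
#' @param target point matrix (or cloud list) to align to.
#' @param max_iters maximum ICP iterations.
#' @param tol relative RMS convergence tolerance.
#' @return list with `transform` (list `R` 3x3 rotation, `t` translation in
#'   mm) and `mesh` (the transformed source).
#' @export
icp_rigid <- function(source, target, max_iters = 50L, tol = 1e-6) {
  tp <- as_surface_points(target)
  if (nrow(tp) < 3) stopf("degenerate target: need at least 3 points")
  if (qr(sweep(tp, 2, colMeans(tp)))$rank < 2)
    stopf("degenerate target: points are collinear")
  v0 <- source$vertices
  # centroid pre-alignment keeps the nearest-neighbour correspondences sane
  # under large initial offsets
  R_tot <- diag(3)
  t_tot <- colMeans(tp) - colMeans(v0)
  v <- sweep(v0, 2, t_tot, "+")
  rms_prev <- Inf
  for (it in seq_len(max_iters)) {
    nn <- .nn1(tp, v)
    corr <- tp[nn$index, , drop = FALSE]
    fit <- kabsch(v, corr)
    v <- sweep(v %*% t(fit$R), 2, fit$t, "+")
    R_tot <- fit$R %*% R_tot
    t_tot <- as.vector(fit$R %*% t_tot) + fit$t
    rms <- sqrt(mean(.nn1(tp, v)$dist^2))
    if (is.finite(rms_prev) && abs(rms_prev - rms) <= tol * max(rms_prev, 1e-12))
      break
    rms_prev <- rms
  }
  out <- source
  out$vertices <- v
  list(transform = list(R = R_tot, t = t_tot), mesh = out)
}

# least-squares rigid transform mapping x onto y (Kabsch, det +1)
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  H <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.vector(cy - R %*% cx))
}

#' Configuration for non-rigid ICP
#'
#' @param stiffness strictly decreasing positive stiffness schedule.
#' @param iters_per_level inner iterations per stiffness level.
#' @param max_corr_dist correspondence distance cap in mm; matches farther
#'   than this get zero weight.
#' @return an object of class `nricp_config`.
#' @export
nricp_config <- function(stiffness = c(50, 20, 5, 2), iters_per_level = 10L,
                         max_corr_dist = 10) {
  if (any(diff(stiffness) >= 0) || any(stiffness <= 0))
    stopf("'stiffness' must be strictly decreasing and positive")
  structure(list(stiffness = stiffness,
                 iters_per_level = as.integer(iters_per_level),
                 max_corr_dist = max_corr_dist),
            class = "nricp_config")
}

#' Non-rigid ICP (stiffness-regularised per-vertex affine deformation)
#'
#' Amberg-style optimal-step NRICP: each vertex carries a 3x4 affine transform;
#' every step minimises weighted squared correspondence distance plus
#' `stiffness^2` times the squared graph difference of neighbouring vertex
#' transforms, solved as one sparse least-squares system, over a decreasing
#' stiffness schedule. Connectivity and `vertex_uid` are untouched.
#'
#' @param source a [trimesh()].
#' @param target point matrix (or cloud list) to align to.
#' @param cfg an [nricp_config()].
#' @param return_transforms attach the final 4N x 3 per-vertex transform
#'   stack as attribute `"transforms"`.
#' @return the deformed [trimesh()].
#' @export
icp_nonrigid <- function(source, target, cfg = nricp_config(),
                         return_transforms = FALSE) {
  tp <- as_surface_points(target)
  if (nrow(tp) < 3) stopf("degenerate target: need at least 3 points")
  v0 <- source$vertices
  n <- nrow(v0)
  e <- mesh_edges(source)
  ne <- nrow(e)
  # D: n x 4n block design, row i = [v_i^T 1] in block i
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = 4),
    j = as.vector(t(cbind(4 * (seq_len(n) - 1) + 1, 4 * (seq_len(n) - 1) + 2,
                          4 * (seq_len(n) - 1) + 3, 4 * seq_len(n)))),
    x = as.vector(t(cbind(v0, rep(1, n)))),
    dims = c(n, 4 * n))
  # M kron G: 4 rows per edge, difference of per-vertex transforms
  gi <- rep(seq_len(4 * ne), 2)
  blk <- rep(4 * (e[, 1] - 1), each = 4) + rep(1:4, ne)
  blk2 <- rep(4 * (e[, 2] - 1), each = 4) + rep(1:4, ne)
  gx <- c(rep(1, 4 * ne), rep(-1, 4 * ne))
  MG <- Matrix::sparseMatrix(i = gi, j = c(blk, blk2), x = gx,
                             dims = c(4 * ne, 4 * n))
  MGtMG <- Matrix::crossprod(MG)
  # X: 4n x 3 stacked per-vertex affines, initialised to identity
  X <- do.call(rbind, rep(list(rbind(diag(3), c(0, 0, 0))), n))
  for (alpha in cfg$stiffness) {
    for (it in seq_len(cfg$iters_per_level)) {
      v <- as.matrix(D %*% X)
      nn <- .nn1(tp, v)
      w <- as.numeric(nn$dist <= cfg$max_corr_dist)
      U <- tp[nn$index, , drop = FALSE]
      WD <- D * w
      A <- alpha^2 * MGtMG + Matrix::crossprod(WD, D)
      B <- Matrix::crossprod(WD, U)
      X_new <- tryCatch(as.matrix(Matrix::solve(A, B)), error = function(e) NULL)
      if (is.null(X_new)) {
        A <- (4 * alpha^2) * MGtMG + Matrix::crossprod(WD, D)
        X_new <- as.matrix(Matrix::solve(A, B))
      }
      delta <- max(abs(X_new - X))
      X <- X_new
      if (delta < 1e-6) break
    }
  }
  out <- source
  out$vertices <- as.matrix(D %*% X)
  if (return_transforms) attr(out, "transforms") <- X
  out
}

#' Align predicted meshes to the predicted voxel segmentation
#'
#' Per organ, the registration target is the surface of that organ's predicted
#' voxel mask ([marching_cubes()] then dense area-weighted sampling); the
#' selected registration is applied per mesh component. `"nricp"` runs rigid
#' ICP first and refines non-rigidly. Organs with an empty predicted mask are
#' returned unregistered with a warning.
#'
#' @param pred_meshes list of per-organ predicted [trimesh()] objects, indexed
#'   by organ label.
#' @param seg 3D integer label array (the predicted segmentation).
#' @param spacing voxel spacing (mm).
#' @param mode `"none"`, `"icp"` or `"nricp"`.
#' @param n_target_points samples drawn from each organ's voxel surface.
#' @param nricp_cfg an [nricp_config()] for mode `"nricp"`.
#' @return list of aligned meshes, same order and structure as `pred_meshes`.
#' @export
align_to_voxels <- function(pred_meshes, seg, spacing,
                            mode = c("none", "icp", "nricp"),
                            n_target_points = 10000L,
                            nricp_cfg = nricp_config()) {
  mode <- match.arg(mode)
  if (mode == "none") return(pred_meshes)
  out <- pred_meshes
  for (org in seq_along(pred_meshes)) {
    pm <- pred_meshes[[org]]
    if (is.null(pm)) next
    mask <- seg == org
    if (!any(mask)) {
      warning(sprintf("organ %d: empty predicted voxel mask, mesh left unregistered", org))
      next
    }
    surf <- marching_cubes(mask, spacing)
    tp <- sample_surface(surf, n_target_points)$points
    parts <- split_components(pm)
    aligned <- lapply(parts, function(p) {
      r <- icp_rigid(p, tp)
      if (mode == "nricp") icp_nonrigid(r$mesh, tp, nricp_cfg) else r$mesh
    })
    out[[org]] <- merge_meshes(aligned, renumber = FALSE)
  }
  out
}
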