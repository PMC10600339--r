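#' Voxel cross-entropy loss
#'
#' Mean over voxels of the negative log softmax probability of the true class.
#'
#' @param seg_logits array `c(C, nx, ny, nz)` of class scores.
#' @param gt_labels 3D integer array with values in `0..C-1`.
#' @return scalar loss.
#' @export
cross_entropy <- function(seg_logits, gt_labels) {
  ce_fwd(seg_logits, gt_labels)$loss
}

ce_fwd <- function(seg_logits, gt_labels) {
  d <- dim(seg_logits)
  C <- d[1]
  lab <- as.integer(gt_labels)
  if (length(lab) != prod(d[2:4]))
    stopf("label volume shape does not match logits")
  if (any(lab < 0 | lab >= C)) stopf("labels must lie in [0, %d)", C)
  mat <- matrix(seg_logits, C)          # C x V
  mx <- apply(mat, 2, max)
  ex <- exp(sweep(mat, 2, mx))
  Z <- colSums(ex)
  p <- sweep(ex, 2, Z, "/")
  V <- ncol(mat)
  idx <- cbind(lab + 1L, seq_len(V))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  list(loss = loss, p = p, idx = idx, dim = d)
}

ce_bwd <- function(cache, gscale = 1) {
  p <- cache$p
  V <- ncol(p)
  p[cache$idx] <- p[cache$idx] - 1
  array(p * (gscale / V), dim = cache$dim)
}

#' Symmetric squared-distance Chamfer loss between two point clouds
#'
#' Mean over ground-truth points of the squared distance to the nearest
#' predicted point, plus the mean over predicted points of the squared distance
#' to the nearest ground-truth point.
#'
#' @param pred_points M x 3 matrix of predicted surface samples.
#' @param gt_points N x 3 matrix of ground-truth surface samples.
#' @return scalar loss (mm^2).
#' @export
chamfer <- function(pred_points, gt_points) {
  chamfer_fwd(pred_points, gt_points)$loss
}

chamfer_fwd <- function(pred_points, gt_points) {
  pred_points <- as.matrix(pred_points)
  gt_points <- as.matrix(gt_points)
  if (nrow(pred_points) == 0 || nrow(gt_points) == 0)
    stopf("point clouds must be nonempty")
  a <- .nn1(pred_points, gt_points)   # for each gt point, nearest pred
  b <- .nn1(gt_points, pred_points)   # for each pred point, nearest gt
  loss <- mean(a$dist^2) + mean(b$dist^2)
  list(loss = loss, gt_to_pred = a, pred_to_gt = b,
       pred = pred_points, gt = gt_points)
}

# gradient w.r.t. predicted points (gt treated as data)
chamfer_bwd <- function(cache, gscale = 1) {
  m <- nrow(cache$pred)
  n <- nrow(cache$gt)
  g <- matrix(0, m, 3)
  # term 2: mean over pred of ||pred - nearest_gt||^2
  diff2 <- cache$pred - cache$gt[cache$pred_to_gt$index, , drop = FALSE]
  g <- g + (2 / m) * diff2
  # term 1: mean over gt of ||gt - nearest_pred||^2; d/dpred = -2(gt - pred)
  diff1 <- cache$gt - cache$pred[cache$gt_to_pred$index, , drop = FALSE]
  for (c in 1:3) {
    acc <- rowsum(diff1[, c], cache$gt_to_pred$index)
    rows <- as.integer(rownames(acc))
    g[rows, c] <- g[rows, c] - (2 / n) * acc[, 1]
  }
  g * gscale
}

#' Edge-length regularisation loss
#'
#' Mean squared edge length over the undirected edge set of a mesh (each edge
#' counted once).
#'
#' @param mesh a [trimesh()] with at least one edge.
#' @return scalar loss (mm^2).
#' @export
edge_loss <- function(mesh) {
  e <- mesh_edges(mesh)
  if (nrow(e) == 0) stopf("mesh has no edges")
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(rowSums(d * d))
}

# gradient of edge_loss w.r.t. vertices
edge_loss_bwd <- function(mesh, gscale = 1) {
  e <- mesh_edges(mesh)
  ne <- nrow(e)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  g <- matrix(0, n_vertices(mesh), 3)
  for (c in 1:3) {
    acc1 <- rowsum(d[, c], e[, 1])
    g[as.integer(rownames(acc1)), c] <- g[as.integer(rownames(acc1)), c] + acc1[, 1]
    acc2 <- rowsum(-d[, c], e[, 2])
    g[as.integer(rownames(acc2)), c] <- g[as.integer(rownames(acc2)), c] + acc2[, 1]
  }
  g * (2 * gscale / ne)
}

#' Assemble the total training loss
#'
#' `total = ce + chamfer + lambda * edge`. The cross-entropy term sums the
#' final and deep-supervision voxel outputs (ground truth downsampled by
#' nearest neighbour to match); the Chamfer and edge terms sum over all five
#' stage meshes under deep mesh supervision, or use the final mesh only when
#' it is off. Chamfer is computed per organ against that organ's ground-truth
#' cloud and summed over organs.
#'
#' @param outputs a [net_forward()] result.
#' @param stage_meshes the five post-stage meshes from [euler_integrate()].
#' @param gt list with `labels` (3D integer array) and `clouds` (list of per-
#'   organ ground-truth point matrices, indexed by component).
#' @param cfg a [net_config()].
#' @param lambda edge-loss weight (default 10).
#' @param n_surface_points predicted-surface samples per organ per stage.
#' @return a `loss_breakdown` list: `ce`, `chamfer`, `edge`, `total`, and
#'   per-stage sub-terms.
#' @export
total_loss <- function(outputs, stage_meshes, gt, cfg, lambda = 10,
                       n_surface_points = 2000L) {
  tl <- total_loss_fwd(outputs, stage_meshes, gt, cfg, lambda, n_surface_points)
  tl$breakdown
}

# forward with caches kept for the training backward
total_loss_fwd <- function(outputs, stage_meshes, gt, cfg, lambda = 10,
                           n_surface_points = 2000L) {
  ce_val <- 0
  ce_caches <- list()
  if (cfg$use_voxel_branch && !is.null(outputs$seg_logits)) {
    cc <- ce_fwd(outputs$seg_logits, gt$labels)
    ce_val <- ce_val + cc$loss
    ce_caches$final <- cc
    for (s in names(outputs$deep_seg_logits)) {
      logits <- outputs$deep_seg_logits[[s]]
      labs <- downsample_labels(gt$labels, dim(logits)[2:4])
      cc <- ce_fwd(logits, labs)
      ce_val <- ce_val + cc$loss
      ce_caches[[s]] <- cc
    }
  }
  stages <- if (cfg$use_deep_mesh_supervision) 1:5 else 5L
  ch_val <- 0
  ed_val <- 0
  stage_terms <- list()
  mesh_caches <- list()
  for (s in stages) {
    m <- stage_meshes[[s]]
    ch_s <- 0
    ch_caches <- list()
    for (org in seq_along(gt$clouds)) {
      samp <- sample_surface_comp(m, org, n_surface_points)
      if (is.null(samp)) next
      cc <- chamfer_fwd(samp$points, gt$clouds[[org]])
      ch_s <- ch_s + cc$loss
      ch_caches[[org]] <- list(cache = cc, samp = samp)
    }
    ed_s <- edge_loss(m)
    ch_val <- ch_val + ch_s
    ed_val <- ed_val + ed_s
    stage_terms[[as.character(s)]] <- c(chamfer = ch_s, edge = ed_s)
    mesh_caches[[as.character(s)]] <- list(chamfer = ch_caches, mesh = m)
  }
  total <- ce_val + ch_val + lambda * ed_val
  breakdown <- structure(list(ce = ce_val, chamfer = ch_val, edge = ed_val,
                              total = total, lambda = lambda,
                              per_stage = stage_terms),
                         class = "loss_breakdown")
  list(breakdown = breakdown, ce_caches = ce_caches, mesh_caches = mesh_caches,
       stages = stages, lambda = lambda)
}

# backward: returns g_seg, g_deep, and per-stage vertex gradients
total_loss_bwd <- function(tl, cfg) {
  g_seg <- NULL
  g_deep <- list()
  if (length(tl$ce_caches) > 0) {
    for (nm in names(tl$ce_caches)) {
      g <- ce_bwd(tl$ce_caches[[nm]])
      if (nm == "final") g_seg <- g else g_deep[[nm]] <- g
    }
  }
  g_stage <- vector("list", 5)
  for (s in tl$stages) {
    mc <- tl$mesh_caches[[as.character(s)]]
    m <- mc$mesh
    gv <- edge_loss_bwd(m, gscale = tl$lambda)
    for (org in seq_along(mc$chamfer)) {
      entry <- mc$chamfer[[org]]
      if (is.null(entry)) next
      g_pts <- chamfer_bwd(entry$cache)
      gv <- gv + sample_surface_backward(m, entry$samp, g_pts)
    }
    g_stage[[s]] <- gv
  }
  list(g_seg = g_seg, g_deep = g_deep, g_stage = g_stage)
}

# nearest-neighbour downsampling of a label volume to a coarser shape
downsample_labels <- function(labels, target_shape) {
  d <- dim(labels)
  ix <- round(seq(1, d[1], length.out = target_shape[1] + 1)[-1] - d[1] / target_shape[1] / 2)
  iy <- round(seq(1, d[2], length.out = target_shape[2] + 1)[-1] - d[2] / target_shape[2] / 2)
  iz <- round(seq(1, d[3], length.out = target_shape[3] + 1)[-1] - d[3] / target_shape[3] / 2)
  labels[pmax(ix, 1), pmax(iy, 1), pmax(iz, 1), drop = FALSE]
}
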