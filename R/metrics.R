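#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical/0-1 arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stopf("mask shapes differ")
  a <- mask_a != 0
  b <- mask_b != 0
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Voxelize a watertight mesh onto a grid
#'
#' A voxel is foreground iff its centre lies inside the closed surface,
#' decided by parity ray casting. Deterministic; requires a watertight mesh.
#'
#' @param mesh a watertight [trimesh()].
#' @param grid_shape 3 integers, output shape.
#' @param spacing voxel spacing (mm); voxel centre i maps to world i * spacing.
#' @return logical 3D array.
#' @export
voxelize <- function(mesh, grid_shape, spacing) {
  if (!is_watertight(mesh))
    stopf(paste0("mesh is not watertight; voxelization by parity ray casting ",
                 "needs a closed surface (check self_intersecting_faces())"))
  .voxelize_mesh(mesh$vertices, mesh$faces, as.integer(grid_shape),
                 as.double(spacing))
}

# surfaces may be point matrices, sample lists or meshes; normalise to points
as_surface_points <- function(x, n_points = 10000L) {
  if (inherits(x, "trimesh")) sample_surface(x, n_points)$points
  else if (is.list(x) && !is.null(x$points)) as.matrix(x$points)
  else as.matrix(x)
}

#' Average symmetric surface distance (mm)
#'
#' `(mean_a min_b ||a-b|| + mean_b min_a ||a-b||) / 2` on dense surface
#' samples. Meshes are sampled area-weighted with `n_points` points per side;
#' matrices are used as-is.
#'
#' @param surface_a,surface_b meshes, point matrices or point-cloud lists.
#' @param n_points samples per mesh surface (default 10^4).
#' @return scalar distance in mm.
#' @export
assd <- function(surface_a, surface_b, n_points = 10000L) {
  a <- as_surface_points(surface_a, n_points)
  b <- as_surface_points(surface_b, n_points)
  if (nrow(a) == 0 || nrow(b) == 0) stopf("surfaces must be nonempty")
  (mean(.nn1(b, a)$dist) + mean(.nn1(a, b)$dist)) / 2
}

#' 99th-percentile Hausdorff distance (mm)
#'
#' The maximum of the two directed 99th-percentile nearest-neighbour distance
#' distributions; percentiles interpolate linearly between order statistics.
#'
#' @inheritParams assd
#' @param probs percentile (default 0.99).
#' @return scalar distance in mm.
#' @export
hd99 <- function(surface_a, surface_b, n_points = 10000L, probs = 0.99) {
  a <- as_surface_points(surface_a, n_points)
  b <- as_surface_points(surface_b, n_points)
  if (nrow(a) == 0 || nrow(b) == 0) stopf("surfaces must be nonempty")
  da <- .nn1(b, a)$dist   # a -> b
  db <- .nn1(a, b)$dist   # b -> a
  max(stats::quantile(da, probs, type = 7, names = FALSE),
      stats::quantile(db, probs, type = 7, names = FALSE))
}

#' Percentage of self-intersecting faces per component
#'
#' `100 * |self-intersecting faces| / |faces|`, computed within each
#' component (organ) of the mesh.
#'
#' @param mesh a [trimesh()].
#' @return named numeric vector, one percentage per component id.
#' @export
sif_pct <- function(mesh) {
  sif <- self_intersecting_faces(mesh)
  face_comp <- mesh$component_id[mesh$faces[, 1]]
  comps <- sort(unique(mesh$component_id))
  out <- vapply(comps, function(cc) {
    nf <- sum(face_comp == cc)
    if (nf == 0) return(0)
    100 * sum(face_comp[sif] == cc) / nf
  }, 0)
  names(out) <- comps
  out
}

#' Evaluate predicted meshes and segmentation against ground truth
#'
#' Computes, per case and organ: mesh Dice (predicted mesh voxelized on the
#' ground-truth grid against that organ's label mask), ASSD, HD99 and SIF.
#'
#' @param pred_meshes list over cases of lists of per-organ [trimesh()].
#' @param gt_labels list over cases of 3D integer label arrays.
#' @param spacing voxel spacing (mm).
#' @param gt_meshes optional list over cases of per-organ ground-truth meshes;
#'   extracted with [marching_cubes()] from the labels when omitted.
#' @param n_points surface samples per side for the distance metrics.
#' @return a tibble with columns `case`, `organ`, `dice`, `assd_mm`,
#'   `hd99_mm`, `sif_pct` (class `metric_report`).
#' @export
evaluate_cases <- function(pred_meshes, gt_labels, spacing, gt_meshes = NULL,
                           n_points = 4000L) {
  rows <- list()
  for (i in seq_along(pred_meshes)) {
    labs <- gt_labels[[i]]
    organs <- sort(unique(as.vector(labs[labs > 0])))
    for (org in organs) {
      pm <- pred_meshes[[i]][[org]]
      if (is.null(pm)) next
      gmask <- labs == org
      gm <- if (!is.null(gt_meshes)) gt_meshes[[i]][[org]]
            else marching_cubes(gmask, spacing)
      pmask <- voxelize(pm, dim(labs), spacing)
      rows[[length(rows) + 1]] <- tibble::tibble(
        case = i, organ = org,
        dice = dice(pmask, gmask),
        assd_mm = assd(pm, gm, n_points),
        hd99_mm = hd99(pm, gm, n_points),
        sif_pct = unname(sif_pct(pm)[1]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' Aggregate a metric report to mean and SD per organ and overall
#'
#' @param report a tibble from [evaluate_cases()].
#' @return a tibble with one row per organ plus an `overall` row, columns
#'   `<metric>_mean` and `<metric>_sd`.
#' @export
summarize_metrics <- function(report) {
  metrics <- c("dice", "assd_mm", "hd99_mm", "sif_pct")
  per_organ <- lapply(split(report, report$organ), function(d) {
    row <- tibble::tibble(organ = as.character(d$organ[1]))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    row
  })
  overall <- tibble::tibble(organ = "overall")
  for (m in metrics) {
    overall[[paste0(m, "_mean")]] <- mean(report[[m]])
    overall[[paste0(m, "_sd")]] <- stats::sd(report[[m]])
  }
  do.call(rbind, c(per_organ, list(overall)))
}

#' Per-organ box plot of one metric from a report
#'
#' @param report a tibble from [evaluate_cases()].
#' @param metric one of `"dice"`, `"assd_mm"`, `"hd99_mm"`, `"sif_pct"`.
#' @return a ggplot object.
#' @export
plot_metric <- function(report, metric = "dice") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
  df <- data.frame(organ = factor(report$organ), value = report[[metric]])
  ggplot2::ggplot(df, ggplot2::aes(x = organ, y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "organ", y = metric) +
    ggplot2::theme_minimal()
}
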