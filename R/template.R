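#' Build the multi-organ mesh template from training label volumes
#'
#' For every class label, the per-voxel occupancy is the fraction of training
#' volumes containing that label at that voxel. Occupancy is binarised at
#' `occupancy_threshold` (inclusive: a voxel present in exactly 30% of volumes
#' is kept at the default threshold), each connected foreground component is
#' extracted with [marching_cubes()] and smoothed with [laplacian_smooth()],
#' and the components are concatenated with stable `vertex_uid` 0..N-1.
#'
#' @param label_volumes list of 3D integer label arrays, all the same shape.
#' @param spacing voxel spacing (mm), shared by all volumes.
#' @param occupancy_threshold occupancy fraction in (0, 1] (default 0.30).
#' @param smooth_iters Laplacian smoothing iterations (default 20).
#' @return an object of class `mesh_template`: list with `mesh` (a multi-
#'   component [trimesh()]), `organ_of_component` (integer vector mapping
#'   component id to class label), `grid_shape` and `spacing`.
#' @export
build_template <- function(label_volumes, spacing,
                           occupancy_threshold = 0.30, smooth_iters = 20L) {
  if (length(label_volumes) < 1) stopf("need at least one label volume")
  if (occupancy_threshold <= 0 || occupancy_threshold > 1)
    stopf("'occupancy_threshold' must be in (0, 1]")
  d <- dim(label_volumes[[1]])
  for (v in label_volumes)
    if (!identical(dim(v), d)) stopf("all label volumes must share one grid")
  classes <- sort(unique(unlist(lapply(label_volumes, function(v) {
    u <- unique(as.vector(v)); u[u > 0]
  }))))
  if (length(classes) == 0) stopf("no foreground classes in the label volumes")
  n <- length(label_volumes)
  comp_meshes <- list()
  organ_of_component <- integer(0)
  for (cl in classes) {
    occ <- Reduce(`+`, lapply(label_volumes, function(v) (v == cl) * 1)) / n
    # inclusive threshold, robust to the binary representation of e.g. 0.30
    bin <- occ >= occupancy_threshold - 1e-12
    if (!any(bin))
      stopf("class %d: occupancy never reaches threshold %.2f", cl,
            occupancy_threshold)
    surf <- marching_cubes(bin, spacing)
    surf <- laplacian_smooth(surf, smooth_iters)
    parts <- split_components(surf)
    for (p in parts) {
      chi <- euler_characteristic(p)
      if (chi != 2)
        stopf(paste0("class %d: a template component is not genus-0 ",
                     "(Euler characteristic %d, V=%d E=%d F=%d)"),
              cl, chi, n_vertices(p), nrow(mesh_edges(p)), n_faces(p))
      comp_meshes[[length(comp_meshes) + 1]] <- p
      organ_of_component <- c(organ_of_component, as.integer(cl))
    }
  }
  mesh <- merge_meshes(comp_meshes, renumber = TRUE)
  structure(list(mesh = mesh, organ_of_component = organ_of_component,
                 grid_shape = as.integer(d), spacing = as.double(spacing),
                 occupancy_threshold = occupancy_threshold,
                 smooth_iters = as.integer(smooth_iters)),
            class = "mesh_template")
}

#' @export
print.mesh_template <- function(x, ...) {
  cat(sprintf("<mesh_template> %d component(s) for classes {%s}; %d vertices, %d faces\n",
              length(x$organ_of_component),
              paste(x$organ_of_component, collapse = ","),
              n_vertices(x$mesh), n_faces(x$mesh)))
  invisible(x)
}
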