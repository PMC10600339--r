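#' Stack of five stationary flow fields
#'
#' The deformation is parameterised by five stationary vector fields
#' \eqn{\Phi_0, \ldots, \Phi_4} at strictly increasing grid resolutions.
#' Stages 1-4 (\eqn{\Phi_0}-\eqn{\Phi_3}) hold one field per organ; the final
#' stage (\eqn{\Phi_4}) holds a single field shared by all organs, which keeps
#' close-by organ boundaries from crossing. Field vectors are in world mm per
#' unit integration time; each field grid covers the volume's world extent and
#' is sampled by trilinear interpolation (queries outside the grid are clamped
#' to the boundary).
#'
#' @param fields list of 5 stages; stages 1-4 are lists of K arrays of
#'   dimension `c(3, gx, gy, gz)`, stage 5 a list of exactly one such array.
#' @param grid_shape shape of the image volume the fields refer to.
#' @param spacing voxel spacing of that volume (mm).
#' @return an object of class `flow_stack`.
#' @export
flow_stack <- function(fields, grid_shape, spacing) {
  if (length(fields) != 5) stopf("a flow stack has exactly 5 stages")
  res <- sapply(fields, function(st) dim(st[[1]])[2])
  if (any(diff(res) <= 0)) stopf("stage resolutions must strictly increase")
  if (length(fields[[5]]) != 1) stopf("the final stage holds exactly one shared field")
  for (st in fields) for (f in st) {
    d <- dim(f)
    if (length(d) != 4 || d[1] != 3) stopf("each field must have dim c(3, gx, gy, gz)")
  }
  structure(list(fields = fields, grid_shape = as.integer(grid_shape),
                 spacing = as.double(spacing)),
            class = "flow_stack")
}

# world geometry of a field grid with resolution g over a volume grid n
field_geometry <- function(field, grid_shape, spacing) {
  g <- dim(field)[2:4]
  ext <- (grid_shape - 1) * spacing
  fs <- ifelse(g > 1, ext / (g - 1), ext)
  list(origin = c(0, 0, 0), spacing = fs)
}

#' An all-zero flow stack (identity deformation)
#'
#' @param grid_shape volume shape the stack refers to.
#' @param spacing voxel spacing (mm).
#' @param k_fields number of per-organ fields in stages 1-4.
#' @param stage_res resolutions of the five stages (defaults to the decoder
#'   resolutions for `grid_shape`, i.e. `grid_shape / 16 ... grid_shape`).
#' @return a [flow_stack()] of zeros.
#' @export
flow_stack_zero <- function(grid_shape, spacing, k_fields,
                            stage_res = NULL) {
  if (is.null(stage_res))
    stage_res <- lapply(4:0, function(l) as.integer(grid_shape / 2^l))
  fields <- lapply(seq_len(5), function(s) {
    nk <- if (s < 5) k_fields else 1L
    lapply(seq_len(nk), function(k)
      array(0, dim = c(3, stage_res[[s]])))
  })
  flow_stack(fields, grid_shape, spacing)
}

#' Integration settings for the piecewise-stationary flow ODE
#'
#' Each stationary field acts over one unit of integration time, solved with
#' `steps_per_stage` forward Euler steps of size `h`; the product must be 1.
#'
#' @param steps_per_stage Euler steps per field (default 5).
#' @param h step size (default 0.2).
#' @return an object of class `integration_config`.
#' @export
integration_config <- function(steps_per_stage = 5L, h = 0.2) {
  if (abs(steps_per_stage * h - 1) > 1e-9)
    stopf("steps_per_stage * h must equal 1 (each field integrates unit time)")
  structure(list(steps_per_stage = as.integer(steps_per_stage), h = h),
            class = "integration_config")
}

#' Sample a flow field at continuous world positions
#'
#' Trilinear interpolation of a vector grid at arbitrary world coordinates;
#' positions outside the grid are clamped to the boundary first.
#'
#' @param field array `c(3, gx, gy, gz)` of flow vectors.
#' @param points M x 3 world coordinates (mm).
#' @param grid_shape,spacing geometry of the volume the field covers.
#' @return M x 3 matrix of interpolated vectors.
#' @export
sample_flow <- function(field, points, grid_shape, spacing) {
  points <- as.matrix(points)
  if (any(!is.finite(points))) stopf("'points' must be finite")
  geo <- field_geometry(field, grid_shape, spacing)
  .sample_flow_cpp(field, geo$origin, geo$spacing, points)
}

#' Deform a template mesh through a flow stack by Euler integration
#'
#' For stage i = 1..5 the vertex update `x <- x + h * Phi_i(x)` is applied
#' `steps_per_stage` times; in stages 1-4 each vertex follows the field of its
#' organ (via `organ_routing`), in stage 5 all vertices follow the shared
#' field. Connectivity, `component_id` and `vertex_uid` never change, so the
#' output vertices correspond one-to-one to the template's.
#'
#' @param mesh template [trimesh()].
#' @param flows a [flow_stack()].
#' @param cfg an [integration_config()].
#' @param organ_routing integer vector mapping each component id to its
#'   per-organ field index in stages 1-4; defaults to the identity mapping.
#' @param keep_cache keep the integration tape needed for the training
#'   backward pass (internal).
#' @return list with `mesh` (final [trimesh()]) and `stage_meshes` (the five
#'   post-stage meshes used for deep mesh supervision; the fifth equals
#'   `mesh`), plus `cache` when requested.
#' @export
euler_integrate <- function(mesh, flows, cfg = integration_config(),
                            organ_routing = NULL, keep_cache = FALSE) {
  stopifnot(inherits(flows, "flow_stack"), inherits(cfg, "integration_config"))
  comps <- sort(unique(mesh$component_id))
  k_fields <- length(flows$fields[[1]])
  if (is.null(organ_routing)) organ_routing <- seq_along(comps)
  if (length(organ_routing) != length(comps))
    stopf("'organ_routing' must map every mesh component (in sorted id order)")
  if (any(organ_routing < 1 | organ_routing > k_fields))
    stopf("routing index outside 1..%d", k_fields)
  for (st in flows$fields) for (f in st)
    if (any(!is.finite(f))) stopf("flow field contains NaN/Inf")
  x <- mesh$vertices
  stage_meshes <- vector("list", 5)
  cache <- if (keep_cache) vector("list", 5) else NULL
  for (s in 1:5) {
    st <- flows$fields[[s]]
    stage_cache <- list()
    if (s < 5) {
      groups <- split(seq_along(comps), organ_routing)
      for (gname in names(groups)) {
        fi <- as.integer(gname)
        rows <- which(mesh$component_id %in% comps[groups[[gname]]])
        geo <- field_geometry(st[[fi]], flows$grid_shape, flows$spacing)
        res <- .euler_fwd_cpp(x[rows, , drop = FALSE], st[[fi]], geo$origin,
                              geo$spacing, cfg$h, cfg$steps_per_stage)
        x[rows, ] <- res$x
        if (keep_cache)
          stage_cache[[length(stage_cache) + 1]] <-
            list(rows = rows, field_index = fi, traj = res$traj, geo = geo)
      }
    } else {
      geo <- field_geometry(st[[1]], flows$grid_shape, flows$spacing)
      res <- .euler_fwd_cpp(x, st[[1]], geo$origin, geo$spacing, cfg$h,
                            cfg$steps_per_stage)
      x <- res$x
      if (keep_cache)
        stage_cache[[1]] <- list(rows = seq_len(nrow(x)), field_index = 1L,
                                 traj = res$traj, geo = geo)
    }
    m <- mesh
    m$vertices <- x
    stage_meshes[[s]] <- m
    if (keep_cache) cache[[s]] <- stage_cache
  }
  out <- list(mesh = stage_meshes[[5]], stage_meshes = stage_meshes)
  if (keep_cache) out$cache <- cache
  out
}

# reverse-mode of euler_integrate: g_stage is a list of 5 vertex-gradient
# matrices (NULL where a stage receives no loss). Returns gradients for every
# field grid (same nesting as flows$fields) and for the template vertices.
euler_integrate_backward <- function(mesh, flows, cfg, cache, g_stage) {
  g_fields <- lapply(flows$fields, function(st) lapply(st, function(f) {
    g <- array(0, dim = dim(f)); g
  }))
  n <- n_vertices(mesh)
  gx <- matrix(0, n, 3)
  for (s in 5:1) {
    if (!is.null(g_stage[[s]])) gx <- gx + g_stage[[s]]
    for (grp in cache[[s]]) {
      f <- flows$fields[[s]][[grp$field_index]]
      res <- .euler_bwd_cpp(grp$traj, f, grp$geo$origin, grp$geo$spacing,
                            cfg$h, cfg$steps_per_stage,
                            gx[grp$rows, , drop = FALSE])
      gx[grp$rows, ] <- res$g_x
      g_fields[[s]][[grp$field_index]] <-
        g_fields[[s]][[grp$field_index]] + res$g_field
    }
  }
  list(g_fields = g_fields, g_vertices = gx)
}
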