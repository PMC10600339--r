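#' Training configuration
#'
#' AdamW (beta1 = 0.9, beta2 = 0.999) with a triangular cyclic learning-rate
#' schedule (base rate 1e-4); the best epoch is selected by validation ASSD.
#'
#' @param base_lr cyclic schedule floor (default 1e-4).
#' @param max_lr cyclic schedule ceiling (a documented knob; default 5e-3 at
#'   desk scale).
#' @param cycle_epochs full triangle length in epochs (default 10).
#' @param batch_size volumes per optimiser step (default 2).
#' @param max_epochs hard epoch limit (default 30).
#' @param weight_decay AdamW decoupled weight decay on conv weights.
#' @param lambda edge-loss weight (default 10).
#' @param n_surface_points Chamfer samples per organ per stage during training.
#' @param val_points surface samples per side for validation ASSD.
#' @param seed seed for init, data order and sampling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(base_lr = 1e-4, max_lr = 5e-3, cycle_epochs = 10L,
                         batch_size = 2L, max_epochs = 30L,
                         weight_decay = 0.01, lambda = 10,
                         n_surface_points = 1500L, val_points = 2000L,
                         seed = 1L) {
  if (base_lr <= 0 || max_lr < base_lr) stopf("need 0 < base_lr <= max_lr")
  if (max_epochs < 1) stopf("'max_epochs' must be >= 1")
  structure(list(base_lr = base_lr, max_lr = max_lr,
                 cycle_epochs = as.integer(cycle_epochs),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, lambda = lambda,
                 n_surface_points = as.integer(n_surface_points),
                 val_points = as.integer(val_points),
                 seed = as.integer(seed)),
            class = "train_config")
}

# triangular cyclic LR, evaluated at a (0-based) epoch
cyclic_lr <- function(epoch, cfg) {
  half <- cfg$cycle_epochs / 2
  pos <- epoch %% cfg$cycle_epochs
  frac <- if (pos < half) pos / half else (cfg$cycle_epochs - pos) / half
  cfg$base_lr + (cfg$max_lr - cfg$base_lr) * frac
}

# organ routing for a template: component -> per-organ field index; components
# sharing a class label (e.g. two kidney lobes) share a field
template_routing <- function(template) {
  as.integer(factor(template$organ_of_component,
                    levels = sort(unique(template$organ_of_component))))
}

# per-sample ground truth bundle used by the loss
make_gt <- function(sample, template, n_cloud = 2000L) {
  organs <- sort(unique(template$organ_of_component))
  clouds <- lapply(seq_along(template$organ_of_component), function(ci) {
    org <- template$organ_of_component[ci]
    sample_surface(sample$gt_meshes[[org]], n_cloud)$points
  })
  # labels may exceed the template's classes only if data and template disagree
  list(labels = sample$labels, clouds = clouds)
}

# validation ASSD: mean over organs and cases, unregistered meshes
validation_assd <- function(params, net_cfg, template, val_samples, icfg,
                            routing, val_points, spacing) {
  vals <- vapply(val_samples, function(sm) {
    fw <- net_forward(sm$intensity, params, net_cfg, spacing = spacing)
    de <- euler_integrate(template$mesh, fw$flows, icfg, routing)
    organs <- sort(unique(template$organ_of_component))
    per <- vapply(organs, function(org) {
      sub <- subset_mesh_by_organ(de$mesh, template, org)
      assd(sub, sm$gt_meshes[[org]], n_points = val_points)
    }, 0)
    mean(per)
  }, 0)
  mean(vals)
}

# extract all components of one organ label as a single mesh
subset_mesh_by_organ <- function(mesh, template, organ) {
  comps <- which(template$organ_of_component == organ)
  keep <- mesh$component_id %in% comps
  remap <- integer(n_vertices(mesh))
  remap[keep] <- seq_len(sum(keep))
  fkeep <- mesh$component_id[mesh$faces[, 1]] %in% comps
  trimesh(mesh$vertices[keep, , drop = FALSE],
          matrix(remap[mesh$faces[fkeep, , drop = FALSE]], ncol = 3),
          component_id = mesh$component_id[keep],
          vertex_uid = mesh$vertex_uid[keep])
}

#' Train the flow-prediction network on phantom samples
#'
#' Per step: forward pass, Euler integration of the template, deeply
#' supervised voxel + mesh loss, AdamW update. Per epoch: validation ASSD
#' (mesh, mean over organs, unregistered) is logged and the best-epoch
#' parameters are retained. Fully seeded: two runs with the same seed produce
#' identical loss curves on one platform.
#'
#' @param train_samples,val_samples lists of `phantom_sample` objects (or any
#'   list with `intensity`, `labels`, `gt_meshes`).
#' @param template a [build_template()] result.
#' @param net_cfg a [net_config()].
#' @param train_cfg a [train_config()].
#' @param icfg an [integration_config()].
#' @param init optional `net_params` to resume from (fine-tuning); heads are
#'   NOT re-zeroed.
#' @param log_path optional JSON-lines file receiving one record per step.
#' @param quiet suppress progress output.
#' @return a `flow_checkpoint`: list with `params` (best epoch), `net_cfg`,
#'   `train_cfg`, `icfg`, `template`, `epoch`, `val_assd` and `history`
#'   (tibble of per-epoch train loss and validation ASSD).
#' @export
train <- function(train_samples, val_samples, template, net_cfg,
                  train_cfg = train_config(), icfg = integration_config(),
                  init = NULL, log_path = NULL, quiet = TRUE) {
  spacing <- template$spacing
  routing <- template_routing(template)
  if (net_cfg$k_fields < max(routing))
    stopf("net k_fields (%d) cannot route %d organ groups",
          net_cfg$k_fields, max(routing))
  with_seed(train_cfg$seed, {
    params <- if (is.null(init)) init_params(net_cfg, seed = derive_seed(train_cfg$seed, 77L))
              else init
    opt <- adamw_init(params)
    best <- list(params = params, epoch = 0L, val_assd = Inf)
    history <- list()
    n_tr <- length(train_samples)
    # epoch-0 (pre-update) validation: identity deformation under zero init
    va0 <- validation_assd(params, net_cfg, template, val_samples, icfg,
                           routing, train_cfg$val_points, spacing)
    best$val_assd <- va0
    history[[1]] <- tibble::tibble(epoch = 0L, lr = NA_real_,
                                   train_loss = NA_real_, ce = NA_real_,
                                   chamfer = NA_real_, edge = NA_real_,
                                   val_assd = va0)
    for (epoch in seq_len(train_cfg$max_epochs)) {
      lr <- cyclic_lr(epoch - 1, train_cfg)
      order <- sample.int(n_tr)
      ep_losses <- c(total = 0, ce = 0, chamfer = 0, edge = 0)
      nb <- 0
      for (start in seq(1, n_tr, by = train_cfg$batch_size)) {
        batch <- order[start:min(start + train_cfg$batch_size - 1, n_tr)]
        gacc <- NULL
        bl <- c(total = 0, ce = 0, chamfer = 0, edge = 0)
        for (bi in batch) {
          sm <- train_samples[[bi]]
          gt <- make_gt(sm, template, n_cloud = train_cfg$n_surface_points)
          fw <- net_forward(sm$intensity, params, net_cfg, keep_cache = TRUE,
                            spacing = spacing)
          de <- euler_integrate(template$mesh, fw$flows, icfg, routing,
                                keep_cache = TRUE)
          tl <- total_loss_fwd(fw, de$stage_meshes, gt, net_cfg,
                               lambda = train_cfg$lambda,
                               n_surface_points = train_cfg$n_surface_points)
          if (!is.finite(tl$breakdown$total))
            stopf("NaN/Inf loss at epoch %d; last good checkpoint is epoch %d",
                  epoch, best$epoch)
          lb <- total_loss_bwd(tl, net_cfg)
          ei <- euler_integrate_backward(template$mesh, fw$flows, icfg,
                                         de$cache, lb$g_stage)
          gr <- net_backward(fw$cache, params, net_cfg, ei$g_fields,
                             lb$g_seg, lb$g_deep)
          gacc <- if (is.null(gacc)) gr else add_grads(gacc, gr)
          bl <- bl + c(tl$breakdown$total, tl$breakdown$ce,
                       tl$breakdown$chamfer, tl$breakdown$edge)
        }
        gacc <- scale_grads(gacc, 1 / length(batch))
        stp <- adamw_step(params, gacc, opt, lr,
                          weight_decay = train_cfg$weight_decay)
        params <- stp$params
        opt <- stp$state
        nb <- nb + 1
        ep_losses <- ep_losses + bl / length(batch)
        log_jsonl(log_path, list(epoch = epoch, step = nb, lr = lr,
                                 total = bl[["total"]] / length(batch),
                                 ce = bl[["ce"]] / length(batch),
                                 chamfer = bl[["chamfer"]] / length(batch),
                                 edge = bl[["edge"]] / length(batch)))
      }
      ep_losses <- ep_losses / nb
      va <- validation_assd(params, net_cfg, template, val_samples, icfg,
                            routing, train_cfg$val_points, spacing)
      history[[epoch + 1]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = ep_losses[["total"]],
        ce = ep_losses[["ce"]], chamfer = ep_losses[["chamfer"]],
        edge = ep_losses[["edge"]], val_assd = va)
      if (va < best$val_assd) {
        best <- list(params = params, epoch = epoch, val_assd = va)
      }
      if (!quiet)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val ASSD %.3f mm%s",
                        epoch, lr, ep_losses[["total"]], va,
                        if (best$epoch == epoch) "  *" else ""))
    }
    structure(list(params = best$params, net_cfg = net_cfg,
                   train_cfg = train_cfg, icfg = icfg, template = template,
                   epoch = best$epoch, val_assd = best$val_assd,
                   history = do.call(rbind, history)),
              class = "flow_checkpoint")
  })
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) { a[[nm]] <- b[[nm]]; next }
    for (gn in names(b[[nm]])) a[[nm]][[gn]] <- a[[nm]][[gn]] + b[[nm]][[gn]]
  }
  a
}

scale_grads <- function(a, s) {
  for (nm in names(a)) for (gn in names(a[[nm]])) a[[nm]][[gn]] <- a[[nm]][[gn]] * s
  a
}

#' Fine-tune a trained checkpoint on new data
#'
#' Resumes the checkpoint's parameters with a fresh optimiser state; output
#' heads are NOT re-zeroed. Training then proceeds exactly as in [train()].
#'
#' @param checkpoint a `flow_checkpoint`.
#' @param train_samples,val_samples the new dataset.
#' @param train_cfg a [train_config()] for the fine-tuning run.
#' @param template optional replacement template; defaults to the
#'   checkpoint's. Its class count must match the checkpoint's network.
#' @return a new `flow_checkpoint`.
#' @export
finetune <- function(checkpoint, train_samples, val_samples,
                     train_cfg = train_config(), template = NULL) {
  template <- template %||% checkpoint$template
  k_needed <- max(template_routing(template))
  if (checkpoint$net_cfg$k_fields < k_needed)
    stopf("checkpoint has %d per-organ fields but the new template needs %d",
          checkpoint$net_cfg$k_fields, k_needed)
  train(train_samples, val_samples, template, checkpoint$net_cfg, train_cfg,
        checkpoint$icfg, init = checkpoint$params)
}

#' Predict meshes and voxel segmentation for one volume
#'
#' Deterministic: forward pass, Euler integration of the checkpoint's
#' template, and (with the voxel branch) the argmax class map.
#'
#' @param checkpoint a `flow_checkpoint`.
#' @param volume 3D intensity array matching the network input shape.
#' @return list with `meshes` (per-organ list of [trimesh()], indexed by class
#'   label), `mesh` (all organs in one mesh), and `seg` (3D integer array, or
#'   `NULL` with the voxel branch off).
#' @export
predict_volume <- function(checkpoint, volume) {
  template <- checkpoint$template
  routing <- template_routing(template)
  fw <- net_forward(volume, checkpoint$params, checkpoint$net_cfg,
                    spacing = template$spacing)
  de <- euler_integrate(template$mesh, fw$flows, checkpoint$icfg, routing)
  organs <- sort(unique(template$organ_of_component))
  meshes <- stats::setNames(vector("list", max(organs)), seq_len(max(organs)))
  for (org in organs)
    meshes[[org]] <- subset_mesh_by_organ(de$mesh, template, org)
  seg <- NULL
  if (checkpoint$net_cfg$use_voxel_branch) {
    d <- dim(fw$seg_logits)
    seg <- array(max.col(t(matrix(fw$seg_logits, d[1])), ties.method = "first") - 1L,
                 dim = d[2:4])
  }
  list(meshes = meshes, mesh = de$mesh, seg = seg,
       stage_meshes = de$stage_meshes)
}

#' Save / load a checkpoint as a JSON archive
#'
#' Text-based round trip of parameters, configs and history; parameter values
#' survive bit-exactly (doubles are serialised losslessly).
#'
#' @param checkpoint a `flow_checkpoint`.
#' @param path file path (`.json.gz` recommended).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  ser <- list(
    params = lapply(checkpoint$params, function(p)
      lapply(p, function(a) list(dim = dim(a) %||% length(a), data = as.vector(a)))),
    net_cfg = unclass(checkpoint$net_cfg),
    train_cfg = unclass(checkpoint$train_cfg),
    icfg = unclass(checkpoint$icfg),
    epoch = checkpoint$epoch,
    val_assd = checkpoint$val_assd,
    history = as.data.frame(checkpoint$history),
    template = list(
      vertices = checkpoint$template$mesh$vertices,
      faces = checkpoint$template$mesh$faces,
      component_id = checkpoint$template$mesh$component_id,
      vertex_uid = checkpoint$template$mesh$vertex_uid,
      organ_of_component = checkpoint$template$organ_of_component,
      grid_shape = checkpoint$template$grid_shape,
      spacing = checkpoint$template$spacing))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::serializeJSON(ser, digits = 17), con)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::unserializeJSON(paste(readLines(gzfile(path)), collapse = "\n"))
  params <- lapply(ser$params, function(p)
    lapply(p, function(a) {
      if (length(a$dim) > 1) array(a$data, dim = a$dim) else a$data
    }))
  class(params) <- "net_params"
  tmpl <- structure(list(
    mesh = trimesh(ser$template$vertices, ser$template$faces,
                   component_id = ser$template$component_id,
                   vertex_uid = ser$template$vertex_uid),
    organ_of_component = ser$template$organ_of_component,
    grid_shape = ser$template$grid_shape,
    spacing = ser$template$spacing), class = "mesh_template")
  structure(list(params = params,
                 net_cfg = structure(ser$net_cfg, class = "net_config"),
                 train_cfg = structure(ser$train_cfg, class = "train_config"),
                 icfg = structure(ser$icfg, class = "integration_config"),
                 template = tmpl, epoch = ser$epoch, val_assd = ser$val_assd,
                 history = tibble::as_tibble(ser$history)),
            class = "flow_checkpoint")
}

#' @export
print.flow_checkpoint <- function(x, ...) {
  cat(sprintf("<flow_checkpoint> best epoch %d, val ASSD %.3f mm, %d parameters\n",
              x$epoch, x$val_assd, n_params(x$params)))
  invisible(x)
}

#' Broom-style accessors for a trained checkpoint
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary.
#'
#' @param x a `flow_checkpoint`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.flow_checkpoint <- function(x, ...) x$history

#' @rdname tidy.flow_checkpoint
#' @export
glance.flow_checkpoint <- function(x, ...) {
  tibble::tibble(best_epoch = x$epoch, val_assd_mm = x$val_assd,
                 n_params = n_params(x$params),
                 epochs_run = max(x$history$epoch))
}

#' Plot training history
#'
#' @param checkpoint a `flow_checkpoint`.
#' @return a ggplot object with train loss and validation ASSD per epoch.
#' @export
plot_history <- function(checkpoint) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("ggplot2 is required for plotting")
  h <- as.data.frame(checkpoint$history)
  df <- rbind(
    data.frame(epoch = h$epoch, value = h$train_loss, series = "train loss"),
    data.frame(epoch = h$epoch, value = h$val_assd, series = "val ASSD (mm)"))
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Run the deep-mesh-supervision / voxel-branch ablation grid
#'
#' Trains one model per (DMS, VB) configuration with shared seeds and data and
#' reports validation metrics per configuration.
#'
#' @param train_samples,val_samples dataset lists.
#' @param template a [build_template()] result.
#' @param net_cfg base [net_config()]; its DMS/VB flags are overridden.
#' @param train_cfg a [train_config()].
#' @param grid data frame with logical columns `dms` and `vb` (default: the
#'   full 2x2 grid).
#' @param seeds integer vector of seeds to average over.
#' @return a tibble with one row per configuration and seed: mean validation
#'   Dice, ASSD and SIF over organs, plus the configuration flags.
#' @export
run_ablation <- function(train_samples, val_samples, template, net_cfg,
                         train_cfg = train_config(),
                         grid = expand.grid(dms = c(FALSE, TRUE),
                                            vb = c(FALSE, TRUE)),
                         seeds = 1L) {
  if (nrow(grid) < 2) stopf("need at least 2 configurations")
  rows <- list()
  for (seed in seeds) {
    for (i in seq_len(nrow(grid))) {
      cfg <- net_cfg
      cfg$use_deep_mesh_supervision <- grid$dms[i]
      cfg$use_voxel_branch <- grid$vb[i]
      tc <- train_cfg
      tc$seed <- as.integer(seed)
      ck <- train(train_samples, val_samples, template, cfg, tc)
      ev <- evaluate_checkpoint(ck, val_samples)
      rows[[length(rows) + 1]] <- tibble::tibble(
        dms = grid$dms[i], vb = grid$vb[i], seed = seed,
        dice = mean(ev$dice), assd_mm = mean(ev$assd_mm),
        sif_pct = mean(ev$sif_pct))
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a checkpoint on a sample list
#'
#' @param checkpoint a `flow_checkpoint`.
#' @param samples list of phantom samples.
#' @param registration passed to [align_to_voxels()] (`"none"` by default).
#' @param n_points surface samples per side for distances.
#' @return a `metric_report` tibble from [evaluate_cases()].
#' @export
evaluate_checkpoint <- function(checkpoint, samples, registration = "none",
                                n_points = 4000L) {
  preds <- lapply(samples, function(sm) {
    pr <- predict_volume(checkpoint, sm$intensity)
    if (registration != "none" && !is.null(pr$seg))
      pr$meshes <- align_to_voxels(pr$meshes, pr$seg,
                                   checkpoint$template$spacing,
                                   mode = registration)
    pr$meshes
  })
  evaluate_cases(preds, lapply(samples, `[[`, "labels"),
                 checkpoint$template$spacing,
                 gt_meshes = lapply(samples, `[[`, "gt_meshes"),
                 n_points = n_points)
}
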