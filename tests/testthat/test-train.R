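# a tiny shared training setup (2 organs, 16^3) kept cheap enough for units
tiny_setup <- function(n_train = 4, n_val = 2, seed = 71L) {
  spec <- tiny_spec(seed)
  tr <- lapply(seq_len(n_train) - 1, function(i) generate_phantom(spec, i))
  va <- lapply(10000 + seq_len(n_val) - 1, function(i) generate_phantom(spec, i))
  tmpl <- build_template(lapply(tr, `[[`, "labels"), spec$spacing)
  list(spec = spec, tr = tr, va = va, tmpl = tmpl)
}

test_that("epoch-0 validation ASSD equals the template-to-gt ASSD", {
  s <- tiny_setup()
  cfg <- tiny_net_config()
  tc <- train_config(max_epochs = 1L, seed = 2L, val_points = 1000L,
                     n_surface_points = 300L)
  ck <- train(s$tr, s$va, s$tmpl, cfg, tc)
  va0 <- ck$history$val_assd[ck$history$epoch == 0]
  # direct computation: the zero-initialised model deforms nothing
  ref <- with_seed(2L, {
    flowmesh:::validation_assd(init_params(cfg, derive_seed(2L, 77L)), cfg,
                               s$tmpl, s$va, integration_config(),
                               flowmesh:::template_routing(s$tmpl), 1000L,
                               s$spec$spacing)
  })
  tmpl_assd <- mean(sapply(s$va, function(sm) {
    mean(sapply(1:2, function(org) {
      sub <- flowmesh:::subset_mesh_by_organ(s$tmpl$mesh, s$tmpl, org)
      assd(sub, sm$gt_meshes[[org]], n_points = 1000)
    }))
  }))
  expect_equal(va0, ref, tolerance = 0.05)
  expect_equal(va0, tmpl_assd, tolerance = 0.1)
})

test_that("a short training run descends and selects the best epoch", {
  s <- tiny_setup()
  cfg <- tiny_net_config()
  tc <- train_config(max_epochs = 4L, seed = 3L, val_points = 500L,
                     n_surface_points = 300L, batch_size = 2L)
  ck <- train(s$tr, s$va, s$tmpl, cfg, tc)
  h <- ck$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[2])
  expect_equal(ck$val_assd, min(h$val_assd))
  expect_equal(ck$epoch, h$epoch[which.min(h$val_assd)])
  expect_s3_class(tidy(ck), "tbl_df")
  g <- glance(ck)
  expect_equal(g$best_epoch, ck$epoch)
  expect_equal(g$n_params, n_params(ck$params))
})

test_that("training is bitwise deterministic under a fixed seed", {
  s <- tiny_setup(n_train = 2, n_val = 1)
  cfg <- tiny_net_config()
  tc <- train_config(max_epochs = 2L, seed = 11L, val_points = 300L,
                     n_surface_points = 200L)
  a <- train(s$tr, s$va, s$tmpl, cfg, tc)
  b <- train(s$tr, s$va, s$tmpl, cfg, tc)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("prediction at zero-init returns the template; reruns are identical", {
  s <- tiny_setup(n_train = 2, n_val = 1)
  cfg <- tiny_net_config()
  ck <- structure(list(params = init_params(cfg, 1), net_cfg = cfg,
                       icfg = integration_config(), template = s$tmpl,
                       train_cfg = train_config(), epoch = 0L,
                       val_assd = NA_real_, history = NULL),
                  class = "flow_checkpoint")
  pr <- predict_volume(ck, s$tr[[1]]$intensity)
  expect_identical(pr$mesh$vertices, s$tmpl$mesh$vertices)
  expect_length(pr$meshes, 2)
  expect_equal(dim(pr$seg), dim(s$tr[[1]]$labels))
  pr2 <- predict_volume(ck, s$tr[[1]]$intensity)
  expect_identical(pr$mesh$vertices, pr2$mesh$vertices)
  expect_identical(pr$seg, pr2$seg)
})

test_that("checkpoints round-trip bit-exactly through the JSON archive", {
  s <- tiny_setup(n_train = 2, n_val = 1)
  cfg <- tiny_net_config()
  tc <- train_config(max_epochs = 1L, seed = 5L, val_points = 300L,
                     n_surface_points = 200L)
  ck <- train(s$tr, s$va, s$tmpl, cfg, tc)
  path <- withr::local_tempfile(fileext = ".json.gz")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, ck$params)
  expect_identical(back$template$mesh$vertices, ck$template$mesh$vertices)
  expect_equal(back$epoch, ck$epoch)
  # loaded checkpoints predict identically
  p1 <- predict_volume(ck, s$tr[[1]]$intensity)
  p2 <- predict_volume(back, s$tr[[1]]$intensity)
  expect_identical(p1$mesh$vertices, p2$mesh$vertices)
})

test_that("fine-tuning resumes parameters and rejects incompatible templates", {
  s <- tiny_setup(n_train = 2, n_val = 1)
  cfg <- tiny_net_config()
  tc <- train_config(max_epochs = 1L, seed = 7L, val_points = 300L,
                     n_surface_points = 200L)
  ck <- train(s$tr, s$va, s$tmpl, cfg, tc)
  ck2 <- finetune(ck, s$tr, s$va, tc)
  expect_s3_class(ck2, "flow_checkpoint")
  # heads are not re-zeroed on resume: the fine-tuned start is the checkpoint
  expect_gt(max(abs(ck$params$flow_head4$w)), 0)
  # a template needing more per-organ fields than the net provides fails
  fake <- s$tmpl
  fake$organ_of_component <- 1:3
  expect_error(finetune(ck, s$tr, s$va, tc, template = fake), "fields")
})

test_that("the ablation grid trains every configuration on shared data", {
  s <- tiny_setup(n_train = 2, n_val = 1)
  cfg <- tiny_net_config()
  tc <- train_config(max_epochs = 1L, seed = 13L, val_points = 300L,
                     n_surface_points = 200L)
  grid <- expand.grid(dms = c(FALSE, TRUE), vb = TRUE)
  tab <- run_ablation(s$tr, s$va, s$tmpl, cfg, tc, grid = grid, seeds = 1L)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("dice", "assd_mm", "sif_pct") %in% names(tab)))
  expect_error(run_ablation(s$tr, s$va, s$tmpl, cfg, tc,
                            grid = expand.grid(dms = TRUE, vb = TRUE)),
               "2 configurations")
})
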