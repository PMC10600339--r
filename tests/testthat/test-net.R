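test_that("config validates shape divisibility and class count", {
  expect_error(net_config(input_shape = c(24L, 24L, 24L)), "divisible")
  expect_error(net_config(n_classes = 1L), "n_classes")
  cfg <- net_config(base_channels = 4L)
  expect_equal(cfg$channels, c(4L, 8L, 16L, 32L, 32L))
})

test_that("decoder emits flow grids at doubling resolutions", {
  cfg <- tiny_net_config()
  params <- init_params(cfg, 1)
  set.seed(2)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  fw <- net_forward(vol, params, cfg)
  res <- sapply(fw$flows$fields, function(s) dim(s[[1]])[2])
  expect_equal(res, c(1, 2, 4, 8, 16))
  expect_length(fw$flows$fields[[1]], cfg$k_fields)
  expect_length(fw$flows$fields[[5]], 1)           # shared final field
  expect_equal(dim(fw$seg_logits), c(cfg$n_classes, 16, 16, 16))
  expect_named(fw$deep_seg_logits, c("2", "3"))
  expect_error(net_forward(array(0, c(8, 8, 8)), params, cfg), "match")
})

test_that("zero-initialised heads give exactly zero flow for any input", {
  cfg <- tiny_net_config()
  params <- init_params(cfg, 3)
  for (w in params[grepl("head", names(params))])
    expect_equal(max(abs(w$w)), 0)
  for (rep in 1:3) {
    vol <- array(rnorm(16^3, sd = 10), c(16, 16, 16))
    fw <- net_forward(vol, params, cfg)
    for (st in fw$flows$fields) for (f in st) expect_equal(max(abs(f)), 0)
  }
})

test_that("initialisation is seeded and reproducible", {
  cfg <- tiny_net_config()
  a <- init_params(cfg, 42)
  b <- init_params(cfg, 42)
  expect_identical(a, b)
  c <- init_params(cfg, 43)
  expect_false(identical(a, c))
  # parameter count is config-derived and stable
  expect_identical(n_params(a), n_params(c))
})

test_that("the voxel-branch ablation removes all segmentation outputs", {
  cfg <- tiny_net_config(use_voxel_branch = FALSE)
  params <- init_params(cfg, 1)
  expect_false(any(grepl("seg_head", names(params))))
  vol <- array(rnorm(16^3), c(16, 16, 16))
  fw <- net_forward(vol, params, cfg)
  expect_null(fw$seg_logits)
  expect_length(fw$deep_seg_logits, 0)
})

test_that("shifting the input changes the output (no global collapse)", {
  cfg <- tiny_net_config()
  params <- init_params(cfg, 9)
  # make a head nonzero so flows respond to features
  params$flow_head4$w <- matrix(0.05, nrow(params$flow_head4$w),
                                ncol(params$flow_head4$w))
  set.seed(5)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  shifted <- vol[c(2:16, 1), , ]
  f1 <- net_forward(vol, params, cfg)$flows$fields[[5]][[1]]
  f2 <- net_forward(shifted, params, cfg)$flows$fields[[5]][[1]]
  expect_gt(max(abs(f1 - f2)), 1e-8)
})

test_that("network gradients agree with finite differences", {
  cfg <- tiny_net_config()
  params <- init_params(cfg, 5)
  set.seed(11)
  for (nm in names(params)) if (grepl("head", nm)) {
    params[[nm]]$w <- matrix(rnorm(length(params[[nm]]$w), 0, 0.05),
                             nrow(params[[nm]]$w))
  }
  vol <- array(rnorm(16^3), c(16, 16, 16))
  labs <- array(sample(0:2, 16^3, replace = TRUE), c(16, 16, 16))
  # scalar loss: CE plus the mean of the final shared flow field
  loss_of <- function(p) {
    fw <- net_forward(vol, p, cfg, keep_cache = TRUE)
    list(value = cross_entropy(fw$seg_logits, labs) +
           mean(fw$flows$fields[[5]][[1]]), fw = fw)
  }
  r <- loss_of(params)
  g_fields <- lapply(1:5, function(s) NULL)
  gf5 <- array(1 / length(r$fw$flows$fields[[5]][[1]]),
               dim = dim(r$fw$flows$fields[[5]][[1]]))
  g_fields[[5]] <- list(gf5)
  cc <- flowmesh:::ce_fwd(r$fw$seg_logits, labs)
  gr <- flowmesh:::net_backward(r$fw$cache, params, cfg, g_fields,
                                g_seg = flowmesh:::ce_bwd(cc))
  # central differences: eps balances truncation against cancellation noise
  eps <- 1e-4
  checks <- list(c("enc0_in", "w", 3), c("enc3_r2", "w", 17),
                 c("dec2_up", "w", 40), c("dec4_c1", "b", 2),
                 c("enc1_down", "gamma", 3), c("seg_head4", "w", 5),
                 c("flow_head4", "w", 2))
  for (ch in checks) {
    nm <- ch[1]; slot <- ch[2]; idx <- as.integer(ch[3])
    p2 <- params; p2[[nm]][[slot]][idx] <- p2[[nm]][[slot]][idx] + eps
    p3 <- params; p3[[nm]][[slot]][idx] <- p3[[nm]][[slot]][idx] - eps
    fd <- (loss_of(p2)$value - loss_of(p3)$value) / (2 * eps)
    gslot <- c(w = "w", b = "b", gamma = "g_gamma", beta = "g_beta")[[slot]]
    an <- gr[[nm]][[gslot]][idx]
    expect_equal(an, fd, tolerance = 2e-3)
  }
})

test_that("AdamW updates every parameter group and keeps shapes", {
  cfg <- tiny_net_config()
  params <- init_params(cfg, 2)
  opt <- flowmesh:::adamw_init(params)
  grads <- lapply(params, function(p) {
    g <- list(w = p$w * 0 + 0.1, b = p$b * 0 + 0.1)
    if (!is.null(p$gamma)) {
      g$g_gamma <- p$gamma * 0 + 0.1
      g$g_beta <- p$beta * 0 + 0.1
    }
    g
  })
  stp <- flowmesh:::adamw_step(params, grads, opt, lr = 1e-3)
  expect_identical(dim(stp$params$enc0_in$w), dim(params$enc0_in$w))
  expect_false(is.array(stp$params$enc0_in$b) && is.null(dim(params$enc0_in$b)))
  expect_lt(max(stp$params$enc2_r1$w - params$enc2_r1$w), 0)
  expect_equal(stp$state$step, 1L)
})
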