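test_that("cross entropy: uniform logits, confident limit, scalar-loop oracle", {
  C <- 5
  logits <- array(0, c(C, 3, 3, 3))
  labs <- array(sample(0:4, 27, replace = TRUE), c(3, 3, 3))
  expect_equal(cross_entropy(logits, labs), log(5), tolerance = 1e-12)
  # large margin on the true class drives the loss to zero
  conf <- array(0, c(C, 3, 3, 3))
  for (k in 1:3) for (j in 1:3) for (i in 1:3)
    conf[labs[i, j, k] + 1, i, j, k] <- 50
  expect_lt(cross_entropy(conf, labs), 1e-15)
  # random fixture equals the direct per-voxel evaluation
  set.seed(8)
  logits <- array(rnorm(C * 64), c(C, 4, 4, 4))
  labs <- array(sample(0:4, 64, replace = TRUE), c(4, 4, 4))
  expect_equal(cross_entropy(logits, labs), oracle_ce(logits, labs),
               tolerance = 1e-12)
  expect_error(cross_entropy(logits, labs + 4L), "labels")
})

test_that("chamfer: zero at identity, hand example, brute-force oracle", {
  set.seed(3)
  p <- matrix(runif(60), 20, 3)
  expect_equal(chamfer(p, p), 0)
  # gt = {origin}; pred = {(1,0,0), (0,1,0)}
  expect_equal(chamfer(rbind(c(1, 0, 0), c(0, 1, 0)), rbind(c(0, 0, 0))),
               1 + (1 + 1) / 2, tolerance = 1e-12)
  for (rep in 1:5) {
    a <- matrix(rnorm(150), 50, 3)
    b <- matrix(rnorm(120), 40, 3)
    expect_equal(chamfer(a, b), oracle_chamfer(a, b), tolerance = 1e-12)
  }
  # permutation invariance
  a <- matrix(rnorm(90), 30, 3); b <- matrix(rnorm(90), 30, 3)
  expect_equal(chamfer(a[sample(30), ], b[sample(30), ]), chamfer(a, b),
               tolerance = 1e-12)
})

test_that("edge loss: degenerate, regular tetrahedron, enumeration oracle", {
  v0 <- matrix(1, 4, 3)
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  expect_equal(edge_loss(trimesh(v0, f)), 0)
  # regular tetrahedron with unit edges
  tet <- trimesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
                   (2 * sqrt(2)), f)
  expect_equal(edge_loss(tet), 1, tolerance = 1e-12)
  m <- icosphere(1, r = 2)
  expect_equal(edge_loss(m), oracle_edge_loss(m), tolerance = 1e-12)
})

test_that("loss gradients match finite differences through sampling", {
  set.seed(13)
  m <- icosphere(0, r = 2)
  gtc <- matrix(rnorm(60, sd = 2), 20, 3)
  # the sampled (face, barycentric) pairs are held fixed: gradients flow
  # through the barycentric interpolation, not the discrete face draw
  s <- with_seed(5, sample_surface(m, 200))
  points_of <- function(verts) {
    f <- m$faces[s$face, , drop = FALSE]
    s$bary[, 1] * verts[f[, 1], , drop = FALSE] +
      s$bary[, 2] * verts[f[, 2], , drop = FALSE] +
      s$bary[, 3] * verts[f[, 3], , drop = FALSE]
  }
  loss_of <- function(verts) {
    m2 <- m; m2$vertices <- verts
    chamfer(points_of(verts), gtc) + 10 * edge_loss(m2)
  }
  base <- {
    cc <- flowmesh:::chamfer_fwd(points_of(m$vertices), gtc)
    g <- flowmesh:::chamfer_bwd(cc)
    flowmesh:::sample_surface_backward(m, s, g) +
      flowmesh:::edge_loss_bwd(m, gscale = 10)
  }
  eps <- 1e-6
  for (idx in c(1, 14, 30)) {
    v2 <- m$vertices; v2[idx] <- v2[idx] + eps
    v3 <- m$vertices; v3[idx] <- v3[idx] - eps
    fd <- (loss_of(v2) - loss_of(v3)) / (2 * eps)
    expect_equal(base[idx], fd, tolerance = 1e-3)
  }
})

test_that("total loss assembles Eq-style terms with deep supervision", {
  spec <- tiny_spec(33L)
  samples <- lapply(0:2, function(i) generate_phantom(spec, i))
  tmpl <- build_template(lapply(samples, `[[`, "labels"), spec$spacing)
  cfg <- tiny_net_config()
  params <- init_params(cfg, 4)
  gt <- with_seed(1, flowmesh:::make_gt(samples[[1]], tmpl, 300))
  fw <- net_forward(samples[[1]]$intensity, params, cfg, spacing = spec$spacing)
  de <- euler_integrate(tmpl$mesh, fw$flows, integration_config(),
                        flowmesh:::template_routing(tmpl))
  # zero-init: every stage mesh equals the template, so with DMS the mesh
  # terms are exactly five times the single-stage terms
  bd_on <- with_seed(2, total_loss(fw, de$stage_meshes, gt, cfg, lambda = 10,
                                   n_surface_points = 300))
  cfg_off <- cfg; cfg_off$use_deep_mesh_supervision <- FALSE
  bd_off <- with_seed(2, total_loss(fw, de$stage_meshes, gt, cfg_off, lambda = 10,
                                    n_surface_points = 300))
  expect_equal(bd_on$edge, 5 * bd_off$edge, tolerance = 1e-9)
  expect_equal(bd_on$chamfer / bd_off$chamfer, 5, tolerance = 0.2)
  single_ch <- with_seed(7, {
    s <- lapply(1:2, function(org) flowmesh:::sample_surface_comp(de$mesh, org, 300))
    chamfer(s[[1]]$points, gt$clouds[[1]]) + chamfer(s[[2]]$points, gt$clouds[[2]])
  })
  expect_equal(bd_off$chamfer, single_ch, tolerance = 0.5)
  # lambda = 0 removes the edge term
  bd0 <- with_seed(2, total_loss(fw, de$stage_meshes, gt, cfg, lambda = 0,
                                 n_surface_points = 300))
  expect_equal(bd0$total, bd0$ce + bd0$chamfer, tolerance = 1e-12)
  # total identity
  expect_equal(bd_on$total, bd_on$ce + bd_on$chamfer + 10 * bd_on$edge,
               tolerance = 1e-12)
  # VB off drops the CE term
  cfg_nvb <- tiny_net_config(use_voxel_branch = FALSE)
  params_nvb <- init_params(cfg_nvb, 4)
  fw_nvb <- net_forward(samples[[1]]$intensity, params_nvb, cfg_nvb,
                        spacing = spec$spacing)
  bd_nvb <- with_seed(2, total_loss(fw_nvb, de$stage_meshes, gt, cfg_nvb,
                                    n_surface_points = 300))
  expect_equal(bd_nvb$ce, 0)
})
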