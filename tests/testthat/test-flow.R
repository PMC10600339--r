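test_that("flow sampling: constant, node-exact, and linear fields", {
  gs <- c(16L, 16L, 16L)
  sp <- c(1, 1, 1)
  # constant field returns c everywhere, including far off-grid (clamping)
  f <- array(0, dim = c(3, 4, 4, 4))
  f[1, , , ] <- 2; f[2, , , ] <- -1; f[3, , , ] <- 0.5
  pts <- rbind(c(0, 0, 0), c(7.3, 2.2, 14.9), c(100, -50, 3))
  out <- sample_flow(f, pts, gs, sp)
  expect_equal(out, matrix(rep(c(2, -1, 0.5), each = 3), 3), tolerance = 1e-14)
  # query exactly at a grid node returns that node's vector
  set.seed(4)
  f2 <- array(rnorm(3 * 4^3), dim = c(3, 4, 4, 4))
  node_spacing <- 15 / 3   # 4 nodes span the 16-voxel world extent
  out2 <- sample_flow(f2, rbind(c(2, 1, 3) * node_spacing), gs, sp)
  expect_equal(as.vector(out2), f2[, 3, 2, 4], tolerance = 1e-12)
  # axis-aligned linear field is reproduced exactly by trilinear interpolation
  f3 <- array(0, dim = c(3, 4, 4, 4))
  for (i in 1:4) f3[1, i, , ] <- (i - 1) * node_spacing * 0.1
  qx <- c(1.7, 6.05, 11.3)
  out3 <- sample_flow(f3, cbind(qx, 5, 5), gs, sp)
  expect_equal(out3[, 1], 0.1 * qx, tolerance = 1e-12)
})

test_that("integration config enforces unit time per field", {
  expect_error(integration_config(5L, 0.3), "unit time")
  expect_silent(integration_config(10L, 0.1))
})

test_that("euler integration: identity, constant displacement, linear growth", {
  m <- icosphere(1, r = 3)
  m$vertices <- m$vertices + 8
  gs <- c(16L, 16L, 16L); sp <- c(1, 1, 1)
  zero <- flow_stack_zero(gs, sp, k_fields = 1L)
  cfg <- integration_config()
  out <- euler_integrate(m, zero, cfg)
  expect_identical(out$mesh$vertices, m$vertices)
  expect_identical(out$mesh$faces, m$faces)
  expect_length(out$stage_meshes, 5)
  # constant per-stage fields: total displacement is the sum (Euler exact)
  const <- zero
  shifts <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, -1), c(0.5, 0.5, 0), c(0, -1, 1))
  for (s in 1:5) for (c in 1:3) const$fields[[s]][[1]][c, , , ] <- shifts[s, c]
  out2 <- euler_integrate(m, const, cfg)
  expect_equal(out2$mesh$vertices, m$vertices +
                 matrix(colSums(shifts), n_vertices(m), 3, byrow = TRUE),
               tolerance = 1e-12)
  # linear field phi(x) = 0.1 x1 on the final stage only: x1 multiplies by
  # 1.02^5 (five steps of x <- x + 0.2 * 0.1 * x)
  lin <- zero
  g <- dim(lin$fields[[5]][[1]])[2]
  node <- (16 - 1) / (g - 1)
  for (i in seq_len(g)) lin$fields[[5]][[1]][1, i, , ] <- 0.1 * (i - 1) * node
  vm <- trimesh(rbind(c(1, 5, 5), c(2, 5, 5)), matrix(integer(0), 0, 3),
                component_id = c(1L, 1L))
  out3 <- euler_integrate(vm, lin, cfg)
  expect_equal(out3$mesh$vertices[1, 1], 1.02^5, tolerance = 1e-12)
  expect_equal(out3$mesh$vertices[2, 1], 2 * 1.02^5, tolerance = 1e-12)
})

test_that("per-organ routing applies each organ's field, shared final field", {
  s1 <- icosphere(0, r = 1); s1$vertices <- s1$vertices + 4
  s2 <- icosphere(0, r = 1); s2$vertices <- s2$vertices + 10
  m <- merge_meshes(list(s1, s2))
  gs <- c(16L, 16L, 16L); sp <- c(1, 1, 1)
  fl <- flow_stack_zero(gs, sp, k_fields = 2L)
  fl$fields[[1]][[1]][1, , , ] <- 1    # organ 1 moves +x in stage 1
  fl$fields[[1]][[2]][2, , , ] <- 1    # organ 2 moves +y
  fl$fields[[5]][[1]][3, , , ] <- 2    # everyone moves +2z in stage 5
  out <- euler_integrate(m, fl, integration_config(), organ_routing = c(1L, 2L))
  d1 <- out$mesh$vertices[m$component_id == 1, ] - m$vertices[m$component_id == 1, ]
  d2 <- out$mesh$vertices[m$component_id == 2, ] - m$vertices[m$component_id == 2, ]
  expect_equal(unique(round(d1, 9)), matrix(c(1, 0, 2), 1), ignore_attr = TRUE)
  expect_equal(unique(round(d2, 9)), matrix(c(0, 1, 2), 1), ignore_attr = TRUE)
})

test_that("NaN fields are rejected before integration", {
  m <- icosphere(0)
  fl <- flow_stack_zero(c(16L, 16L, 16L), c(1, 1, 1), 1L)
  fl$fields[[2]][[1]][1, 1, 1, 1] <- NaN
  expect_error(euler_integrate(m, fl, integration_config()), "NaN")
})

test_that("halving h shows first-order Euler convergence", {
  set.seed(31)
  gs <- c(16L, 16L, 16L); sp <- c(1, 1, 1)
  m <- icosphere(1, r = 3); m$vertices <- m$vertices + 8
  fl <- random_flow_stack(gs, sp, 1L, max_mag = 0.8)
  run <- function(steps) {
    cfg <- integration_config(steps, 1 / steps)
    euler_integrate(m, fl, cfg)$mesh$vertices
  }
  ref <- run(320L)
  e1 <- max(abs(run(5L) - ref))
  e2 <- max(abs(run(10L) - ref))
  e4 <- max(abs(run(20L) - ref))
  expect_gt(e1 / e2, 1.5); expect_lt(e1 / e2, 2.5)
  expect_gt(e2 / e4, 1.5); expect_lt(e2 / e4, 2.5)
})

test_that("small smooth flows keep an intersection-free mesh intersection-free", {
  set.seed(57)
  spec <- tiny_spec(91L)
  vols <- lapply(0:3, function(i) generate_phantom(spec, i)$labels)
  tmpl <- build_template(vols, spec$spacing)
  med_edge <- {
    e <- mesh_edges(tmpl$mesh)
    median(sqrt(rowSums((tmpl$mesh$vertices[e[, 1], ] - tmpl$mesh$vertices[e[, 2], ])^2)))
  }
  cfg <- integration_config()
  for (i in 1:5) {
    fl <- random_flow_stack(spec$grid_shape, spec$spacing, 2L,
                            max_mag = 0.1 * med_edge / cfg$h)
    out <- euler_integrate(tmpl$mesh, fl, cfg,
                           organ_routing = flowmesh:::template_routing(tmpl))
    expect_length(self_intersecting_faces(out$mesh), 0)
    expect_identical(out$mesh$faces, tmpl$mesh$faces)
    expect_identical(out$mesh$vertex_uid, tmpl$mesh$vertex_uid)
  }
})
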