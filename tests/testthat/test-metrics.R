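test_that("dice handles identity, disjoint, partial and empty masks", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[3:4, , ] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(e, e), 1)
  # |A| = |B| = 8, overlap 4
  a2 <- array(FALSE, c(4, 4, 4)); a2[1:8] <- TRUE
  b2 <- array(FALSE, c(4, 4, 4)); b2[5:12] <- TRUE
  expect_equal(dice(a2, b2), 0.5)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "differ")
})

test_that("voxelization inverts marching cubes and is translation-equivariant", {
  r <- 8
  dims <- c(24, 24, 24)
  ball <- ball_volume(dims, c(12, 12, 12), r)
  m <- marching_cubes(ball, c(1, 1, 1))
  vox <- voxelize(m, dims, c(1, 1, 1))
  expect_gte(dice(vox, ball), 0.95)
  # translation by exactly one voxel translates the mask
  m2 <- m; m2$vertices[, 1] <- m2$vertices[, 1] + 1
  vox2 <- voxelize(m2, dims, c(1, 1, 1))
  expect_identical(vox2[2:24, , ], vox[1:23, , ])
  # mesh entirely outside the grid gives an all-zero volume
  m3 <- m; m3$vertices <- m3$vertices + 100
  expect_equal(sum(voxelize(m3, dims, c(1, 1, 1))), 0)
  # open surfaces are rejected
  open_mesh <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_error(voxelize(open_mesh, dims, c(1, 1, 1)), "watertight")
})

test_that("assd: identity, collinear points, brute-force oracle, symmetry", {
  a <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(assd(a, a), 0)
  expect_equal(assd(rbind(c(0, 0, 0)), rbind(c(3, 0, 0))), 3)
  set.seed(17)
  for (rep in 1:5) {
    x <- matrix(rnorm(150), 50, 3)
    y <- matrix(rnorm(150, 1), 50, 3)
    expect_equal(assd(x, y), oracle_assd(x, y), tolerance = 1e-12)
    expect_equal(assd(x, y), assd(y, x), tolerance = 1e-12)
    # translation invariance
    expect_equal(assd(x + 5, y + 5), assd(x, y), tolerance = 1e-9)
  }
})

test_that("hd99: identity, symmetry, interpolated percentile, bounded by max", {
  a <- matrix(rnorm(90), 30, 3)
  expect_equal(hd99(a, a), 0)
  set.seed(19)
  x <- matrix(rnorm(300), 100, 3)
  y <- matrix(rnorm(300, 0.5), 100, 3)
  expect_equal(hd99(x, y), hd99(y, x), tolerance = 1e-12)
  expect_equal(hd99(x, y), oracle_hd(x, y, 0.99), tolerance = 1e-12)
  # 100 distances of ~1 and one outlier of ~50: the 99th percentile
  # interpolates between the two largest order statistics
  base <- cbind(seq(0, 99), 0, 0)
  offs <- rbind(cbind(seq(0, 99), 1, 0), c(200, 50, 0))
  expect_equal(hd99(offs, base), oracle_hd(offs, base, 0.99), tolerance = 1e-12)
  # robust percentile never exceeds the exact Hausdorff distance
  expect_lte(hd99(x, y), oracle_hd(x, y, 1) + 1e-12)
})

test_that("sif percentage is an exact per-component face fraction", {
  expect_equal(unname(sif_pct(icosphere(1))), 0)
  # 2 intersecting faces in a 200-face component -> 1%
  set.seed(23)
  m <- icosphere(2)   # 320 faces, no intersections
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
             c(0.5, 0.5, -1), c(1.5, 0.5, 1), c(0.5, 1.5, 1))
  cross <- trimesh(v + 5, rbind(c(1, 2, 3), c(4, 5, 6)),
                   component_id = rep(1L, 6))
  fixture <- merge_meshes(list(cross))
  expect_equal(unname(sif_pct(fixture)), 100)
  padded <- trimesh(rbind(v + 5, matrix(20 + runif(24), 8, 3)),
                    rbind(c(1, 2, 3), c(4, 5, 6),
                          t(replicate(198, sample(7:14, 3)))),
                    component_id = rep(1L, 14))
  sif <- self_intersecting_faces(padded)
  expect_equal(unname(sif_pct(padded)),
               100 * length(sif) / n_faces(padded))
  expect_true(all(c(1L, 2L) %in% sif))
})

test_that("evaluation reports per-case per-organ metrics with aggregation", {
  spec <- tiny_spec(29L)
  samples <- lapply(0:1, function(i) generate_phantom(spec, i))
  preds <- lapply(samples, `[[`, "gt_meshes")   # perfect predictions
  set.seed(1)
  rep <- evaluate_cases(preds, lapply(samples, `[[`, "labels"), spec$spacing,
                        gt_meshes = lapply(samples, `[[`, "gt_meshes"),
                        n_points = 1000L)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$dice > 0.97))
  # identical surfaces, so the residual is pure sampling noise
  expect_true(all(rep$assd_mm < 0.4))
  expect_true(all(rep$sif_pct == 0))
  s <- summarize_metrics(rep)
  expect_equal(nrow(s), 3)   # 2 organs + overall
  expect_equal(s$dice_mean[s$organ == "overall"], mean(rep$dice))
})
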