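test_that("trimesh construction validates faces and derives components", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  m <- trimesh(v, f)
  expect_equal(n_vertices(m), 4)
  expect_equal(n_faces(m), 4)
  expect_equal(unique(m$component_id), 1L)
  expect_equal(m$vertex_uid, 0:3)
  expect_error(trimesh(v, rbind(c(1, 1, 2))), "degenerate")
  expect_error(trimesh(v, rbind(c(1, 2, 9))), "out of range")
})

test_that("marching cubes closes a single-voxel mask with chi = 2", {
  vol <- array(FALSE, c(3, 3, 3))
  vol[2, 2, 2] <- TRUE
  m <- marching_cubes(vol, c(1, 1, 1))
  expect_true(is_watertight(m))
  expect_equal(euler_characteristic(m), 2)
  # surface encloses the voxel centre at world (1,1,1)
  ctr <- colMeans(m$vertices)
  expect_equal(ctr, c(1, 1, 1), tolerance = 1e-12)
})

test_that("marching cubes on a digital ball approximates the sphere", {
  r <- 10
  vol <- ball_volume(c(28, 28, 28), c(14, 14, 14), r)
  m <- marching_cubes(vol, c(1, 1, 1))
  expect_true(is_watertight(m))
  expect_equal(euler_characteristic(m), 2)
  expect_lt(abs(surface_area(m) - 4 * pi * r^2) / (4 * pi * r^2), 0.15)
  # anisotropic spacing scales coordinates per axis
  m2 <- marching_cubes(vol, c(2, 2, 3))
  expect_equal(max(m2$vertices[, 3]) / max(m$vertices[, 3]), 3, tolerance = 1e-9)
})

test_that("marching cubes rejects empty volumes", {
  expect_error(marching_cubes(array(0, c(4, 4, 4))), "no surface")
})

test_that("laplacian smoothing: identity at 0 iters, neighbour mean at 1", {
  # regular octahedron: every vertex has 4 neighbours
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  m <- trimesh(v, f)
  expect_identical(laplacian_smooth(m, 0)$vertices, m$vertices)
  sm <- laplacian_smooth(m, 1)
  # direct evaluation of the averaging rule: vertex 1 averages 3,4,5,6
  for (i in seq_len(6)) {
    nb <- setdiff(unique(as.vector(f[apply(f, 1, function(r) i %in% r), ])), i)
    expect_equal(sm$vertices[i, ], colMeans(v[nb, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # octahedral symmetry: all smoothed vertices equidistant from origin
  d <- sqrt(rowSums(sm$vertices^2))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
})

test_that("laplacian smoothing shrinks a closed surface", {
  m <- icosphere(2, r = 5)
  expect_lt(surface_area(laplacian_smooth(m, 20)), surface_area(m))
})

test_that("surface sampling is area-weighted, in-plane, and seeded", {
  tri <- trimesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)), rbind(c(1, 2, 3)))
  set.seed(1)
  s <- sample_surface(tri, 500)
  expect_true(all(abs(s$points[, 3]) < 1e-12))
  expect_true(all(s$bary >= 0 & s$bary <= 1))
  # two triangles with areas 1 and 3
  two <- trimesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0),
                       c(10, 0, 0), c(13, 0, 0), c(10, 2, 0)),
                 rbind(c(1, 2, 3), c(4, 5, 6)))
  set.seed(7)
  s2 <- sample_surface(two, 40000)
  frac <- mean(s2$face == 2)
  expect_equal(frac, 0.75, tolerance = 0.01)
  set.seed(123); a <- sample_surface(two, 100)
  set.seed(123); b <- sample_surface(two, 100)
  expect_identical(a$points, b$points)
})

test_that("self-intersection detection matches the independent oracle", {
  # convex surface: no intersections
  expect_length(self_intersecting_faces(icosphere(1)), 0)
  # two interpenetrating triangles sharing no vertex
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
             c(0.5, 0.5, -1), c(1.5, 0.5, 1), c(0.5, 1.5, 1))
  cross <- trimesh(v, rbind(c(1, 2, 3), c(4, 5, 6)),
                   component_id = rep(1L, 6))
  expect_equal(self_intersecting_faces(cross), c(1L, 2L))
  # faces sharing a vertex are never reported
  fan <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1)),
                 rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_length(self_intersecting_faces(fan), 0)
  # random fixtures: grid == brute == R oracle
  set.seed(21)
  for (rep in 1:6) {
    nv <- 24
    v <- matrix(runif(nv * 3, 0, 2), nv, 3)
    f <- t(replicate(30, sample.int(nv, 3)))
    ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    m <- trimesh(v, f[ok, , drop = FALSE], component_id = rep(1L, nv))
    grid <- self_intersecting_faces(m, "grid")
    brute <- self_intersecting_faces(m, "brute")
    expect_identical(grid, brute)
    expect_identical(grid, as.integer(oracle_self_intersections(m)))
  }
})

test_that("intersections are only counted within a component", {
  # same crossing triangles, but in different components
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
             c(0.5, 0.5, -1), c(1.5, 0.5, 1), c(0.5, 1.5, 1))
  m <- trimesh(v, rbind(c(1, 2, 3), c(4, 5, 6)),
               component_id = c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_length(self_intersecting_faces(m), 0)
})

test_that("split and merge conserve vertices, faces and identifiers", {
  s1 <- icosphere(1, r = 1)
  s2 <- icosphere(1, r = 2)
  s2$vertices <- s2$vertices + 10
  merged <- merge_meshes(list(s1, s2))
  expect_equal(length(unique(merged$component_id)), 2)
  parts <- split_components(merged)
  expect_length(parts, 2)
  expect_equal(sum(vapply(parts, n_vertices, 0L)), n_vertices(merged))
  expect_equal(sum(vapply(parts, n_faces, 0L)), n_faces(merged))
  round_trip <- merge_meshes(parts, renumber = FALSE)
  expect_equal(n_vertices(round_trip), n_vertices(merged))
  expect_equal(nrow(mesh_edges(round_trip)), nrow(mesh_edges(merged)))
  expect_setequal(round_trip$vertex_uid, merged$vertex_uid)
})

test_that("PLY round trips preserve geometry and tags bit-exactly", {
  m <- icosphere(1, r = 2.5)
  m$component_id <- rep(3L, n_vertices(m))
  m$vertex_uid <- seq_len(n_vertices(m)) + 100L
  for (fmt in c("binary", "ascii")) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_ply(m, path, format = fmt)
    back <- read_ply(path)
    expect_identical(back$faces, m$faces)
    expect_identical(back$component_id, m$component_id)
    expect_identical(back$vertex_uid, m$vertex_uid)
    if (fmt == "binary") expect_identical(back$vertices, m$vertices)
    else expect_equal(back$vertices, m$vertices, tolerance = 1e-15)
  }
})
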