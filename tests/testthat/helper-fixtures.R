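# fixture builders shared across test files

# digital ball mask centred on a grid point
ball_volume <- function(dims, center, radius) {
  idx <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                     z = seq_len(dims[3]) - 1)
  array((idx$x - center[1])^2 + (idx$y - center[2])^2 + (idx$z - center[3])^2
        <= radius^2, dim = dims)
}

# icosahedron with optional midpoint subdivisions, projected to radius r
icosphere <- function(subdiv = 2, r = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdiv)) {
    nv <- nrow(v)
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  trimesh(v, f)
}

# a small phantom population shared by several test files (kept cheap)
tiny_spec <- function(seed = 42L) {
  phantom_spec(grid_shape = c(16L, 16L, 16L), spacing = c(2, 2, 2),
               n_organs = 2L,
               organ_centers = rbind(c(0.3, 0.35, 0.4), c(0.7, 0.65, 0.6)),
               radius_range = rbind(c(2.4, 3), c(2, 2.6)),
               wobble_amp = 0.12, jitter_amp = 0.7,
               intensity_means = c(0, 0.5, 1.0),
               noise_sigma = 0.06, blur_sigma = 0.5, seed = seed)
}

tiny_net_config <- function(...) {
  net_config(base_channels = 2L, n_classes = 3L, k_fields = 2L,
             input_shape = c(16L, 16L, 16L), ...)
}

# ---- independent brute-force oracles (plain R loops) ----------------------

oracle_nn_dist <- function(from, to) {
  apply(from, 1, function(p) sqrt(min(colSums((t(to) - p)^2))))
}

oracle_chamfer <- function(pred, gt) {
  mean(oracle_nn_dist(gt, pred)^2) + mean(oracle_nn_dist(pred, gt)^2)
}

oracle_assd <- function(a, b) {
  (mean(oracle_nn_dist(a, b)) + mean(oracle_nn_dist(b, a))) / 2
}

oracle_hd <- function(a, b, q = 1) {
  da <- sort(oracle_nn_dist(a, b))
  db <- sort(oracle_nn_dist(b, a))
  pct <- function(d) {
    h <- (length(d) - 1) * q + 1
    lo <- floor(h); hi <- ceiling(h)
    d[lo] + (h - lo) * (d[hi] - d[lo])
  }
  max(pct(da), pct(db))
}

oracle_edge_loss <- function(mesh) {
  f <- mesh$faces
  seen <- c()
  tot <- 0; n <- 0
  for (i in seq_len(nrow(f))) for (pair in list(f[i, 1:2], f[i, 2:3], f[i, c(3, 1)])) {
    key <- paste(min(pair), max(pair))
    if (key %in% seen) next
    seen <- c(seen, key)
    tot <- tot + sum((mesh$vertices[pair[1], ] - mesh$vertices[pair[2], ])^2)
    n <- n + 1
  }
  tot / n
}

oracle_ce <- function(logits, labels) {
  d <- dim(logits)
  acc <- 0
  for (k in seq_len(d[4])) for (j in seq_len(d[3])) for (i in seq_len(d[2])) {
    sc <- logits[, i, j, k]
    p <- exp(sc - max(sc)) / sum(exp(sc - max(sc)))
    acc <- acc - log(p[labels[i, j, k] + 1])
  }
  acc / prod(d[2:4])
}

# independent triangle-triangle intersection via segment/triangle tests
oracle_seg_tri <- function(p, q, a, b, c, eps = 1e-9) {
  # does segment pq cross triangle abc?
  n <- pracma_cross(b - a, c - a)
  dp <- sum(n * (p - a)); dq <- sum(n * (q - a))
  if ((dp > eps && dq > eps) || (dp < -eps && dq < -eps)) return(FALSE)
  denom <- dp - dq
  if (abs(denom) < eps) return(FALSE)  # parallel/coplanar handled elsewhere
  t <- dp / denom
  x <- p + t * (q - p)
  # barycentric containment
  v0 <- b - a; v1 <- c - a; v2 <- x - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  u > eps && v > eps && u + v < 1 - eps
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

oracle_tri_tri <- function(t1, t2) {
  segs1 <- list(t1[1:2, ], t1[2:3, ], t1[c(3, 1), ])
  for (s in segs1)
    if (oracle_seg_tri(s[1, ], s[2, ], t2[1, ], t2[2, ], t2[3, ])) return(TRUE)
  segs2 <- list(t2[1:2, ], t2[2:3, ], t2[c(3, 1), ])
  for (s in segs2)
    if (oracle_seg_tri(s[1, ], s[2, ], t1[1, ], t1[2, ], t1[3, ])) return(TRUE)
  FALSE
}

oracle_self_intersections <- function(mesh) {
  f <- mesh$faces
  fc <- mesh$component_id[f[, 1]]
  hit <- rep(FALSE, nrow(f))
  for (i in seq_len(nrow(f) - 1)) for (j in (i + 1):nrow(f)) {
    if (fc[i] != fc[j]) next
    if (length(intersect(f[i, ], f[j, ])) > 0) next
    t1 <- mesh$vertices[f[i, ], , drop = FALSE]
    t2 <- mesh$vertices[f[j, ], , drop = FALSE]
    if (oracle_tri_tri(t1, t2)) { hit[i] <- TRUE; hit[j] <- TRUE }
  }
  which(hit)
}

# random flow stack with smooth coarse fields, |phi| bounded
random_flow_stack <- function(grid_shape, spacing, k_fields, max_mag) {
  stage_res <- lapply(4:0, function(l) pmax(as.integer(grid_shape / 2^l), 1L))
  fields <- lapply(1:5, function(s) {
    nk <- if (s < 5) k_fields else 1L
    lapply(seq_len(nk), function(k) {
      f <- array(rnorm(3 * prod(stage_res[[s]])), dim = c(3, stage_res[[s]]))
      f / max(abs(f)) * max_mag
    })
  })
  flow_stack(fields, grid_shape, spacing)
}
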