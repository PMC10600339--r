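#' Configuration of the flow-predicting 3D residual UNet
#'
#' A five-stage residual encoder-decoder. The encoder halves the resolution
#' four times (two 3x3x3 convolutions with instance normalisation, leaky ReLU
#' and an additive skip per level); the decoder recovers resolution step-wise
#' with nearest-neighbour upsampling, convolution and encoder skip additions.
#' Every decoder stage feeds a dedicated 1x1x1 linear head emitting that
#' stage's flow field(s): `k_fields` per-organ fields in stages 0-3 and a
#' single shared field in stage 4. With the voxel branch enabled, 1x1x1
#' segmentation heads emit class scores at the final stage and at the two
#' intermediate deep-supervision stages (the two coarsest stages carry none).
#'
#' @param base_channels channels of the finest level; doubled per level and
#'   capped at `8 * base_channels`.
#' @param n_classes number of voxel classes C including background (>= 2).
#' @param k_fields number of per-organ flow fields in stages 0-3.
#' @param use_voxel_branch enable the segmentation branch (VB).
#' @param use_deep_mesh_supervision apply mesh losses to every stage mesh (DMS)
#'   rather than the final mesh only.
#' @param input_shape volume shape; every axis must be divisible by 16.
#' @param n_stages number of stages; fixed at 5.
#' @return an object of class `net_config`.
#' @export
net_config <- function(base_channels = 4L, n_classes = 5L, k_fields = 4L,
                       use_voxel_branch = TRUE, use_deep_mesh_supervision = TRUE,
                       input_shape = c(32L, 32L, 32L), n_stages = 5L) {
  if (n_stages != 5) stopf("the architecture is defined for exactly 5 stages")
  if (n_classes < 2) stopf("'n_classes' must be >= 2 (incl. background)")
  div <- 2^(n_stages - 1)
  if (any(input_shape %% div != 0))
    stopf("input shape (%s) must be divisible by %d on every axis",
          paste(input_shape, collapse = "x"), div)
  channels <- pmin(base_channels * 2^(0:4), base_channels * 8L)
  structure(list(base_channels = as.integer(base_channels),
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 k_fields = as.integer(k_fields),
                 use_voxel_branch = isTRUE(use_voxel_branch),
                 use_deep_mesh_supervision = isTRUE(use_deep_mesh_supervision),
                 input_shape = as.integer(input_shape),
                 n_stages = 5L,
                 deep_seg_stages = c(2L, 3L)),
            class = "net_config")
}

# ---- primitive layers with explicit forward/backward ----------------------

IN_EPS <- 1e-5
LRELU_SLOPE <- 0.01

inorm_fwd <- function(x, gamma, beta) {
  d <- dim(x)
  mat <- matrix(x, d[1])
  m <- rowMeans(mat)
  v <- rowMeans(mat * mat) - m * m
  istd <- 1 / sqrt(v + IN_EPS)
  xhat <- (mat - m) * istd
  y <- array(gamma * xhat + beta, dim = d)
  list(y = y, xhat = xhat, istd = istd, gamma = gamma, dim = d)
}

inorm_bwd <- function(cache, g) {
  d <- cache$dim
  gm <- matrix(g, d[1])
  ggamma <- rowSums(gm * cache$xhat)
  gbeta <- rowSums(gm)
  nv <- ncol(gm)
  gx <- (cache$gamma * cache$istd) *
    (gm - rowMeans(gm) - cache$xhat * rowMeans(gm * cache$xhat))
  list(g_x = array(gx, dim = d), g_gamma = ggamma, g_beta = gbeta)
}

# sign of the pre-activation survives leaky ReLU, so the output itself is a
# sufficient backward cache
lrelu_fwd <- function(x) {
  y <- pmax(x, 0) + LRELU_SLOPE * pmin(x, 0)
  dim(y) <- dim(x)
  list(y = y)
}

lrelu_bwd <- function(cache, g) {
  neg <- cache$y < 0
  g[neg] <- g[neg] * LRELU_SLOPE
  g
}

# convolution as GEMM on the im2col matrix; weights are (cout x cin*k^3).
# The column matrix is kept for the backward pass.
conv_fwd_mat <- function(x, w, b, stride = 1L, ksize = 3L) {
  d <- dim(x)
  cols <- if (ksize == 1L && stride == 1L) matrix(x, d[1]) else .im2col(x, ksize, stride)
  out <- w %*% cols + b
  pad <- (ksize - 1L) %/% 2L
  sp <- (d[2:4] + 2L * pad - ksize) %/% stride + 1L
  list(y = array(out, dim = c(nrow(w), sp)), cols = cols, xdim = d)
}

conv_bwd_mat <- function(fwd, w, gout, stride = 1L, ksize = 3L) {
  co <- nrow(w)
  gmat <- matrix(gout, co)
  g_w <- tcrossprod(gmat, fwd$cols)
  g_b <- rowSums(gmat)
  gcols <- crossprod(w, gmat)
  g_x <- if (ksize == 1L && stride == 1L) array(gcols, dim = fwd$xdim)
         else .col2im(gcols, fwd$xdim, ksize, stride)
  list(g_x = g_x, g_w = g_w, g_b = g_b)
}

# backward context for a 1x1x1 convolution (its cols matrix is just a view)
conv1_ctx <- function(x) list(cols = matrix(x, dim(x)[1]), xdim = dim(x))

# conv + instance norm + leaky relu, the basic unit
cnl_fwd <- function(x, p, stride = 1L, ksize = 3L) {
  cv <- conv_fwd_mat(x, p$w, p$b, stride, ksize)
  nc <- inorm_fwd(cv$y, p$gamma, p$beta)
  ac <- lrelu_fwd(nc$y)
  list(y = ac$y, conv = cv, norm = nc, act = ac, stride = stride, ksize = ksize)
}

cnl_bwd <- function(cache, p, g) {
  g <- lrelu_bwd(cache$act, g)
  nb <- inorm_bwd(cache$norm, g)
  cb <- conv_bwd_mat(cache$conv, p$w, nb$g_x, cache$stride, cache$ksize)
  list(g_x = cb$g_x,
       grads = list(w = cb$g_w, b = cb$g_b, g_gamma = nb$g_gamma, g_beta = nb$g_beta))
}

# residual block: two conv+IN with additive skip, trailing activation
res_fwd <- function(x, p1, p2) {
  cv1 <- conv_fwd_mat(x, p1$w, p1$b, 1L, 3L)
  n1 <- inorm_fwd(cv1$y, p1$gamma, p1$beta)
  a1 <- lrelu_fwd(n1$y)
  cv2 <- conv_fwd_mat(a1$y, p2$w, p2$b, 1L, 3L)
  n2 <- inorm_fwd(cv2$y, p2$gamma, p2$beta)
  s <- n2$y + x
  a2 <- lrelu_fwd(s)
  list(y = a2$y, cv1 = cv1, a1 = a1, cv2 = cv2, n1 = n1, n2 = n2, a2 = a2)
}

res_bwd <- function(cache, p1, p2, g) {
  g <- lrelu_bwd(cache$a2, g)
  g_skip <- g
  nb2 <- inorm_bwd(cache$n2, g)
  cb2 <- conv_bwd_mat(cache$cv2, p2$w, nb2$g_x, 1L, 3L)
  ga1 <- lrelu_bwd(cache$a1, cb2$g_x)
  nb1 <- inorm_bwd(cache$n1, ga1)
  cb1 <- conv_bwd_mat(cache$cv1, p1$w, nb1$g_x, 1L, 3L)
  list(g_x = cb1$g_x + g_skip,
       g1 = list(w = cb1$g_w, b = cb1$g_b, g_gamma = nb1$g_gamma, g_beta = nb1$g_beta),
       g2 = list(w = cb2$g_w, b = cb2$g_b, g_gamma = nb2$g_gamma, g_beta = nb2$g_beta))
}

# ---- parameter construction ----------------------------------------------

conv_param <- function(cin, cout, ksize, zero = FALSE, norm = TRUE) {
  fan_in <- cin * ksize^3
  bound <- 1 / sqrt(fan_in)
  w <- if (zero) matrix(0, cout, fan_in)
       else matrix(runif(fan_in * cout, -bound, bound), cout, fan_in)
  b <- if (zero) numeric(cout) else runif(cout, -bound, bound)
  p <- list(w = w, b = b)
  if (norm) { p$gamma <- rep(1, cout); p$beta <- rep(0, cout) }
  p
}

#' Initialise network parameters
#'
#' Flow and segmentation head weights and biases are exactly zero, which makes
#' a fresh model predict the identity deformation (the template itself) for any
#' input; this zero initialisation is essential for stable training. All other
#' weights follow the uniform fan-in scheme, seeded.
#'
#' @param cfg a [net_config()].
#' @param seed RNG seed.
#' @return named list of parameter arrays (class `net_params`).
#' @export
init_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    ch <- cfg$channels
    p <- list()
    p$enc0_in <- conv_param(1, ch[1], 3)
    p$enc0_r1 <- conv_param(ch[1], ch[1], 3)
    p$enc0_r2 <- conv_param(ch[1], ch[1], 3)
    for (l in 1:4) {
      p[[sprintf("enc%d_down", l)]] <- conv_param(ch[l], ch[l + 1], 3)
      p[[sprintf("enc%d_r1", l)]] <- conv_param(ch[l + 1], ch[l + 1], 3)
      p[[sprintf("enc%d_r2", l)]] <- conv_param(ch[l + 1], ch[l + 1], 3)
    }
    for (s in 1:4) {
      cin <- ch[6 - s]
      cout <- ch[5 - s]
      p[[sprintf("dec%d_up", s)]] <- conv_param(cin, cout, 3)
      p[[sprintf("dec%d_c1", s)]] <- conv_param(cout, cout, 3)
    }
    for (s in 0:4) {
      cin <- if (s == 0) ch[5] else ch[5 - s]
      cout <- if (s < 4) 3L * cfg$k_fields else 3L
      p[[sprintf("flow_head%d", s)]] <- conv_param(cin, cout, 1, zero = TRUE, norm = FALSE)
    }
    if (cfg$use_voxel_branch) {
      for (s in c(cfg$deep_seg_stages, 4L)) {
        cin <- ch[5 - s]
        p[[sprintf("seg_head%d", s)]] <- conv_param(cin, cfg$n_classes, 1,
                                                    zero = TRUE, norm = FALSE)
      }
    }
    class(p) <- "net_params"
    p
  })
}

#' Total number of trainable parameters
#' @param params a `net_params` list.
#' @return integer count.
#' @export
n_params <- function(params) {
  sum(vapply(params, function(p) sum(lengths(lapply(p, as.vector))), 0))
}

# ---- forward / backward ---------------------------------------------------

#' Forward pass: intensity volume to flow stack and segmentation
#'
#' @param volume 3D intensity array matching `cfg$input_shape`.
#' @param params parameters from [init_params()].
#' @param cfg a [net_config()].
#' @param keep_cache keep activations for the backward pass (training).
#' @param spacing voxel spacing of the input volume (mm), attached to the
#'   emitted flow stack.
#' @return list with `flows` (a [flow_stack()]), `seg_logits` (array
#'   `c(C, shape)` or `NULL` when the voxel branch is off), `deep_seg_logits`
#'   (list keyed by stage) and optionally `cache`.
#' @export
net_forward <- function(volume, params, cfg, keep_cache = FALSE,
                        spacing = c(1, 1, 1)) {
  d <- dim(volume)
  if (!identical(as.integer(d), cfg$input_shape))
    stopf("volume shape (%s) does not match config input shape (%s)",
          paste(d, collapse = "x"), paste(cfg$input_shape, collapse = "x"))
  x <- array(as.double(volume), dim = c(1L, d))
  cache <- list()
  # encoder
  e <- vector("list", 5)
  c0a <- cnl_fwd(x, params$enc0_in)
  r0 <- res_fwd(c0a$y, params$enc0_r1, params$enc0_r2)
  e[[1]] <- r0$y
  cache$enc0 <- list(inl = c0a, res = r0)
  for (l in 1:4) {
    dn <- cnl_fwd(e[[l]], params[[sprintf("enc%d_down", l)]], stride = 2L)
    rs <- res_fwd(dn$y, params[[sprintf("enc%d_r1", l)]],
                  params[[sprintf("enc%d_r2", l)]])
    e[[l + 1]] <- rs$y
    cache[[sprintf("enc%d", l)]] <- list(down = dn, res = rs)
  }
  # decoder
  feat <- vector("list", 5)  # stage 0..4 features
  feat[[1]] <- e[[5]]
  for (s in 1:4) {
    up <- .up2_fwd(feat[[s]])
    upc <- cnl_fwd(up, params[[sprintf("dec%d_up", s)]])
    added <- upc$y + e[[5 - s]]
    c1 <- cnl_fwd(added, params[[sprintf("dec%d_c1", s)]])
    feat[[s + 1]] <- c1$y
    cache[[sprintf("dec%d", s)]] <- list(upc = upc, c1 = c1)
  }
  # flow heads
  fields <- vector("list", 5)
  for (s in 0:4) {
    hp <- params[[sprintf("flow_head%d", s)]]
    out <- conv_fwd_mat(feat[[s + 1]], hp$w, hp$b, 1L, 1L)$y
    if (s < 4) {
      fields[[s + 1]] <- lapply(seq_len(cfg$k_fields), function(k)
        out[(3 * (k - 1) + 1):(3 * k), , , , drop = FALSE])
    } else {
      fields[[s + 1]] <- list(out)
    }
  }
  flows <- flow_stack(fields, d, spacing)
  seg_logits <- NULL
  deep_seg_logits <- list()
  if (cfg$use_voxel_branch) {
    hp <- params$seg_head4
    seg_logits <- conv_fwd_mat(feat[[5]], hp$w, hp$b, 1L, 1L)$y
    for (s in cfg$deep_seg_stages) {
      hp <- params[[sprintf("seg_head%d", s)]]
      deep_seg_logits[[as.character(s)]] <-
        conv_fwd_mat(feat[[s + 1]], hp$w, hp$b, 1L, 1L)$y
    }
  }
  out <- list(flows = flows, seg_logits = seg_logits,
              deep_seg_logits = deep_seg_logits)
  if (keep_cache) {
    cache$x <- x
    cache$e <- e
    cache$feat <- feat
    out$cache <- cache
  }
  out
}

# backward: g_fields nested like flows$fields (NULL entries allowed),
# g_seg / g_deep gradients on logits. Returns gradient list shaped like params.
net_backward <- function(cache, params, cfg, g_fields, g_seg = NULL,
                         g_deep = NULL) {
  grads <- list()
  feat <- cache$feat
  gfeat <- lapply(feat, function(f) array(0, dim = dim(f)))
  # heads
  for (s in 0:4) {
    nm <- sprintf("flow_head%d", s)
    hp <- params[[nm]]
    gst <- g_fields[[s + 1]]
    if (is.null(gst)) next
    if (s < 4) {
      gall <- array(0, dim = c(3L * cfg$k_fields, dim(feat[[s + 1]])[2:4]))
      for (k in seq_len(cfg$k_fields))
        if (!is.null(gst[[k]]))
          gall[(3 * (k - 1) + 1):(3 * k), , , ] <- gst[[k]]
    } else {
      gall <- gst[[1]]
    }
    cb <- conv_bwd_mat(conv1_ctx(feat[[s + 1]]), hp$w, gall, 1L, 1L)
    grads[[nm]] <- list(w = cb$g_w, b = cb$g_b)
    gfeat[[s + 1]] <- gfeat[[s + 1]] + cb$g_x
  }
  if (cfg$use_voxel_branch) {
    if (!is.null(g_seg)) {
      cb <- conv_bwd_mat(conv1_ctx(feat[[5]]), params$seg_head4$w, g_seg, 1L, 1L)
      grads$seg_head4 <- list(w = cb$g_w, b = cb$g_b)
      gfeat[[5]] <- gfeat[[5]] + cb$g_x
    }
    for (s in cfg$deep_seg_stages) {
      gs <- g_deep[[as.character(s)]]
      if (is.null(gs)) next
      nm <- sprintf("seg_head%d", s)
      cb <- conv_bwd_mat(conv1_ctx(feat[[s + 1]]), params[[nm]]$w, gs, 1L, 1L)
      grads[[nm]] <- list(w = cb$g_w, b = cb$g_b)
      gfeat[[s + 1]] <- gfeat[[s + 1]] + cb$g_x
    }
  }
  # decoder, reverse
  ge <- lapply(cache$e, function(f) array(0, dim = dim(f)))
  for (s in 4:1) {
    dc <- cache[[sprintf("dec%d", s)]]
    g <- gfeat[[s + 1]]
    b1 <- cnl_bwd(dc$c1, params[[sprintf("dec%d_c1", s)]], g)
    grads[[sprintf("dec%d_c1", s)]] <- b1$grads
    ge[[5 - s]] <- ge[[5 - s]] + b1$g_x       # skip addition
    bu <- cnl_bwd(dc$upc, params[[sprintf("dec%d_up", s)]], b1$g_x)
    grads[[sprintf("dec%d_up", s)]] <- bu$grads
    gfeat[[s]] <- gfeat[[s]] + .up2_bwd(bu$g_x)
  }
  ge[[5]] <- ge[[5]] + gfeat[[1]]
  # encoder, reverse
  for (l in 4:1) {
    ec <- cache[[sprintf("enc%d", l)]]
    rb <- res_bwd(ec$res, params[[sprintf("enc%d_r1", l)]],
                  params[[sprintf("enc%d_r2", l)]], ge[[l + 1]])
    grads[[sprintf("enc%d_r1", l)]] <- rb$g1
    grads[[sprintf("enc%d_r2", l)]] <- rb$g2
    db <- cnl_bwd(ec$down, params[[sprintf("enc%d_down", l)]], rb$g_x)
    grads[[sprintf("enc%d_down", l)]] <- db$grads
    ge[[l]] <- ge[[l]] + db$g_x
  }
  rb <- res_bwd(cache$enc0$res, params$enc0_r1, params$enc0_r2, ge[[1]])
  grads$enc0_r1 <- rb$g1
  grads$enc0_r2 <- rb$g2
  ib <- cnl_bwd(cache$enc0$inl, params$enc0_in, rb$g_x)
  grads$enc0_in <- ib$grads
  grads
}

# ---- optimiser ------------------------------------------------------------

adamw_init <- function(params) {
  zeros <- function(p) lapply(p[names(p) %in% c("w", "b", "gamma", "beta")],
                              function(a) a * 0)
  list(step = 0L, m = lapply(params, zeros), v = lapply(params, zeros))
}

# grads use names w/b/g_gamma/g_beta; map onto parameter slots
grad_slot <- c(w = "w", b = "b", g_gamma = "gamma", g_beta = "beta")

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$step <- state$step + 1L
  t <- state$step
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (gn in names(g)) {
      slot <- grad_slot[[gn]]
      if (is.null(slot) || is.null(params[[nm]][[slot]])) next
      gv <- g[[gn]]
      m <- state$m[[nm]][[slot]] * beta1 + (1 - beta1) * gv
      v <- state$v[[nm]][[slot]] * beta2 + (1 - beta2) * gv * gv
      state$m[[nm]][[slot]] <- m
      state$v[[nm]][[slot]] <- v
      upd <- (m / bc1) / (sqrt(v / bc2) + eps)
      pv <- params[[nm]][[slot]]
      if (slot == "w") pv <- pv - lr * weight_decay * pv
      params[[nm]][[slot]] <- pv - lr * upd
    }
  }
  list(params = params, state = state)
}
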