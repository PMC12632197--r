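# Image backbones. Both map an RGB patch batch (H, W, 3, B) to a feature
# map whose spatial positions become attention tokens.
#
# * "resnet34": the standard 34-layer residual network truncated before
#   global pooling and the classifier, keeping the 7x7x512 map (so 49
#   tokens of width 512 for 224x224 input). Batch-norm layers run with
#   fixed statistics; weights are randomly initialized from the model seed
#   (the package runs fully offline, so no pretrained weights are loaded;
#   checkpoints trained elsewhere can be dropped into the same tree).
# * "small": a compact strided CNN for desk-scale experiments — an 8x8
#   stride-8 patch-embedding convolution followed by a 3x3 stride-2
#   convolution (64x64 input -> 4x4 tokens), fully trainable.

init_backbone <- function(kind, d_att) {
  switch(kind,
    small = list(
      conv1 = init_conv(8, 3, 48),
      conv2 = init_conv(3, 48, d_att)
    ),
    resnet34 = init_resnet34(),
    stopf("unknown backbone kind '%s'", kind)
  )
}

init_conv <- function(k, c_in, c_out) {
  list(W = init_weight(k * k * c_in, c_out, gain = sqrt(2)), b = numeric(c_out))
}

backbone_fw <- function(X, p, kind) {
  switch(kind,
    small = small_cnn_fw(X, p),
    resnet34 = resnet34_fw(X, p))
}

backbone_bw <- function(dT, cache, kind, need_dx = FALSE) {
  switch(kind,
    small = small_cnn_bw(dT, cache, need_dx = need_dx),
    resnet34 = resnet34_bw(dT, cache, need_dx = need_dx))
}

small_cnn_geom <- list(list(k = 8L, stride = 8L, pad = 0L),
                       list(k = 3L, stride = 2L, pad = 1L))

small_cnn_fw <- function(X, p) {
  caches <- list()
  h <- X
  for (i in seq_along(small_cnn_geom)) {
    gm <- small_cnn_geom[[i]]
    cv <- conv2d_fw(h, p[[paste0("conv", i)]], k = gm$k, stride = gm$stride,
                    pad = gm$pad)
    rl <- relu_fw(cv$out)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
    h <- rl$out
  }
  d <- dim(h)
  list(tokens = map_to_tokens(h), n = d[1] * d[2],
       cache = list(layers = caches, dims = d))
}

small_cnn_bw <- function(dT, cache, need_dx = FALSE) {
  d <- cache$dims
  dh <- tokens_to_map(dT, d[1], d[2], d[3], d[4])
  dp <- list()
  nl <- length(small_cnn_geom)
  for (i in nl:1) {
    dh <- relu_bw(dh, cache$layers[[i]]$relu)
    cb <- conv2d_bw(dh, cache$layers[[i]]$conv, need_dx = i > 1 || need_dx)
    dh <- cb$dx
    dp[[paste0("conv", i)]] <- cb$dp
  }
  list(dx = dh, dp = dp[paste0("conv", seq_len(nl))])
}

# --- 34-layer residual trunk -------------------------------------------

resnet34_spec <- function() {
  list(blocks = c(3L, 4L, 6L, 3L), channels = c(64L, 128L, 256L, 512L))
}

init_resnet34 <- function() {
  sp <- resnet34_spec()
  p <- list(stem = list(conv = init_conv(7, 3, 64), bn = init_bnorm(64)))
  c_in <- 64L
  for (s in seq_along(sp$blocks)) {
    stage <- list()
    c_out <- sp$channels[s]
    for (b in seq_len(sp$blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blk <- list(
        conv1 = init_conv(3, c_in, c_out), bn1 = init_bnorm(c_out),
        conv2 = init_conv(3, c_out, c_out), bn2 = init_bnorm(c_out)
      )
      if (stride != 1L || c_in != c_out) {
        blk$down <- list(conv = init_conv(1, c_in, c_out),
                         bn = init_bnorm(c_out))
      }
      stage[[b]] <- blk
      c_in <- c_out
    }
    p[[paste0("stage", s)]] <- stage
  }
  p
}

res_block_fw <- function(X, p, stride) {
  c1 <- conv2d_fw(X, p$conv1, k = 3, stride = stride, pad = 1)
  b1 <- bnorm_fw(c1$out, p$bn1)
  r1 <- relu_fw(b1$out)
  c2 <- conv2d_fw(r1$out, p$conv2, k = 3, stride = 1, pad = 1)
  b2 <- bnorm_fw(c2$out, p$bn2)
  if (!is.null(p$down)) {
    dc <- conv2d_fw(X, p$down$conv, k = 1, stride = stride, pad = 0)
    db <- bnorm_fw(dc$out, p$down$bn)
    shortcut <- db$out
    down_cache <- list(conv = dc$cache, bn = db$cache)
  } else {
    shortcut <- X
    down_cache <- NULL
  }
  r2 <- relu_fw(b2$out + shortcut)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    down = down_cache))
}

res_block_bw <- function(dY, cache) {
  dsum <- relu_bw(dY, cache$r2)
  db2 <- bnorm_bw(dsum, cache$b2)
  cb2 <- conv2d_bw(db2, cache$c2)
  dr1 <- relu_bw(cb2$dx, cache$r1)
  db1 <- bnorm_bw(dr1, cache$b1)
  cb1 <- conv2d_bw(db1, cache$c1)
  dp <- list(conv1 = cb1$dp, bn1 = zero_bnorm_grad(cache$b1),
             conv2 = cb2$dp, bn2 = zero_bnorm_grad(cache$b2))
  if (!is.null(cache$down)) {
    cbd <- conv2d_bw(bnorm_bw(dsum, cache$down$bn), cache$down$conv)
    dp$down <- list(conv = cbd$dp, bn = zero_bnorm_grad(cache$down$bn))
    dx <- cb1$dx + cbd$dx
  } else {
    dx <- cb1$dx + dsum
  }
  list(dx = dx, dp = dp)
}

# batch-norm statistics are frozen, so their parameter gradients are
# reported as zeros to keep the gradient tree aligned with the param tree
zero_bnorm_grad <- function(bn_cache) {
  C <- length(bn_cache$scale)
  list(gamma = numeric(C), beta = numeric(C), mean = numeric(C),
       var = numeric(C))
}

resnet34_fw <- function(X, p) {
  sp <- resnet34_spec()
  st_c <- conv2d_fw(X, p$stem$conv, k = 7, stride = 2, pad = 3)
  st_b <- bnorm_fw(st_c$out, p$stem$bn)
  st_r <- relu_fw(st_b$out)
  st_m <- maxpool_fw(st_r$out, k = 3, stride = 2, pad = 1)
  h <- st_m$out
  stage_caches <- list()
  for (s in seq_along(sp$blocks)) {
    blks <- list()
    for (b in seq_len(sp$blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      bf <- res_block_fw(h, p[[paste0("stage", s)]][[b]], stride)
      h <- bf$out
      blks[[b]] <- bf$cache
    }
    stage_caches[[s]] <- blks
  }
  d <- dim(h)
  list(tokens = map_to_tokens(h), n = d[1] * d[2],
       cache = list(stem = list(c = st_c$cache, b = st_b$cache,
                                r = st_r$cache, m = st_m$cache),
                    stages = stage_caches, dims = d))
}

resnet34_bw <- function(dT, cache, need_dx = FALSE) {
  sp <- resnet34_spec()
  d <- cache$dims
  dh <- tokens_to_map(dT, d[1], d[2], d[3], d[4])
  dp <- list()
  for (s in rev(seq_along(sp$blocks))) {
    stage_dp <- vector("list", sp$blocks[s])
    for (b in rev(seq_len(sp$blocks[s]))) {
      bb <- res_block_bw(dh, cache$stages[[s]][[b]])
      dh <- bb$dx
      stage_dp[[b]] <- bb$dp
    }
    dp[[paste0("stage", s)]] <- stage_dp
  }
  dh <- maxpool_bw(dh, cache$stem$m)
  dh <- relu_bw(dh, cache$stem$r)
  dh <- bnorm_bw(dh, cache$stem$b)
  cbs <- conv2d_bw(dh, cache$stem$c, need_dx = need_dx)
  dp$stem <- list(conv = cbs$dp, bn = zero_bnorm_grad(cache$stem$b))
  # reorder to match init layout (stem first)
  dp <- dp[c("stem", paste0("stage", seq_along(sp$blocks)))]
  list(dx = cbs$dx, dp = dp)
}
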