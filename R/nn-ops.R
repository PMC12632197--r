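# Differentiable primitives. Each *_fw returns list(out, cache); each *_bw
# takes the upstream gradient and the cache and returns gradients for inputs
# (`dx`) and, where present, parameters (`dp`, matching the init_* layout).
#
# Token batches are plain matrices of shape ((B * n_tokens) x d) with rows
# ordered token-major within sample: row (b - 1) * n + i is token i of
# sample b. Image batches are arrays (H, W, C, B).

add_bias <- function(X, b) X + rep(b, each = nrow(X))

linear_fw <- function(X, p) {
  list(out = cpp_linear(X, p$W, p$b), cache = list(X = X, p = p))
}

linear_bw <- function(dY, cache) {
  list(dx = dY %*% t(cache$p$W),
       dp = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

gelu_fw <- function(X) {
  list(out = cpp_gelu_fw(X), cache = X)
}

gelu_bw <- function(dY, cache) {
  cpp_gelu_bw(dY, cache)
}

relu_fw <- function(X) {
  list(out = pmax(X, 0), cache = X > 0)
}

relu_bw <- function(dY, cache) dY * cache

# row-wise layer norm over the feature (column) dimension
layernorm_fw <- function(X, p, eps = 1e-5) {
  r <- cpp_layernorm_fw(X, p$gamma, p$beta, eps)
  list(out = r$out, cache = list(xhat = r$xhat, inv = r$inv, p = p))
}

layernorm_bw <- function(dY, cache) {
  r <- cpp_layernorm_bw(dY, cache$xhat, as.numeric(cache$inv), cache$p$gamma)
  list(dx = r$dx, dp = list(gamma = as.numeric(r$dgamma),
                            beta = as.numeric(r$dbeta)))
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# --- multi-head attention ----------------------------------------------
#
# Xq: ((B*nq) x d), Xk/Xv: ((B*nk) x d). `kv_perm` optionally permutes the
# key and value token order independently per sample (the scramble ablation);
# each is an integer permutation of 1..nk or NULL.

mha_fw <- function(Xq, Xk, Xv, p, n_heads, B, nq, nk,
                   k_perm = NULL, v_perm = NULL, record_attn = FALSE) {
  d <- ncol(Xq)
  dh <- d %/% n_heads
  Q <- cpp_linear(Xq, p$Wq, p$bq)
  K <- cpp_linear(Xk, p$Wk, p$bk)
  V <- cpp_linear(Xv, p$Wv, p$bv)
  scl <- 1 / sqrt(dh)
  A_rec <- NULL

  if (nk == 1L) {
    # single key: the attention weight is identically 1 and the context
    # is the (broadcast) value token
    grp <- rep(seq_len(B), each = nq)
    Ctx <- V[grp, , drop = FALSE]
    path <- "bcast"
    A_h <- grp_k <- NULL
    if (record_attn) {
      A_rec <- rep(list(rep(list(matrix(1, nq, 1)), n_heads)), B)
    }
  } else if (nq == 1L) {
    # single query per sample: fused batch kernel
    r <- cpp_mha_vec1_fw(Q, K, V, n_heads,
                         (k_perm %||% seq_len(nk)) - 1L,
                         (v_perm %||% seq_len(nk)) - 1L)
    Ctx <- r$Ctx
    A_h <- r$A                                # (nk*B) x n_heads
    path <- "vec1"
    if (record_attn) {
      A_rec <- lapply(seq_len(B), function(b) {
        lapply(seq_len(n_heads), function(h) {
          matrix(A_h[(b - 1L) * nk + seq_len(nk), h], 1, nk)
        })
      })
    }
  } else {
    r <- cpp_mha_gen_fw(Q, K, V, n_heads, B, nq, nk,
                        (k_perm %||% seq_len(nk)) - 1L,
                        (v_perm %||% seq_len(nk)) - 1L)
    Ctx <- r$Ctx
    A_h <- r$A                                # (B*n_heads*nq) x nk
    path <- "gen"
    if (record_attn) {
      A_rec <- lapply(seq_len(B), function(b) {
        lapply(seq_len(n_heads), function(h) {
          A_h[((b - 1L) * n_heads + (h - 1L)) * nq + seq_len(nq), ,
              drop = FALSE]
        })
      })
    }
  }

  outl <- linear_fw(Ctx, list(W = p$Wo, b = p$bo))
  cache <- list(Xq = Xq, Xk = Xk, Xv = Xv, Q = Q, K = K, V = V, A = A_h,
                Ctx = Ctx, p = p, n_heads = n_heads, B = B, nq = nq, nk = nk,
                k_perm = k_perm, v_perm = v_perm, path = path,
                grp = if (path == "bcast") rep(seq_len(B), each = nq))
  list(out = outl$out, cache = cache, attn = A_rec)
}

mha_bw <- function(dOut, cache) {
  p <- cache$p
  B <- cache$B; nq <- cache$nq; nk <- cache$nk
  n_heads <- cache$n_heads
  d <- ncol(cache$Q)
  dh <- d %/% n_heads
  scl <- 1 / sqrt(dh)

  dWo <- crossprod(cache$Ctx, dOut)
  dbo <- colSums(dOut)
  dCtx <- dOut %*% t(p$Wo)

  if (cache$path == "bcast") {
    # constant attention: no gradient through scores
    dQ <- matrix(0, B * nq, d)
    dK <- matrix(0, B, d)
    dV <- rowsum(dCtx, cache$grp)
  } else if (cache$path == "vec1") {
    r <- cpp_mha_vec1_bw(dCtx, cache$Q, cache$K, cache$V, cache$A, n_heads,
                         (cache$k_perm %||% seq_len(nk)) - 1L,
                         (cache$v_perm %||% seq_len(nk)) - 1L)
    dQ <- r$dQ; dK <- r$dK; dV <- r$dV
  } else {
    r <- cpp_mha_gen_bw(dCtx, cache$Q, cache$K, cache$V, cache$A, n_heads,
                        B, nq, nk,
                        (cache$k_perm %||% seq_len(nk)) - 1L,
                        (cache$v_perm %||% seq_len(nk)) - 1L)
    dQ <- r$dQ; dK <- r$dK; dV <- r$dV
  }
  dXq <- dQ %*% t(p$Wq)
  dXk <- dK %*% t(p$Wk)
  dXv <- dV %*% t(p$Wv)
  dp <- list(Wq = crossprod(cache$Xq, dQ), bq = colSums(dQ),
             Wk = crossprod(cache$Xk, dK), bk = colSums(dK),
             Wv = crossprod(cache$Xv, dV), bv = colSums(dV),
             Wo = dWo, bo = dbo)
  list(dXq = dXq, dXk = dXk, dXv = dXv, dp = dp)
}

# --- convolution via im2col gather -------------------------------------

# index matrix (out_positions x k*k*C) into a zero-padded (Hp, Wp, C) volume
im2col_index <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  oH <- (Hp - k) %/% stride + 1L
  oW <- (Wp - k) %/% stride + 1L
  base_r <- rep((seq_len(oH) - 1L) * stride, times = oW)
  base_c <- rep((seq_len(oW) - 1L) * stride, each = oH)
  kr <- rep(seq_len(k), times = k * C)
  kc <- rep(rep(seq_len(k), each = k), times = C)
  chf <- rep(seq_len(C), each = k * k)
  idx <- outer(base_r, kr, `+`) +
    (outer(base_c, kc, `+`) - 1L) * Hp +
    matrix((chf - 1L) * Hp * Wp, nrow = oH * oW, ncol = k * k * C,
           byrow = TRUE)
  list(idx = idx, oH = oH, oW = oW, Hp = Hp, Wp = Wp)
}

pad_image <- function(X, pad, value = 0) {
  if (pad == 0) return(X)
  d <- dim(X)
  Xp <- array(value, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  Xp
}

# cached batch-expanded gather index per layer geometry
.conv_memo <- new.env(parent = emptyenv())

conv_batch_info <- function(info, C, B) {
  oHW <- info$oH * info$oW
  kkC <- ncol(info$idx)
  if (as.double(oHW) * B * kkC > 2e7) return(NULL)  # fall back if huge
  key <- paste(info$Hp, info$Wp, C, oHW, kkC, B, sep = "_")
  bi <- .conv_memo[[key]]
  if (!is.null(bi)) return(bi)
  vol <- info$Hp * info$Wp * C
  idxb <- matrix(0L, oHW * B, kkC)
  for (b in seq_len(B)) {
    idxb[((b - 1L) * oHW + 1L):(b * oHW), ] <-
      as.integer(info$idx + (b - 1L) * vol)
  }
  bi <- list(idxb = idxb, vol = vol)
  .conv_memo[[key]] <- bi
  bi
}

# X: (H, W, C, B); returns col matrix ((B*oH*oW) x k*k*C), rows
# position-major within sample
im2col <- function(X, info, pad, pad_value = 0) {
  d <- dim(X)
  B <- d[4]
  Xp <- pad_image(X, pad, value = pad_value)
  bi <- conv_batch_info(info, d[3], B)
  oHW <- info$oH * info$oW
  kkC <- ncol(info$idx)
  if (!is.null(bi)) return(cpp_gather(Xp, bi$idxb))
  Xm <- matrix(Xp, ncol = B)      # (Hp*Wp*C) x B
  g <- Xm[as.vector(info$idx), , drop = FALSE]  # (oHW*kkC) x B
  dim(g) <- c(oHW, kkC, B)
  g <- aperm(g, c(1, 3, 2))
  dim(g) <- c(oHW * B, kkC)
  g
}

# scatter-add of dcol back to the input image gradient
col2im <- function(dcol, info, H, W, C, B, pad) {
  oHW <- info$oH * info$oW
  kkC <- ncol(info$idx)
  bi <- conv_batch_info(info, C, B)
  if (!is.null(bi)) {
    dXp <- array(cpp_scatter_add(dcol, bi$idxb, bi$vol * B),
                 c(info$Hp, info$Wp, C, B))
  } else {
    dim(dcol) <- c(oHW, B, kkC)
    dcol <- aperm(dcol, c(1, 3, 2))
    dim(dcol) <- c(oHW * kkC, B)
    gidx <- as.vector(info$idx)
    rs <- rowsum(dcol, group = gidx)
    dXp <- matrix(0, info$Hp * info$Wp * C, B)
    dXp[as.integer(rownames(rs)), ] <- rs
    dXp <- array(dXp, c(info$Hp, info$Wp, C, B))
  }
  if (pad > 0) dXp <- dXp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  dXp
}

# p: list(W = (k*k*Cin x Cout), b = Cout); X: (H, W, Cin, B)
conv2d_fw <- function(X, p, k, stride, pad) {
  d <- dim(X)
  info <- im2col_index(d[1], d[2], d[3], k, stride, pad)
  col <- im2col(X, info, pad)
  out_m <- cpp_linear(col, p$W, p$b)
  B <- d[4]
  out <- array(0, c(info$oH, info$oW, ncol(p$W), B))
  # rows of out_m are position-major within sample
  dim(out_m) <- c(info$oH * info$oW, B, ncol(p$W))
  out <- aperm(out_m, c(1, 3, 2))
  dim(out) <- c(info$oH, info$oW, ncol(p$W), B)
  list(out = out,
       cache = list(col = col, p = p, k = k, stride = stride, pad = pad,
                    info = info, dims = d))
}

# need_dx = FALSE skips the input-gradient scatter (input layers)
conv2d_bw <- function(dY, cache, need_dx = TRUE) {
  d <- cache$dims
  B <- d[4]
  info <- cache$info
  Cout <- ncol(cache$p$W)
  dYm <- aperm(array(dY, c(info$oH * info$oW, Cout, B)), c(1, 3, 2))
  dim(dYm) <- c(info$oH * info$oW * B, Cout)
  dW <- crossprod(cache$col, dYm)
  db <- colSums(dYm)
  dX <- NULL
  if (need_dx) {
    dcol <- dYm %*% t(cache$p$W)
    dX <- col2im(dcol, info, d[1], d[2], d[3], B, cache$pad)
  }
  list(dx = dX, dp = list(W = dW, b = db))
}

maxpool_fw <- function(X, k, stride, pad = 0) {
  d <- dim(X)
  B <- d[4]; C <- d[3]
  info <- im2col_index(d[1], d[2], C, k, stride, pad)
  col <- im2col(X, info, pad, pad_value = -Inf)
  oHW <- info$oH * info$oW
  kk <- k * k
  out <- array(0, c(oHW * B, C))
  amax <- array(0L, c(oHW * B, C))
  for (ch in seq_len(C)) {
    blk <- col[, ((ch - 1) * kk + 1):(ch * kk), drop = FALSE]
    mx <- blk[, 1]; wm <- rep(1L, nrow(blk))
    for (j in seq_len(kk)[-1]) {
      upd <- blk[, j] > mx
      mx[upd] <- blk[upd, j]
      wm[upd] <- j
    }
    out[, ch] <- mx
    amax[, ch] <- wm
  }
  outa <- aperm(array(out, c(oHW, B, C)), c(1, 3, 2))
  dim(outa) <- c(info$oH, info$oW, C, B)
  list(out = outa,
       cache = list(amax = amax, info = info, k = k, pad = pad, dims = d))
}

maxpool_bw <- function(dY, cache) {
  d <- cache$dims
  B <- d[4]; C <- d[3]
  info <- cache$info
  oHW <- info$oH * info$oW
  kk <- cache$k^2
  dYm <- aperm(array(dY, c(oHW, C, B)), c(1, 3, 2))
  dim(dYm) <- c(oHW * B, C)
  dcol <- matrix(0, oHW * B, kk * C)
  rows <- seq_len(oHW * B)
  for (ch in seq_len(C)) {
    cols <- (ch - 1) * kk + cache$amax[, ch]
    dcol[cbind(rows, cols)] <- dYm[, ch]
  }
  col2im(dcol, info, d[1], d[2], d[3], B, cache$pad)
}

# batch norm in inference mode (fixed running statistics per channel)
bnorm_fw <- function(X, p, eps = 1e-5) {
  C <- dim(X)[3]
  scale <- p$gamma / sqrt(p$var + eps)
  shift <- p$beta - p$mean * scale
  out <- sweep(X, 3, scale, `*`)
  out <- sweep(out, 3, shift, `+`)
  list(out = out, cache = list(scale = scale))
}

bnorm_bw <- function(dY, cache) {
  sweep(dY, 3, cache$scale, `*`)
}

init_bnorm <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C), mean = numeric(C), var = rep(1, C))
}

# feature map (H, W, C, B) -> token matrix ((B*H*W) x C), position-major
# within sample (column-major spatial order)
map_to_tokens <- function(X) {
  d <- dim(X)
  t <- aperm(X, c(1, 2, 4, 3))
  dim(t) <- c(d[1] * d[2] * d[4], d[3])
  t
}

tokens_to_map <- function(T, H, W, C, B) {
  dim(T) <- c(H * W, B, C)
  T <- aperm(T, c(1, 3, 2))
  dim(T) <- c(H, W, C, B)
  T
}

# transpose token blocks per sample: ((B*n) x d) -> ((B*d) x n)
transpose_tokens <- function(T, B, n, d) {
  dim(T) <- c(n, B, d)
  T <- aperm(T, c(3, 2, 1))
  dim(T) <- c(d * B, n)
  T
}
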