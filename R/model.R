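# The prediction network: an expression encoder embeds the initial
# expression (IE) prior into a single prompt token, an attention-augmented
# CNN encodes the patch into spatial tokens, and a two-way cross-attention
# decoder fuses the two streams over repeated rounds before a linear
# regression head emits the per-gene prediction.

MODEL_VARIANTS <- c("default", "random_ie", "cellratio_noise", "plain_cnn",
                    "concat", "deep3", "cross_gate_zero", "scramble_kv")

#' Model configuration
#'
#' Describes the architecture dimensions, decoder iteration count and
#' ablation variant of the prediction network.
#'
#' @param n_genes Number of genes in the panel (output length).
#' @param backbone `"resnet34"` (224x224 input, 7x7x512 feature map, 49
#'   tokens of width 512) or `"small"` (a compact strided CNN for
#'   desk-scale studies: 64x64 input, 4x4 tokens).
#' @param d_att Attention/token width; must match the backbone's channel
#'   dimension (512 for `"resnet34"`; free for `"small"`).
#' @param n_heads Attention heads for all token-stream attention sites
#'   (must divide `d_att`). Channel self-attention always uses one head
#'   because its feature width is the token count.
#' @param mlp_hidden Hidden width of the decoder MLPs and encoders.
#' @param decoder_rounds Number of decoder iteration rounds (2 by default;
#'   the `deep3` variant forces 3).
#' @param variant One of `"default"`, `"random_ie"`, `"cellratio_noise"`,
#'   `"plain_cnn"`, `"concat"`, `"deep3"`, `"cross_gate_zero"`,
#'   `"scramble_kv"`.
#' @param seed Integer seed from which every weight and every variant
#'   randomization is derived.
#' @param patch_size Input patch side in pixels (224 for `"resnet34"`,
#'   64 for `"small"`).
#' @param cellratio_noise_level Mixing weight of the Dirichlet perturbation
#'   applied to cell-type ratios under the `cellratio_noise` variant.
#' @param scramble_perms Optional list with integer vectors `k` and `v`
#'   (permutations of the image-token order) for the `scramble_kv`
#'   variant; if `NULL` they are drawn from `seed`.
#'
#' @return A `scspot_config` list.
#' @export
scspot_config <- function(n_genes,
                          backbone = c("resnet34", "small"),
                          d_att = NULL, n_heads = NULL,
                          mlp_hidden = NULL, decoder_rounds = 2L,
                          variant = "default", seed = 1L,
                          patch_size = NULL,
                          cellratio_noise_level = 0.3,
                          scramble_perms = NULL) {
  backbone <- match.arg(backbone)
  if (!variant %in% MODEL_VARIANTS) {
    stopf("unknown variant '%s'; valid variants: %s", variant,
          paste(MODEL_VARIANTS, collapse = ", "))
  }
  if (backbone == "resnet34") {
    d_att <- d_att %||% 512L
    if (d_att != 512L) stopf("d_att must be 512 for the resnet34 backbone")
    patch_size <- patch_size %||% 224L
    n_heads <- n_heads %||% 8L
  } else {
    d_att <- d_att %||% 32L
    patch_size <- patch_size %||% 64L
    n_heads <- n_heads %||% 2L
  }
  n_coord <- as.integer((patch_size / if (backbone == "resnet34") 32 else 16)^2)
  if (d_att %% n_heads != 0) stopf("d_att must be divisible by n_heads")
  if (decoder_rounds < 1) stopf("decoder_rounds must be >= 1")
  if (variant == "deep3") decoder_rounds <- 3L
  structure(list(
    n_genes = as.integer(n_genes), backbone = backbone,
    d_att = as.integer(d_att), n_coord = n_coord,
    n_heads = as.integer(n_heads),
    mlp_hidden = as.integer(mlp_hidden %||% (2L * d_att)),
    decoder_rounds = as.integer(decoder_rounds),
    variant = variant, seed = as.integer(seed),
    patch_size = as.integer(patch_size),
    cellratio_noise_level = cellratio_noise_level,
    scramble_perms = scramble_perms
  ), class = "scspot_config")
}

#' @rdname scspot_config
#' @param ... Passed on to [scspot_config()].
#' @export
small_model_config <- function(n_genes, ...) {
  scspot_config(n_genes, backbone = "small", ...)
}

# channel normalization applied to [0,1] RGB patches before the backbone
PATCH_NORM_MEAN <- c(0.485, 0.456, 0.406)
PATCH_NORM_SD <- c(0.229, 0.224, 0.225)

#' Build a model (including ablation variants) from a configuration
#'
#' Initializes every module's weights from `config$seed`. Weight
#' initialization draws the same random sequence for every variant, so
#' variants of the same seed share identical weights for the modules they
#' have in common (the `scramble_kv` variant with identity permutations is
#' weight-for-weight the default model).
#'
#' Variant behaviours: `random_ie` replaces the IE of every spot by a
#' seeded standard-normal vector; `cellratio_noise` mixes the cell-type
#' ratios with a seeded Dirichlet draw before composing the IE;
#' `plain_cnn` drops the channel/spatial self-attention from the image
#' encoder; `concat` replaces the decoder by concatenation of the mean
#' image token with the expression token followed by an MLP; `deep3` runs
#' three decoder rounds; `cross_gate_zero` multiplies every cross-attention
#' output by zero (residual paths only); `scramble_kv` permutes key and
#' value tokens independently at the image-attended sites.
#'
#' @param config A [scspot_config()].
#' @return A `scspot_model` object.
#' @export
make_variant <- function(config) {
  stopifnot(inherits(config, "scspot_config"))
  params <- with_seed(config$seed, {
    d <- config$d_att
    list(
      expr_enc = init_mlp(config$n_genes, config$mlp_hidden, d),
      backbone = init_backbone(config$backbone, d),
      csa = list(mha = init_mha(config$n_coord),
                 ln = init_layernorm(config$n_coord)),
      ssa = list(mha = init_mha(d), ln = init_layernorm(d)),
      dec = list(
        self = init_mha(d), ln_self = init_layernorm(d),
        e2i = init_mha(d), ln_e2i = init_layernorm(d),
        mlp1 = init_mlp(d, config$mlp_hidden, d),
        ln_mlp1 = init_layernorm(d),
        i2e = init_mha(d), ln_i2e = init_layernorm(d),
        term = init_mha(d), ln_term = init_layernorm(d),
        mlp2 = init_mlp(d, config$mlp_hidden, d),
        ln_mlp2 = init_layernorm(d)
      ),
      concat_mlp = init_mlp(2L * d, config$mlp_hidden, d),
      head = init_linear(d, config$n_genes)
    )
  })
  scramble <- NULL
  if (config$variant == "scramble_kv") {
    scramble <- config$scramble_perms %||% with_seed(
      child_seed(config$seed, 77L),
      list(k = sample(config$n_coord), v = sample(config$n_coord)))
    stopifnot(length(scramble$k) == config$n_coord,
              length(scramble$v) == config$n_coord)
  }
  structure(list(
    config = config, params = params,
    gate = if (config$variant == "cross_gate_zero") 0 else 1,
    scramble = scramble
  ), class = "scspot_model")
}

#' @rdname make_variant
#' @export
scspot_model <- function(config) make_variant(config)

#' @export
print.scspot_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<scspot_model> variant=%s backbone=%s d_att=%d n_coord=%d heads=%d rounds=%d genes=%d seed=%d\n",
    cfg$variant, cfg$backbone, cfg$d_att, cfg$n_coord, cfg$n_heads,
    cfg$decoder_rounds, cfg$n_genes, cfg$seed))
  invisible(x)
}

normalize_patches <- function(X) {
  for (ch in 1:3) {
    X[, , ch, ] <- (X[, , ch, ] - PATCH_NORM_MEAN[ch]) / PATCH_NORM_SD[ch]
  }
  X
}

# --- full forward pass --------------------------------------------------

# patches: (H, W, 3, B) in [0, 1]; ie: (B x n_genes).
# Returns pred (B x n_genes), cache for backward, and optional hooks:
# round-initial queries and attention row sums at every site.
# `normalized` skips channel standardization when the caller already did it.
forward_scspot <- function(model, patches, ie, hooks = FALSE,
                           normalized = FALSE) {
  cfg <- model$config
  p <- model$params
  dp <- dim(patches)
  if (length(dp) == 3L) {
    dim(patches) <- c(dp, 1L)
    dp <- dim(patches)
  }
  if (dp[1] != cfg$patch_size || dp[2] != cfg$patch_size || dp[3] != 3L) {
    stopf("patches must be %dx%dx3, got %dx%dx%d",
          cfg$patch_size, cfg$patch_size, dp[1], dp[2], dp[3])
  }
  if (is.null(dim(ie))) ie <- matrix(ie, nrow = 1L)
  if (ncol(ie) != cfg$n_genes) {
    stopf("IE length %d does not match the %d-gene panel", ncol(ie),
          cfg$n_genes)
  }
  B <- dp[4]
  if (nrow(ie) != B) stopf("got %d patches but %d IE rows", B, nrow(ie))
  d <- cfg$d_att
  n <- cfg$n_coord
  hk <- if (hooks) list(attn_rowsums = list(), round_queries = list()) else NULL

  # expression encoder: linear -> GELU -> linear
  e_l1 <- linear_fw(ie, p$expr_enc$fc1)
  e_g <- gelu_fw(e_l1$out)
  e_l2 <- linear_fw(e_g$out, p$expr_enc$fc2)
  E0 <- e_l2$out

  # image encoder
  x <- if (normalized) patches else normalize_patches(patches)
  bk <- backbone_fw(x, p$backbone, cfg$backbone)
  if (bk$n != n) stopf("backbone produced %d tokens, expected %d", bk$n, n)
  T0 <- bk$tokens
  enc <- list()
  if (cfg$variant == "plain_cnn") {
    Timg <- T0
  } else {
    Xc <- transpose_tokens(T0, B, n, d)
    csa <- mha_fw(Xc, Xc, Xc, p$csa$mha, 1L, B, d, d, record_attn = hooks)
    csa_ln <- layernorm_fw(Xc + csa$out, p$csa$ln)
    T1 <- transpose_tokens(csa_ln$out, B, d, n)
    ssa <- mha_fw(T1, T1, T1, p$ssa$mha, cfg$n_heads, B, n, n,
                  record_attn = hooks)
    ssa_ln <- layernorm_fw(T1 + ssa$out, p$ssa$ln)
    Timg <- ssa_ln$out
    enc <- list(csa = csa$cache, csa_ln = csa_ln$cache,
                ssa = ssa$cache, ssa_ln = ssa_ln$cache)
    if (hooks) {
      hk$attn_rowsums$csa <- attn_rowsums(csa$attn)
      hk$attn_rowsums$ssa <- attn_rowsums(ssa$attn)
    }
  }

  if (cfg$variant == "concat") {
    # mean image token per sample, concatenated with the expression token
    zm <- rowsum(Timg, group = rep(seq_len(B), each = n)) / n
    hcat <- cbind(zm, E0)
    c_l1 <- linear_fw(hcat, p$concat_mlp$fc1)
    c_g <- gelu_fw(c_l1$out)
    c_l2 <- linear_fw(c_g$out, p$concat_mlp$fc2)
    hd <- linear_fw(c_l2$out, p$head)
    cache <- list(kind = "concat", B = B, n = n, d = d,
                  e_l1 = e_l1$cache, e_g = e_g$cache, e_l2 = e_l2$cache,
                  bk = bk$cache, enc = enc,
                  c_l1 = c_l1$cache, c_g = c_g$cache, c_l2 = c_l2$cache,
                  head = hd$cache, model = model)
    return(list(pred = hd$out, cache = cache, hooks = hk))
  }

  dec <- decoder_fw(model, E0, Timg, B, hooks = hooks)
  if (hooks) {
    hk$attn_rowsums <- c(hk$attn_rowsums, dec$hooks$attn_rowsums)
    hk$round_queries <- dec$hooks$round_queries
  }
  hd <- linear_fw(dec$out, p$head)
  cache <- list(kind = "full", B = B, n = n, d = d,
                e_l1 = e_l1$cache, e_g = e_g$cache, e_l2 = e_l2$cache,
                bk = bk$cache, enc = enc, dec = dec$cache,
                head = hd$cache, model = model)
  list(pred = hd$out, cache = cache, hooks = hk)
}

attn_rowsums <- function(attn) {
  unlist(lapply(attn, function(ab) lapply(ab, rowSums)))
}

# --- decoder ------------------------------------------------------------
#
# Shared-weight block applied `decoder_rounds` times:
#   self-attention on the query stream -> expr2img cross-attention ->
#   MLP -> img2expr cross-attention,
# with the round-1 query initialized to the expression embedding alone and
# later rounds initialized from the previous round's MLP output. A
# terminal expr2img attention then re-centres the output on the expression
# stream, followed by the second MLP. Cross-attention outputs are scaled
# by `model$gate` (0 under cross_gate_zero) before their residual add.

decoder_fw <- function(model, E0, Timg, B, hooks = FALSE) {
  cfg <- model$config
  pd <- model$params$dec
  g <- model$gate
  H <- cfg$n_heads
  n <- cfg$n_coord
  kp <- model$scramble$k
  vp <- model$scramble$v
  rounds <- cfg$decoder_rounds
  rc <- vector("list", rounds)
  hk <- if (hooks) list(attn_rowsums = list(), round_queries = list()) else NULL

  img <- Timg
  m <- NULL
  for (r in seq_len(rounds)) {
    qin <- if (r == 1L) E0 else m
    if (hooks) hk$round_queries[[r]] <- qin
    sa <- mha_fw(qin, qin, qin, pd$self, H, B, 1L, 1L, record_attn = hooks)
    ln_s <- layernorm_fw(qin + sa$out, pd$ln_self)
    q1 <- ln_s$out
    e2i <- mha_fw(E0 + q1, img, img, pd$e2i, H, B, 1L, n,
                  k_perm = kp, v_perm = vp, record_attn = hooks)
    ln_e <- layernorm_fw(q1 + g * e2i$out, pd$ln_e2i)
    q2 <- ln_e$out
    m_l1 <- linear_fw(q2, pd$mlp1$fc1)
    m_g <- gelu_fw(m_l1$out)
    m_l2 <- linear_fw(m_g$out, pd$mlp1$fc2)
    ln_m <- layernorm_fw(q2 + m_l2$out, pd$ln_mlp1)
    m <- ln_m$out
    i2e <- mha_fw(img, E0 + m, m, pd$i2e, H, B, n, 1L, record_attn = hooks)
    ln_i <- layernorm_fw(img + g * i2e$out, pd$ln_i2e)
    img_new <- ln_i$out
    rc[[r]] <- list(sa = sa$cache, ln_s = ln_s$cache, e2i = e2i$cache,
                    ln_e = ln_e$cache, m_l1 = m_l1$cache, m_g = m_g$cache,
                    m_l2 = m_l2$cache, ln_m = ln_m$cache, i2e = i2e$cache,
                    ln_i = ln_i$cache)
    if (hooks) {
      hk$attn_rowsums[[paste0("self_r", r)]] <- attn_rowsums(sa$attn)
      hk$attn_rowsums[[paste0("expr2img_r", r)]] <- attn_rowsums(e2i$attn)
      hk$attn_rowsums[[paste0("img2expr_r", r)]] <- attn_rowsums(i2e$attn)
    }
    img <- img_new
  }
  term <- mha_fw(E0 + m, img, img, pd$term, H, B, 1L, n,
                 k_perm = kp, v_perm = vp, record_attn = hooks)
  ln_t <- layernorm_fw(m + g * term$out, pd$ln_term)
  qf <- ln_t$out
  f_l1 <- linear_fw(qf, pd$mlp2$fc1)
  f_g <- gelu_fw(f_l1$out)
  f_l2 <- linear_fw(f_g$out, pd$mlp2$fc2)
  ln_f <- layernorm_fw(qf + f_l2$out, pd$ln_mlp2)
  if (hooks) hk$attn_rowsums$terminal <- attn_rowsums(term$attn)
  list(out = ln_f$out,
       cache = list(rounds = rc, term = term$cache, ln_t = ln_t$cache,
                    f_l1 = f_l1$cache, f_g = f_g$cache, f_l2 = f_l2$cache,
                    ln_f = ln_f$cache, g = g, n_rounds = rounds),
       hooks = hk)
}

decoder_bw <- function(dOut, cache, model) {
  g <- cache$g
  dp <- list() # accumulated param grads for the shared decoder tree

  acc <- function(piece) {
    for (nm in names(piece)) {
      dp[[nm]] <<- if (is.null(dp[[nm]])) piece[[nm]] else
        tree_add(dp[[nm]], piece[[nm]])
    }
  }

  lf <- layernorm_bw(dOut, cache$ln_f)
  acc(list(ln_mlp2 = lf$dp))
  dqf <- lf$dx
  l2 <- linear_bw(lf$dx, cache$f_l2)
  dg <- gelu_bw(l2$dx, cache$f_g)
  l1 <- linear_bw(dg, cache$f_l1)
  acc(list(mlp2 = list(fc1 = l1$dp, fc2 = l2$dp)))
  dqf <- dqf + l1$dx

  lt <- layernorm_bw(dqf, cache$ln_t)
  acc(list(ln_term = lt$dp))
  dm <- lt$dx
  tb <- mha_bw(g * lt$dx, cache$term)
  acc(list(term = tb$dp))
  dE0 <- tb$dXq
  dm <- dm + tb$dXq
  dimg <- tb$dXk + tb$dXv

  for (r in rev(seq_len(cache$n_rounds))) {
    rc <- cache$rounds[[r]]
    li <- layernorm_bw(dimg, rc$ln_i)
    acc(list(ln_i2e = li$dp))
    dimg_prev <- li$dx
    ib <- mha_bw(g * li$dx, rc$i2e)
    acc(list(i2e = ib$dp))
    dimg_prev <- dimg_prev + ib$dXq
    dE0 <- dE0 + ib$dXk
    dm <- dm + ib$dXk + ib$dXv

    lm <- layernorm_bw(dm, rc$ln_m)
    acc(list(ln_mlp1 = lm$dp))
    dq2 <- lm$dx
    ml2 <- linear_bw(lm$dx, rc$m_l2)
    mdg <- gelu_bw(ml2$dx, rc$m_g)
    ml1 <- linear_bw(mdg, rc$m_l1)
    acc(list(mlp1 = list(fc1 = ml1$dp, fc2 = ml2$dp)))
    dq2 <- dq2 + ml1$dx

    le <- layernorm_bw(dq2, rc$ln_e)
    acc(list(ln_e2i = le$dp))
    dq1 <- le$dx
    eb <- mha_bw(g * le$dx, rc$e2i)
    acc(list(e2i = eb$dp))
    dE0 <- dE0 + eb$dXq
    dq1 <- dq1 + eb$dXq
    dimg_prev <- dimg_prev + eb$dXk + eb$dXv

    ls <- layernorm_bw(dq1, rc$ln_s)
    acc(list(ln_self = ls$dp))
    dqin <- ls$dx
    sb <- mha_bw(ls$dx, rc$sa)
    acc(list(self = sb$dp))
    dqin <- dqin + sb$dXq + sb$dXk + sb$dXv

    if (r == 1L) dE0 <- dE0 + dqin else dm <- dqin
    dimg <- dimg_prev
  }
  # align param-grad layout with params$dec
  layout <- model$params$dec
  dp_full <- tree_zeros_like(layout)
  for (nm in names(dp)) dp_full[[nm]] <- tree_add(dp_full[[nm]], dp[[nm]])
  list(dE0 = dE0, dTimg = dimg, dp = dp_full)
}

# --- full backward ------------------------------------------------------

backward_scspot <- function(dPred, cache, need_input_grads = FALSE) {
  model <- cache$model
  cfg <- model$config
  p <- model$params
  B <- cache$B; n <- cache$n; d <- cache$d
  grads <- tree_zeros_like(p)

  hb <- linear_bw(dPred, cache$head)
  grads$head <- hb$dp

  if (cache$kind == "concat") {
    c2 <- linear_bw(hb$dx, cache$c_l2)
    cg <- gelu_bw(c2$dx, cache$c_g)
    c1 <- linear_bw(cg, cache$c_l1)
    grads$concat_mlp <- list(fc1 = c1$dp, fc2 = c2$dp)
    dzm <- c1$dx[, seq_len(d), drop = FALSE]
    dE0 <- c1$dx[, d + seq_len(d), drop = FALSE]
    dTimg <- (dzm / n)[rep(seq_len(B), each = n), , drop = FALSE]
  } else {
    db <- decoder_bw(hb$dx, cache$dec, model)
    grads$dec <- db$dp
    dE0 <- db$dE0
    dTimg <- db$dTimg
  }

  # image encoder backward
  if (cfg$variant == "plain_cnn") {
    dT0 <- dTimg
  } else {
    sl <- layernorm_bw(dTimg, cache$enc$ssa_ln)
    grads$ssa$ln <- sl$dp
    dT1 <- sl$dx
    sb <- mha_bw(sl$dx, cache$enc$ssa)
    grads$ssa$mha <- sb$dp
    dT1 <- dT1 + sb$dXq + sb$dXk + sb$dXv
    dXc1 <- transpose_tokens(dT1, B, n, d)
    cl <- layernorm_bw(dXc1, cache$enc$csa_ln)
    grads$csa$ln <- cl$dp
    dXc <- cl$dx
    cb <- mha_bw(cl$dx, cache$enc$csa)
    grads$csa$mha <- cb$dp
    dXc <- dXc + cb$dXq + cb$dXk + cb$dXv
    dT0 <- transpose_tokens(dXc, B, d, n)
  }
  bb <- backbone_bw(dT0, cache$bk, cfg$backbone, need_dx = need_input_grads)
  grads$backbone <- bb$dp

  # expression encoder backward
  e2 <- linear_bw(dE0, cache$e_l2)
  eg <- gelu_bw(e2$dx, cache$e_g)
  e1 <- linear_bw(eg, cache$e_l1)
  grads$expr_enc <- list(fc1 = e1$dp, fc2 = e2$dp)
  d_ie <- e1$dx
  list(grads = grads, d_ie = d_ie, d_image = bb$dx)
}
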