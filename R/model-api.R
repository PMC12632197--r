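# User-facing operations on a fitted or initialized model: the individual
# encoder/decoder stages (useful for inspection and testing) and the
# end-to-end prediction method.

#' Embed an initial-expression vector into the attention space
#'
#' Two affine maps with a GELU in between: `n_genes -> mlp_hidden -> d_att`.
#'
#' @param ie Numeric vector of length `n_genes` (or a matrix with one row
#'   per spot).
#' @param model A `scspot_model`.
#' @return Matrix `(n_spots x d_att)`; a single vector gives one row.
#' @export
encode_expr <- function(ie, model) {
  stopifnot(inherits(model, "scspot_model"))
  if (is.null(dim(ie))) ie <- matrix(ie, nrow = 1L)
  if (ncol(ie) != model$config$n_genes) {
    stopf("IE length %d does not match the %d-gene panel", ncol(ie),
          model$config$n_genes)
  }
  p <- model$params$expr_enc
  linear_fw(gelu_fw(linear_fw(ie, p$fc1)$out)$out, p$fc2)$out
}

#' Encode an image patch into spatial attention tokens
#'
#' Runs the CNN backbone and (unless the `plain_cnn` variant) channel
#' self-attention followed by spatial self-attention, each with a residual
#' connection and layer norm.
#'
#' @param patch RGB array `(patch_size, patch_size, 3)` with values in
#'   `[0, 1]`, or a batch `(patch_size, patch_size, 3, B)`.
#' @param model A `scspot_model`.
#' @return Token matrix `(n_coord x d_att)` for a single patch, or
#'   `((B * n_coord) x d_att)` for a batch.
#' @export
encode_image <- function(patch, model) {
  stopifnot(inherits(model, "scspot_model"))
  cfg <- model$config
  dp <- dim(patch)
  if (length(dp) == 3L) dim(patch) <- c(dp, 1L)
  dp <- dim(patch)
  if (dp[1] != cfg$patch_size || dp[2] != cfg$patch_size || dp[3] != 3L) {
    stopf("patch must be %dx%dx3", cfg$patch_size, cfg$patch_size)
  }
  B <- dp[4]
  p <- model$params
  bk <- backbone_fw(normalize_patches(patch), p$backbone, cfg$backbone)
  T0 <- bk$tokens
  if (cfg$variant == "plain_cnn") return(T0)
  n <- cfg$n_coord; d <- cfg$d_att
  Xc <- transpose_tokens(T0, B, n, d)
  csa <- mha_fw(Xc, Xc, Xc, p$csa$mha, 1L, B, d, d)
  T1 <- transpose_tokens(layernorm_fw(Xc + csa$out, p$csa$ln)$out, B, d, n)
  ssa <- mha_fw(T1, T1, T1, p$ssa$mha, cfg$n_heads, B, n, n)
  layernorm_fw(T1 + ssa$out, p$ssa$ln)$out
}

#' Decoder cross-attention stages
#'
#' `expr2img_attention()` attends from the expression stream into the image
#' tokens: the query is the expression embedding plus the current query
#' stream state, the image tokens serve as both key and value, and the
#' result is residual-added to the query stream and layer-normalized.
#' `img2expr_attention()` is the reverse direction: the image tokens query
#' the expression stream, with key = expression embedding + MLP output and
#' value = MLP output, residual-added to the image stream.
#'
#' @param expr_emb Expression embedding, `(1 x d_att)`.
#' @param carry_state Current query-stream state, `(1 x d_att)`.
#' @param img_emb Image token matrix `(n_coord x d_att)`.
#' @param mlp_out Decoder MLP output token `(1 x d_att)`.
#' @param model A `scspot_model`.
#' @return The updated query token (`expr2img`) or updated image tokens
#'   (`img2expr`).
#' @export
expr2img_attention <- function(expr_emb, carry_state, img_emb, model) {
  stopifnot(inherits(model, "scspot_model"))
  pd <- model$params$dec
  n <- nrow(img_emb)
  at <- mha_fw(expr_emb + carry_state, img_emb, img_emb, pd$e2i,
               model$config$n_heads, 1L, 1L, n,
               k_perm = model$scramble$k, v_perm = model$scramble$v)
  layernorm_fw(carry_state + model$gate * at$out, pd$ln_e2i)$out
}

#' @rdname expr2img_attention
#' @export
img2expr_attention <- function(img_emb, expr_emb, mlp_out, model) {
  stopifnot(inherits(model, "scspot_model"))
  pd <- model$params$dec
  n <- nrow(img_emb)
  at <- mha_fw(img_emb, expr_emb + mlp_out, mlp_out, pd$i2e,
               model$config$n_heads, 1L, n, 1L)
  layernorm_fw(img_emb + model$gate * at$out, pd$ln_i2e)$out
}

#' Run the full two-way decoder on precomputed embeddings
#'
#' Applies the shared decoder block (self-attention on the query stream,
#' expr2img cross-attention, MLP, img2expr cross-attention) for
#' `decoder_rounds` rounds — the round-1 query is the expression embedding
#' alone, later rounds start from the previous round's MLP output — then
#' the terminal expr2img attention and the second MLP.
#'
#' @param img_emb Image token matrix `(n_coord x d_att)` (one sample).
#' @param expr_emb Expression embedding `(1 x d_att)`.
#' @param model A `scspot_model`.
#' @param hooks If `TRUE`, attach an attribute `"hooks"` with the
#'   round-initial queries and per-site attention row sums.
#' @return The output query token `(1 x d_att)`.
#' @export
sc_informed_decode <- function(img_emb, expr_emb, model, hooks = FALSE) {
  stopifnot(inherits(model, "scspot_model"))
  if (nrow(img_emb) != model$config$n_coord) {
    stopf("img_emb must have %d token rows", model$config$n_coord)
  }
  dec <- decoder_fw(model, expr_emb, img_emb, B = 1L, hooks = hooks)
  out <- dec$out
  if (hooks) attr(out, "hooks") <- dec$hooks
  out
}

#' Predict expression for a batch of patches
#'
#' Runs the image encoder, expression encoder, decoder and regression head.
#' Under the `random_ie` variant the supplied IE rows are replaced by
#' seeded standard-normal vectors (deterministic per row index and model
#' seed, so a spot keeps its noise vector across epochs and calls).
#'
#' @param object A `scspot_model`.
#' @param patches Array `(patch_size, patch_size, 3, n_spots)` in `[0, 1]`.
#' @param ie Matrix `(n_spots x n_genes)` of initial-expression priors.
#' @param batch_size Spots per forward pass.
#' @param ... Unused.
#' @return Matrix `(n_spots x n_genes)` of predicted normalized
#'   log-expression.
#' @export
predict.scspot_model <- function(object, patches, ie, batch_size = 32L, ...) {
  if (is.null(dim(ie))) ie <- matrix(ie, nrow = 1L)
  dp <- dim(patches)
  if (length(dp) == 3L) dim(patches) <- c(dp, 1L)
  B <- dim(patches)[4]
  ie <- apply_ie_variant(object, ie)
  out <- matrix(0, B, object$config$n_genes)
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    fw <- forward_scspot(object, patches[, , , idx, drop = FALSE],
                         ie[idx, , drop = FALSE])
    out[idx, ] <- fw$pred
  }
  rownames(out) <- rownames(ie)
  out
}

# replace IE rows by seeded noise under the random_ie variant
apply_ie_variant <- function(model, ie) {
  if (model$config$variant != "random_ie") return(ie)
  noise <- with_seed(child_seed(model$config$seed, 11L),
                     matrix(rnorm(nrow(ie) * ncol(ie)), nrow(ie), ncol(ie)))
  rownames(noise) <- rownames(ie)
  noise
}
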