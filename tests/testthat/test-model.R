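# Encoder, attention sites and decoder wiring, checked against manual
# linear-algebra traces on tiny configurations.

test_that("the expression encoder is Linear-GELU-Linear", {
  m <- tiny_model()
  # zero IE with zero biases gives a zero embedding
  mz <- m
  mz$params$expr_enc$fc1$b <- mz$params$expr_enc$fc1$b * 0
  mz$params$expr_enc$fc2$b <- mz$params$expr_enc$fc2$b * 0
  expect_identical(unname(encode_expr(rep(0, 7), mz)), matrix(0, 1, 8))
  # determinism: byte-identical embeddings across calls
  ie <- withr::with_seed(51, rnorm(7))
  expect_identical(encode_expr(ie, m), encode_expr(ie, m))
  # hand-set 2 -> 3 -> 4 toy weights against a by-hand computation
  W1 <- matrix(c(1, -1, 0.5, 2, 0, 1), 2, 3)
  b1 <- c(0.1, -0.2, 0.3)
  W2 <- matrix(seq(-0.5, 0.6, length.out = 12), 3, 4)
  b2 <- c(0, 0.5, -0.5, 1)
  x <- c(0.7, -1.2)
  h <- as.numeric(x %*% W1) + b1
  h <- h * pnorm(h)
  oracle <- as.numeric(h %*% W2) + b2
  toy <- list(params = list(expr_enc = list(fc1 = list(W = W1, b = b1),
                                            fc2 = list(W = W2, b = b2))),
              config = list(n_genes = 2))
  class(toy) <- "scspot_model"
  expect_equal(as.numeric(encode_expr(x, toy)), oracle, tolerance = 1e-12)
  expect_error(encode_expr(rep(0, 5), m), "panel")
})

test_that("every attention path matches the brute-force softmax(qk/sqrt(d))v oracle", {
  withr::with_seed(52, {
    d <- 8
    p <- scspot:::init_mha(d)
    for (shape in list(c(nq = 3, nk = 4, H = 2),  # general path
                       c(nq = 1, nk = 4, H = 2),  # single-query path
                       c(nq = 4, nk = 1, H = 1),  # broadcast path
                       c(nq = 1, nk = 1, H = 1))) {
      B <- 2
      Xq <- matrix(rnorm(B * shape["nq"] * d), B * shape["nq"], d)
      Xk <- matrix(rnorm(B * shape["nk"] * d), B * shape["nk"], d)
      got <- scspot:::mha_fw(Xq, Xk, Xk, p, shape[["H"]], B,
                             shape[["nq"]], shape[["nk"]])$out
      for (b in 1:B) {
        rq <- ((b - 1) * shape["nq"] + 1):(b * shape["nq"])
        rk <- ((b - 1) * shape["nk"] + 1):(b * shape["nk"])
        oracle <- manual_mha(Xq[rq, , drop = FALSE], Xk[rk, , drop = FALSE],
                             Xk[rk, , drop = FALSE], p, shape[["H"]])
        expect_equal(got[rq, , drop = FALSE], oracle, tolerance = 1e-6)
      }
    }
  })
})

test_that("expr2img attention: identical keys make the query irrelevant", {
  m <- tiny_model(seed = 53)
  tok <- withr::with_seed(53, matrix(rnorm(8), 1, 8))
  img_same <- tok[rep(1, 5), ]                  # five identical tokens
  e1 <- withr::with_seed(54, matrix(rnorm(8), 1, 8))
  e2 <- withr::with_seed(55, matrix(rnorm(8), 1, 8))
  carry <- matrix(0, 1, 8)
  o1 <- expr2img_attention(e1, carry, img_same, m)
  o2 <- expr2img_attention(e2, carry, img_same, m)
  expect_equal(o1, o2, tolerance = 1e-10)
  # single image token: attention output is its value projection
  one <- img_same[1, , drop = FALSE]
  pd <- m$params$dec$e2i
  vproj <- (one %*% pd$Wv + pd$bv) %*% pd$Wo + pd$bo
  oracle <- manual_ln(carry + vproj, m$params$dec$ln_e2i$gamma,
                      m$params$dec$ln_e2i$beta)
  expect_equal(expr2img_attention(e1, carry, one, m), oracle,
               tolerance = 1e-6)
})

test_that("img2expr attention broadcasts the value stream with residual", {
  m <- tiny_model(seed = 56)
  img <- withr::with_seed(56, matrix(rnorm(4 * 8), 4, 8))
  e <- withr::with_seed(57, matrix(rnorm(8), 1, 8))
  # zero value stream with zero output bias: tokens unchanged pre-norm
  mz <- m
  mz$params$dec$i2e$Wv <- mz$params$dec$i2e$Wv * 0
  mz$params$dec$i2e$bv <- mz$params$dec$i2e$bv * 0
  mz$params$dec$i2e$bo <- mz$params$dec$i2e$bo * 0
  out <- img2expr_attention(img, e, matrix(0, 1, 8), mz)
  oracle <- manual_ln(img, m$params$dec$ln_i2e$gamma,
                      m$params$dec$ln_i2e$beta)
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("the decoder follows the documented wiring, traced module by module", {
  m <- tiny_model(seed = 58)
  pd <- m$params$dec
  img <- withr::with_seed(58, matrix(rnorm(16 * 8), 16, 8))
  e0 <- withr::with_seed(59, matrix(rnorm(8), 1, 8))
  got <- sc_informed_decode(img, e0, m, hooks = TRUE)
  hk <- attr(got, "hooks")

  mlp <- function(x, pp) {
    h <- x %*% pp$fc1$W + rep(pp$fc1$b, each = nrow(x))
    h <- h * pnorm(h)
    h %*% pp$fc2$W + rep(pp$fc2$b, each = nrow(x))
  }
  q_state <- e0
  img_state <- img
  mo <- NULL
  for (r in 1:2) {
    qin <- if (r == 1) e0 else mo
    q1 <- manual_ln(qin + manual_mha(qin, qin, qin, pd$self, 1),
                    pd$ln_self$gamma, pd$ln_self$beta)
    a <- manual_mha(e0 + q1, img_state, img_state, pd$e2i, 1)
    q2 <- manual_ln(q1 + a, pd$ln_e2i$gamma, pd$ln_e2i$beta)
    mo <- manual_ln(q2 + mlp(q2, pd$mlp1), pd$ln_mlp1$gamma, pd$ln_mlp1$beta)
    b <- manual_mha(img_state, e0 + mo, mo, pd$i2e, 1)
    img_state <- manual_ln(img_state + b, pd$ln_i2e$gamma, pd$ln_i2e$beta)
  }
  tterm <- manual_mha(e0 + mo, img_state, img_state, pd$term, 1)
  qf <- manual_ln(mo + tterm, pd$ln_term$gamma, pd$ln_term$beta)
  oracle <- manual_ln(qf + mlp(qf, pd$mlp2), pd$ln_mlp2$gamma,
                      pd$ln_mlp2$beta)
  expect_equal(unclass(got)[1, ], oracle[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)

  # round-1 query is the expression embedding itself
  expect_identical(hk$round_queries[[1]], e0)
  # attention rows sum to one at every recorded site
  expect_equal(max(abs(unlist(hk$attn_rowsums) - 1)), 0, tolerance = 1e-12)
})

test_that("with one decoder round the round-2 branch is never exercised", {
  m1 <- make_variant(small_model_config(n_genes = 7, d_att = 8, n_heads = 1,
                                        mlp_hidden = 8, decoder_rounds = 1,
                                        seed = 60))
  img <- withr::with_seed(60, matrix(rnorm(16 * 8), 16, 8))
  e0 <- withr::with_seed(61, matrix(rnorm(8), 1, 8))
  out <- sc_informed_decode(img, e0, m1, hooks = TRUE)
  hk <- attr(out, "hooks")
  expect_length(hk$round_queries, 1)
  expect_identical(hk$round_queries[[1]], e0)
})

test_that("prediction composes the exported stages plus the affine head", {
  m <- tiny_model(seed = 62)
  patch <- random_patches(1, seed = 62)[, , , 1]
  ie <- withr::with_seed(63, rnorm(7))
  pred <- predict(m, patch, ie)
  expect_identical(dim(pred), c(1L, 7L))
  # compositional oracle from the exported stage functions
  tok <- encode_image(patch, m)
  e0 <- encode_expr(ie, m)
  q <- sc_informed_decode(tok, e0, m)
  oracle <- q %*% m$params$head$W + rep(m$params$head$b, each = 1)
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-10)
  # determinism across calls
  expect_identical(pred, predict(m, patch, ie))
})

test_that("the training gradient reaches every submodule", {
  m <- tiny_model(seed = 64)
  patches <- random_patches(3, seed = 64)
  ie <- withr::with_seed(65, matrix(rnorm(3 * 7), 3, 7))
  y <- withr::with_seed(66, matrix(rnorm(3 * 7), 3, 7))
  fw <- scspot:::forward_scspot(m, patches, ie)
  bw <- scspot:::backward_scspot(2 * (fw$pred - y), fw$cache)
  for (part in c("expr_enc", "backbone", "csa", "ssa", "dec", "head")) {
    expect_gt(scspot:::tree_sum_sq(bw$grads[[part]]), 0, label = part)
  }
})

test_that("variants are constructed as specified and share weights", {
  expect_error(make_variant(small_model_config(7, variant = "bogus")),
               "random_ie")
  m_def <- tiny_model(seed = 67)
  m_rand <- tiny_model(variant = "random_ie", seed = 67)
  expect_identical(m_def$params, m_rand$params)
  m_deep <- tiny_model(variant = "deep3", seed = 67)
  expect_identical(m_deep$config$decoder_rounds, 3L)
  # random_ie: the noise for a given spot is stable across calls
  patches <- random_patches(4, seed = 67)
  ie <- matrix(0, 4, 7)
  expect_identical(predict(m_rand, patches, ie),
                   predict(m_rand, patches, ie))
  # and differs from the default model's prediction
  expect_false(isTRUE(all.equal(predict(m_rand, patches, ie),
                                predict(m_def, patches, ie))))
})

test_that("cellratio noise perturbs weights on the simplex", {
  refs <- make_ref_panel(n_genes = 5, seed = 68)
  cts <- tibble::tibble(neoplastic = c(4L, 0L), inflammatory = c(1L, 2L),
                        connective = c(0L, 1L), epithelial = c(1L, 0L))
  ie0 <- compose_ie_matrix(dplyr::mutate(cts, patch_id = c("a", "b")), refs)
  ie1 <- cellratio_noise_ie(cts, refs, level = 0.3, seed = 99)
  ie2 <- cellratio_noise_ie(cts, refs, level = 0.3, seed = 99)
  expect_identical(ie1, ie2)
  expect_false(isTRUE(all.equal(unname(ie0), unname(ie1))))
  # level 0 reproduces the unperturbed IE
  expect_equal(unname(cellratio_noise_ie(cts, refs, level = 0, seed = 99)),
               unname(ie0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("checkpoints round-trip weights, panel and reference fingerprint", {
  m <- tiny_model(seed = 70)
  panel <- scspot:::new_gene_panel(paste0("g", 1:7))
  refs <- make_ref_panel(n_genes = 7, seed = 70)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, panel, target_sum = 123, reference = refs)
  back <- load_checkpoint(path, reference_check = refs)
  expect_identical(back$params, m$params)
  expect_identical(as.character(attr(back, "panel")), as.character(panel))
  expect_identical(attr(back, "target_sum"), 123)
  patches <- random_patches(2, seed = 70)
  ie <- withr::with_seed(70, matrix(rnorm(14), 2, 7))
  expect_identical(predict(back, patches, ie), predict(m, patches, ie))
  refs2 <- make_ref_panel(n_genes = 7, seed = 71)
  expect_error(load_checkpoint(path, reference_check = refs2), "reference")
})
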