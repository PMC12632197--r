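# Shared fixture builders. Everything is generated in code at test time;
# heavier objects are memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# a small synthetic study shared by non-acceptance tests
tiny_study <- function() {
  memo_fixture("tiny_study", function() {
    generate_study(sim_config(n_genes = 24, n_sections = 2,
                              spots_per_section = 48, patch_size = 64,
                              seed = 404))
  })
}

# toy section with deterministic counts
make_section <- function(section_id = "s1", patient_id = "p1", n_spots = 6,
                         genes = c("gA", "gB", "gC"), n_background = 0,
                         seed = 1) {
  withr::with_seed(seed, {
    spots <- tibble::tibble(
      spot_id = sprintf("%s_%02d", section_id, seq_len(n_spots)),
      x = 200L + seq_len(n_spots) * 10L,
      y = 300L + seq_len(n_spots) * 10L,
      background = rep(c(FALSE, TRUE),
                       c(n_spots - n_background, n_background)))
    counts <- matrix(rpois(n_spots * length(genes), 20),
                     n_spots, length(genes))
    section_data(section_id, patient_id, spots, counts, genes)
  })
}

# labelled single-cell reference with planted subtype sizes
make_scr <- function(n_per_type = 20, genes = paste0("g", 1:8), seed = 2,
                     types = c("neoplastic", "inflammatory"),
                     with_dead = FALSE) {
  withr::with_seed(seed, {
    rows <- list(); metas <- list()
    for (t in seq_along(types)) {
      n_a <- ceiling(0.7 * n_per_type)
      counts <- matrix(rpois(n_per_type * length(genes), lambda = 5 * t),
                       n_per_type, length(genes))
      rows[[t]] <- counts
      metas[[t]] <- tibble::tibble(
        cell_id = sprintf("%s_%03d", types[t], seq_len(n_per_type)),
        major_type = types[t],
        minor_type = rep(paste0(types[t], c("_big", "_small")),
                         c(n_a, n_per_type - n_a)))
    }
    if (with_dead) {
      rows[[length(rows) + 1]] <- matrix(rpois(5 * length(genes), 1), 5)
      metas[[length(metas) + 1]] <- tibble::tibble(
        cell_id = sprintf("dead_%03d", 1:5),
        major_type = "dead", minor_type = "debris")
    }
    scr_dataset(do.call(rbind, rows), genes, dplyr::bind_rows(metas))
  })
}

# a random reference panel object (for IE tests that need no real scr)
make_ref_panel <- function(n_genes = 10, types = nondead_classes(),
                           seed = 3) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    vectors <- matrix(runif(n_genes * length(types), 0, 4), n_genes,
                      length(types), dimnames = list(genes, types))
    structure(list(panel = scspot:::new_gene_panel(genes),
                   vectors = vectors, target_sum = 100,
                   provenance = NULL),
              class = "reference_panel")
  })
}

# tiny model configuration used across model tests
tiny_model <- function(variant = "default", seed = 11, ...) {
  make_variant(small_model_config(n_genes = 7, d_att = 8, n_heads = 1,
                                  mlp_hidden = 8, variant = variant,
                                  seed = seed, ...))
}

random_patches <- function(n, size = 64, seed = 9) {
  withr::with_seed(seed, array(runif(size * size * 3 * n),
                               c(size, size, 3, n)))
}

# --- independent numerical oracles (used across test files) -----------

manual_ln <- function(x, gamma, beta, eps = 1e-5) {
  t(apply(x, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)
  })) * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
}

# independent scaled-dot-product multi-head attention trace
manual_mha <- function(q_in, k_in, v_in, p, H) {
  d <- ncol(q_in)
  dh <- d / H
  Q <- q_in %*% p$Wq + rep(p$bq, each = nrow(q_in))
  K <- k_in %*% p$Wk + rep(p$bk, each = nrow(k_in))
  V <- v_in %*% p$Wv + rep(p$bv, each = nrow(v_in))
  ctx <- matrix(0, nrow(q_in), d)
  for (h in seq_len(H)) {
    ch <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, ch, drop = FALSE] %*% t(K[, ch, drop = FALSE]) / sqrt(dh)
    A <- S
    for (i in seq_len(nrow(S))) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, ] <- e / sum(e)
    }
    ctx[, ch] <- A %*% V[, ch, drop = FALSE]
  }
  ctx %*% p$Wo + rep(p$bo, each = nrow(q_in))
}

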