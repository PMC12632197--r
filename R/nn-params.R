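# Parameter trees: nested named lists with numeric array leaves, plus the
# Adam optimizer that walks them. All randomness is drawn from the caller's
# RNG state so model construction is reproducible from a single seed.

is_leaf <- function(x) is.numeric(x)

# apply f to every leaf of a tree (preserving structure)
tree_map <- function(tree, f) {
  if (is_leaf(tree)) return(f(tree))
  lapply(tree, tree_map, f = f)
}

# apply f to matching leaves of two trees with identical structure;
# named children of b are aligned to a's names
tree_map2 <- function(a, b, f) {
  if (is_leaf(a)) return(f(a, b))
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

tree_zeros_like <- function(tree) tree_map(tree, function(x) x * 0)

# add tree b into a (gradient accumulation)
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(a, b, `+`)
}

tree_sum_sq <- function(tree) {
  s <- 0
  walk_fn <- function(x) s <<- s + sum(x^2)
  invisible(tree_map(tree, walk_fn))
  s
}

# Kaiming-normal weight matrix (fan_in rows)
init_weight <- function(fan_in, fan_out, gain = sqrt(2)) {
  matrix(rnorm(fan_in * fan_out, sd = gain / sqrt(fan_in)), fan_in, fan_out)
}

init_linear <- function(d_in, d_out, gain = 1) {
  list(W = init_weight(d_in, d_out, gain = gain), b = numeric(d_out))
}

init_mha <- function(d_model) {
  list(
    Wq = init_weight(d_model, d_model, gain = 1), bq = numeric(d_model),
    Wk = init_weight(d_model, d_model, gain = 1), bk = numeric(d_model),
    Wv = init_weight(d_model, d_model, gain = 1), bv = numeric(d_model),
    Wo = init_weight(d_model, d_model, gain = 1), bo = numeric(d_model)
  )
}

init_layernorm <- function(d) list(gamma = rep(1, d), beta = numeric(d))

init_mlp <- function(d_in, d_hidden, d_out) {
  list(fc1 = init_linear(d_in, d_hidden, gain = sqrt(2)),
       fc2 = init_linear(d_hidden, d_out, gain = 1))
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_zeros_like(params), v = tree_zeros_like(params))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  walk <- function(p, g, m, v) {
    if (is_leaf(p)) {
      return(cpp_adam_leaf(p, g, m, v, state$lr, state$beta1, state$beta2,
                           state$eps, bc1, bc2))
    }
    if (!is.null(names(p))) {
      g <- g[names(p)]; m <- m[names(p)]; v <- v[names(p)]
    }
    out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
    list(param = lapply(out, `[[`, "param"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(state = state, params = r$param)
}
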