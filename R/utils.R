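# Shared vocabulary and small helpers.

#' The five coarse nucleus classes used throughout the pipeline
#'
#' The nucleus segmenter's coarse typing scheme distinguishes neoplastic,
#' inflammatory, connective, non-neoplastic epithelial and dead nuclei.
#' `dead` is excluded from every reference and mixture computation.
#'
#' @return Character vector of the five class labels.
#' @export
pannuke_classes <- function() {
  c("neoplastic", "inflammatory", "connective", "epithelial", "dead")
}

#' @rdname pannuke_classes
#' @export
nondead_classes <- function() {
  setdiff(pannuke_classes(), "dead")
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

# derive a child seed from a base seed and a stream index, kept within
# 32-bit integer range
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483587L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# library-size scale one non-negative row to `target` then natural log1p;
# all-zero rows stay all-zero
scale_log1p <- function(x, target) {
  s <- sum(x)
  if (s == 0) return(x * 0)
  log1p(x / s * target)
}
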