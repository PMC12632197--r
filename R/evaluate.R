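# Evaluation statistics: per-gene Pearson correlation within a section,
# paired model comparisons, the positive-correlation gene test with BH
# adjustment, the dispersion summary, aggregation maps, and the two
# robustness noise injections.

#' Per-gene Pearson correlation between prediction and truth
#'
#' Correlations are computed per gene across the spots of one section.
#' Genes with zero variance in either argument are flagged undefined
#' (`NA`) and excluded from the mean/median rather than silently scored 0.
#'
#' @param pred,truth Matrices `(n_spots x n_genes)` with matching shapes
#'   (and column names, if present).
#' @return A `pcc_result` list: `per_gene` tibble (`gene`, `pcc`,
#'   `defined`), `mean_pcc`, `median_pcc`, `n_undefined`, `n_spots`.
#' @export
per_sample_pcc <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stopf("pred is %dx%d but truth is %dx%d", nrow(pred), ncol(pred),
          nrow(truth), ncol(truth))
  }
  if (nrow(pred) < 3) stopf("need at least 3 spots")
  genes <- colnames(pred) %||% paste0("g", seq_len(ncol(pred)))
  sd_p <- apply(pred, 2, stats::sd)
  sd_t <- apply(truth, 2, stats::sd)
  defined <- sd_p > 0 & sd_t > 0
  pcc <- rep(NA_real_, ncol(pred))
  if (any(defined)) {
    pcc[defined] <- vapply(which(defined), function(j) {
      stats::cor(pred[, j], truth[, j])
    }, numeric(1))
  }
  structure(list(
    per_gene = tibble(gene = genes, pcc = pcc, defined = defined),
    mean_pcc = mean(pcc[defined]),
    median_pcc = stats::median(pcc[defined]),
    n_undefined = sum(!defined),
    n_spots = nrow(pred)
  ), class = "pcc_result")
}

#' @export
print.pcc_result <- function(x, ...) {
  cat(sprintf("<pcc_result> %d genes (%d undefined), mean PCC %.3f, median %.3f\n",
              nrow(x$per_gene), x$n_undefined, x$mean_pcc, x$median_pcc))
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Compares paired per-section metric values (e.g. mean PCC per held-out
#' section) with the signed-rank test: exact null when no ties or zero
#' differences are present and `n <= 25`, normal approximation otherwise.
#' Zero differences are dropped (reported in the result); if every
#' difference is zero the p-value is undefined and flagged.
#'
#' For `n <= 12` non-zero differences the null distribution of the
#' signed-rank statistic is enumerated over all `2^n` sign patterns
#' (average ranks for tied magnitudes), which stays exact in the presence
#' of ties; larger `n` uses the standard normal approximation.
#'
#' @param metric_a,metric_b Equal-length paired metric vectors (>= 5
#'   pairs).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `p_value`, `statistic` (V, the sum of positive
#'   ranks), `n_nonzero`, `undefined`.
#' @export
compare_models_wilcoxon <- function(metric_a, metric_b,
                                    alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 5)
  d <- metric_a - metric_b
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_nonzero = 0L,
                undefined = TRUE))
  }
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p_ge <- mean(Vs >= V)
    p_le <- mean(Vs <= V)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge, less = p_le)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(nz, alternative = alternative, exact = FALSE))
    p <- unname(wt$p.value)
  }
  list(p_value = p, statistic = V, n_nonzero = n, undefined = FALSE)
}

#' Which genes are predicted with significant positive correlation?
#'
#' One-sided test of `rho > 0` per gene via
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' followed by Benjamini-Hochberg adjustment across genes. Genes are
#' returned ranked by adjusted p-value (the "top accurately predicted
#' genes" ordering).
#'
#' @param pcc Named (or plain) vector of per-gene correlations; `NA`
#'   entries (undefined genes) are carried through untested.
#' @param n_spots Number of spots the correlations were computed over
#'   (>= 4).
#' @return Tibble `gene`, `pcc`, `p`, `p_adj`, sorted by `p_adj`, then
#'   `p`, then gene name.
#' @export
gene_positive_correlation_test <- function(pcc, n_spots) {
  stopifnot(n_spots >= 4)
  genes <- names(pcc) %||% paste0("g", seq_along(pcc))
  r <- pmin(pmax(unname(pcc), -1), 1)
  tt <- r * sqrt((n_spots - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- stats::pt(tt, df = n_spots - 2, lower.tail = FALSE)
  p[!is.na(r) & r == 1] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble(gene = genes, pcc = unname(pcc), p = p, p_adj = p_adj) |>
    arrange(.data$p_adj, .data$p, .data$gene)
}

#' Dispersion of the best-predicted genes above the section median
#'
#' Summarizes how far a section's top-decile genes (by PCC) sit above the
#' section's median PCC: the mean of `pcc - median(pcc)` over the top
#' `ceiling(n / 10)` defined genes. Non-negative by construction.
#'
#' @param pcc Vector of per-gene correlations for one section; `NA`
#'   entries are dropped. At least 10 defined values are required
#'   (otherwise `NA` with a warning).
#' @return Scalar dispersion score.
#' @export
dispersion_score <- function(pcc) {
  pcc <- pcc[!is.na(pcc)]
  if (length(pcc) < 10) {
    warnf("fewer than 10 defined PCCs; dispersion undefined")
    return(NA_real_)
  }
  k <- ceiling(length(pcc) / 10)
  top <- sort(pcc, decreasing = TRUE)[seq_len(k)]
  mean(top - stats::median(pcc))
}

#' Per-spot mean expression over a gene set
#'
#' @param pred Matrix `(n_spots x n_genes)` with gene column names.
#' @param gene_set Genes to average (must intersect the columns).
#' @return Tibble `spot_id`, `score`.
#' @export
geneset_spatial_map <- function(pred, gene_set) {
  hit <- intersect(gene_set, colnames(pred))
  if (length(hit) == 0) stopf("gene set does not intersect the panel")
  tibble(spot_id = rownames(pred) %||% as.character(seq_len(nrow(pred))),
         score = unname(rowMeans(pred[, hit, drop = FALSE])))
}

#' Pseudo-bulk profile of a slide
#'
#' Column mean over all spots/patches, for comparison against bulk
#' RNA-seq.
#'
#' @param pred Matrix `(n_spots x n_genes)`.
#' @return Named numeric vector of length `n_genes`.
#' @export
pseudo_bulk <- function(pred) {
  stopifnot(nrow(pred) >= 1)
  colMeans(pred)
}

#' Inject spot or stain noise into a dataset
#'
#' Robustness perturbations applied to an evaluation/training dataset:
#' * `kind = "spot"` — for a seeded selection of `round(level * n)`
#'   spots, the patch view is displaced by a random integer offset of up
#'   to `radius` pixels per axis (reflect-padded), emulating spot-center
#'   jitter on pre-cut patches.
#' * `kind = "stain"` — for `round(level * n)` patches, a seeded
#'   hue/saturation/value perturbation of magnitude `magnitude`.
#'
#' Labels and IE are never touched; `level = 0` returns the dataset
#' bit-for-bit unchanged.
#'
#' @param dataset A `spot_dataset` (see [as_spot_dataset()]).
#' @param kind `"spot"` or `"stain"`.
#' @param level Fraction of spots perturbed, in `[0, 1]`.
#' @param seed Seed for the selection and the perturbation draws.
#' @param radius Maximum displacement in pixels (spot noise); defaults to
#'   half the patch side (one spot radius).
#' @param magnitude Maximum relative HSV shift (stain noise).
#' @return The perturbed dataset; perturbed spot indices in attribute
#'   `"perturbed"`.
#' @export
inject_noise <- function(dataset, kind = c("spot", "stain"), level,
                         seed = 1L, radius = NULL, magnitude = 0.1) {
  kind <- match.arg(kind)
  if (level < 0 || level > 1) stopf("level must be in [0, 1]")
  if (level == 0) {
    attr(dataset, "perturbed") <- integer(0)
    return(dataset)
  }
  n <- dim(dataset$patches)[4]
  sz <- dim(dataset$patches)[1]
  radius <- radius %||% (sz %/% 2L)
  n_pick <- round(level * n)
  with_seed(child_seed(seed, 5L), {
    picked <- sort(sample(n, n_pick))
    for (i in picked) {
      if (kind == "spot") {
        repeat {
          off <- sample(seq(-radius, radius), 2, replace = TRUE)
          if (any(off != 0)) break
        }
        dataset$patches[, , , i] <-
          shift_patch(dataset$patches[, , , i], off[1], off[2])
      } else {
        dataset$patches[, , , i] <-
          perturb_hsv(dataset$patches[, , , i],
                      runif(3, -magnitude, magnitude))
      }
    }
  })
  attr(dataset, "perturbed") <- picked
  dataset
}

# integer translation with reflection padding
shift_patch <- function(img, dy, dx) {
  d <- dim(img)
  rows <- reflect_index(seq_len(d[1]) + dy, d[1])
  cols <- reflect_index(seq_len(d[2]) + dx, d[2])
  img[rows, cols, , drop = FALSE]
}

# additive shift in HSV space, clamped back to [0, 1] RGB
perturb_hsv <- function(img, shift) {
  d <- dim(img)
  rgb <- matrix(aperm(img, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + shift[1]) %% 1
  hsv[2, ] <- pmin(pmax(hsv[2, ] + shift[2], 0), 1)
  hsv[3, ] <- pmin(pmax(hsv[3, ] + shift[3], 0), 1)
  out <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
  aperm(array(out, c(3, d[1], d[2])), c(2, 3, 1))
}
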