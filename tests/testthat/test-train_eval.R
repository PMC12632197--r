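# Training behaviour, cross-validation folds, and the evaluation
# statistics with their independent oracles.

make_train_ds <- function(n = 16, g = 7, seed = 71, sections = 1) {
  withr::with_seed(seed, {
    patches <- array(runif(64 * 64 * 3 * n), c(64, 64, 3, n))
    ie <- matrix(rnorm(n * g), n, g)
    labels <- ie + matrix(rnorm(n * g, sd = 0.1), n, g)
    meta <- tibble::tibble(
      spot_id = paste0("s", seq_len(n)),
      section_id = paste0("sec", rep_len(seq_len(sections), n)),
      patient_id = "p1")
    as_spot_dataset(patches, ie, labels, meta,
                    scspot:::new_gene_panel(paste0("g", seq_len(g))))
  })
}

test_that("leave-one-section-out folds enumerate each section once", {
  f3 <- loso_folds(c("a", "b", "c"))
  expect_length(f3, 3)
  for (f in f3) {
    expect_setequal(c(f$train, f$test), c("a", "b", "c"))
    expect_length(f$test, 1)
  }
  expect_identical(vapply(f3, `[[`, "", "test"), c("a", "b", "c"))
  # n = 5 equals a brute-force enumeration; each section appears in
  # exactly n - 1 training sets
  ids <- paste0("s", 1:5)
  f5 <- loso_folds(ids)
  expect_identical(lapply(f5, `[[`, "test"), as.list(ids))
  trains <- unlist(lapply(f5, `[[`, "train"))
  expect_true(all(table(trains) == 4))
  expect_error(loso_folds("only_one"), ">= 2")
})

test_that("one epoch of training on one batch decreases the loss", {
  ds <- make_train_ds(n = 8)
  m <- tiny_model(seed = 72)
  fit <- train_scspot(m, ds, train_config(batch_size = 8, epochs = 2,
                                          learning_rate = 1e-3, seed = 72))
  expect_lt(fit$history$loss[2], fit$history$loss[1])
})

test_that("training is deterministic given the seeds", {
  ds <- make_train_ds(n = 12)
  cfg <- train_config(batch_size = 4, epochs = 3, learning_rate = 1e-3,
                      seed = 73)
  f1 <- train_scspot(tiny_model(seed = 73), ds, cfg)
  f2 <- train_scspot(tiny_model(seed = 73), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a linear-in-IE dataset is fit below the label-noise floor", {
  sigma <- 0.25
  withr::with_seed(74, {
    n <- 24; g <- 5
    patches <- array(runif(64 * 64 * 3 * n), c(64, 64, 3, n))
    ie <- matrix(rnorm(n * g), n, g)
    labels <- ie + matrix(rnorm(n * g, sd = sigma), n, g)
    meta <- tibble::tibble(spot_id = paste0("s", 1:n), section_id = "sec1",
                           patient_id = "p1")
    ds <- as_spot_dataset(patches, ie, labels, meta,
                          scspot:::new_gene_panel(paste0("g", 1:g)))
  })
  fit <- train_scspot(make_variant(small_model_config(5, seed = 74)), ds,
                      desk_train_config(epochs = 60, seed = 74))
  expect_lt(fit$history$loss[60], sigma^2)
})

test_that("per-gene PCC matches the covariance formula", {
  withr::with_seed(75, {
    pred <- matrix(rnorm(50 * 20), 50, 20)
    truth <- matrix(rnorm(50 * 20), 50, 20)
  })
  res <- per_sample_pcc(pred, truth)
  for (j in 1:20) {
    x <- pred[, j]; y <- truth[, j]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$per_gene$pcc[j], oracle, tolerance = 1e-12)
  }
  expect_equal(res$mean_pcc, mean(res$per_gene$pcc))
  # perfect and anti-perfect predictions
  expect_equal(per_sample_pcc(truth, truth)$per_gene$pcc, rep(1, 20),
               tolerance = 1e-12)
  expect_equal(per_sample_pcc(-truth, truth)$per_gene$pcc, rep(-1, 20),
               tolerance = 1e-12)
  expect_error(per_sample_pcc(pred, truth[, 1:3]), "truth")
})

test_that("PCC is invariant to positive affine transforms and flags zero variance", {
  withr::with_seed(76, {
    pred <- matrix(rnorm(30 * 5), 30, 5)
    truth <- matrix(rnorm(30 * 5), 30, 5)
  })
  r0 <- per_sample_pcc(pred, truth)
  r1 <- per_sample_pcc(pred * 3.7 + 2, truth)
  r2 <- per_sample_pcc(pred, truth * 0.1 - 5)
  expect_equal(r0$per_gene$pcc, r1$per_gene$pcc, tolerance = 1e-12)
  expect_equal(r0$per_gene$pcc, r2$per_gene$pcc, tolerance = 1e-12)
  # a constant prediction column is undefined, not zero
  pred[, 2] <- 1
  rz <- per_sample_pcc(pred, truth)
  expect_true(is.na(rz$per_gene$pcc[2]))
  expect_identical(rz$n_undefined, 1L)
  expect_equal(rz$mean_pcc, mean(rz$per_gene$pcc[-2]))
})

test_that("signed-rank p-values match exact enumeration for n <= 12", {
  # independent oracle: loop over all sign patterns via bit masks
  exact_oracle <- function(d, alternative) {
    nz <- d[d != 0]
    n <- length(nz)
    r <- rank(abs(nz))
    V <- sum(r[nz > 0])
    Vs <- numeric(2^n)
    for (mask in 0:(2^n - 1)) {
      v <- 0
      for (j in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, j - 1L))) {
        v <- v + r[j]
      }
      Vs[mask + 1] <- v
    }
    switch(alternative,
           greater = mean(Vs >= V),
           less = mean(Vs <= V),
           two.sided = min(1, 2 * min(mean(Vs >= V), mean(Vs <= V))))
  }
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(5:12, 1)
      a <- rnorm(n); b <- rnorm(n)
      for (alt in c("two.sided", "greater", "less")) {
        got <- compare_models_wilcoxon(a, b, alternative = alt)
        expect_equal(got$p_value, exact_oracle(a - b, alt),
                     tolerance = 1e-12)
      }
      # cross-check against the standard exact implementation (tie-free)
      ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(compare_models_wilcoxon(a, b)$p_value, ref$p.value,
                   tolerance = 1e-12)
    }
  })
  # constant positive shift attains the minimal two-sided p for n = 10
  a <- 1:10 / 10
  expect_equal(compare_models_wilcoxon(a + 0.5, a)$p_value, 2 / 2^10)
  # identical vectors: undefined-result policy
  same <- compare_models_wilcoxon(a, a)
  expect_true(same$undefined)
  expect_equal(same$p_value, 1)
})

test_that("the positive-correlation gene test matches the t-tail and BH order", {
  # r = 0: one-sided p is exactly one half
  out0 <- gene_positive_correlation_test(c(gA = 0), n_spots = 20)
  expect_equal(out0$p, 0.5)
  # r = 1: p at the numerical floor
  expect_equal(gene_positive_correlation_test(c(g = 1), 20)$p, 0)
  # r = 0.5, n = 27: matches the t tail computed by numerical integration
  r <- 0.5; n <- 27
  tt <- r * sqrt((n - 2) / (1 - r^2))
  dens <- function(x) {
    gamma((n - 1) / 2) / (sqrt((n - 2) * pi) * gamma((n - 2) / 2)) *
      (1 + x^2 / (n - 2))^(-(n - 1) / 2)
  }
  quad <- integrate(dens, tt, Inf, rel.tol = 1e-10)$value
  expect_equal(gene_positive_correlation_test(c(g = r), n)$p, quad,
               tolerance = 1e-8)
  # BH adjustment preserves the raw p ordering and matches the manual
  # step-up formula
  withr::with_seed(78, {
    pcc <- setNames(runif(40, -0.5, 0.9), paste0("g", 1:40))
    out <- gene_positive_correlation_test(pcc, 30)
    expect_identical(order(out$p_adj, out$p), order(out$p, out$p))
    m <- length(out$p)
    manual <- rev(cummin(rev(out$p[order(out$p)] * m / seq_len(m))))
    manual <- pmin(manual, 1)
    expect_equal(sort(out$p_adj), sort(manual), tolerance = 1e-12)
  })
})

test_that("the dispersion score summarizes top-decile excess over the median", {
  expect_equal(dispersion_score(rep(0.3, 50)), 0)
  # one outlier at 1 among 100 genes at 0: top decile is 10 genes
  pcc <- c(1, rep(0, 99))
  expect_equal(dispersion_score(pcc), mean(c(1, rep(0, 9))) - 0)
  # enumeration oracle on a random vector, plus permutation invariance
  withr::with_seed(79, {
    v <- runif(37)
    k <- ceiling(37 / 10)
    oracle <- mean(sort(v, decreasing = TRUE)[1:k] - median(v))
    expect_equal(dispersion_score(v), oracle, tolerance = 1e-12)
    expect_equal(dispersion_score(sample(v)), dispersion_score(v))
  })
  expect_gte(dispersion_score(rnorm(100)), 0)
  expect_warning(out <- dispersion_score(rep(0.2, 5)), "fewer than 10")
  expect_true(is.na(out))
})

test_that("gene-set maps and pseudo-bulk are masked means", {
  withr::with_seed(80, {
    pred <- matrix(rnorm(12 * 6), 12, 6,
                   dimnames = list(paste0("s", 1:12), paste0("g", 1:6)))
  })
  one <- geneset_spatial_map(pred, "g3")
  expect_equal(one$score, unname(pred[, "g3"]))
  full <- geneset_spatial_map(pred, paste0("g", 1:6))
  expect_equal(full$score, unname(rowMeans(pred)))
  set <- c("g1", "g4", "g5")
  expect_equal(geneset_spatial_map(pred, set)$score,
               unname(rowMeans(pred[, set])))
  expect_error(geneset_spatial_map(pred, "absent"), "intersect")

  expect_equal(pseudo_bulk(pred), colMeans(pred))
  expect_equal(pseudo_bulk(pred[1, , drop = FALSE]), pred[1, ])
  expect_equal(pseudo_bulk(pred[rep(1:12, 2), ]), pseudo_bulk(pred))
})

test_that("noise injection perturbs exactly the requested fraction", {
  ds <- make_train_ds(n = 25, seed = 81)
  # level zero is a bit-exact no-op
  ds0 <- inject_noise(ds, "spot", level = 0, seed = 5)
  expect_identical(ds0$patches, ds$patches)
  ds0s <- inject_noise(ds, "stain", level = 0, seed = 5)
  expect_identical(ds0s$patches, ds$patches)
  # level 1 spot noise: every patch view is displaced
  ds1 <- inject_noise(ds, "spot", level = 1, seed = 5)
  expect_length(attr(ds1, "perturbed"), 25)
  changed <- vapply(1:25, function(i) {
    !identical(ds1$patches[, , , i], ds$patches[, , , i])
  }, logical(1))
  expect_true(all(changed))
  # labels and IE are untouched
  expect_identical(ds1$labels, ds$labels)
  expect_identical(ds1$ie, ds$ie)
  # fractional level: seeded selection of exactly round(level * n) spots
  ds2 <- inject_noise(ds, "spot", level = 0.2, seed = 6)
  expect_length(attr(ds2, "perturbed"), round(0.2 * 25))
  untouched <- setdiff(1:25, attr(ds2, "perturbed"))
  for (i in untouched) {
    expect_identical(ds2$patches[, , , i], ds$patches[, , , i])
  }
  # stain noise keeps values in range and is seeded-reproducible
  st1 <- inject_noise(ds, "stain", level = 0.4, seed = 7)
  st2 <- inject_noise(ds, "stain", level = 0.4, seed = 7)
  expect_identical(st1$patches, st2$patches)
  expect_true(all(st1$patches >= 0 & st1$patches <= 1))
  expect_error(inject_noise(ds, "spot", level = 1.2), "level")
})

test_that("tidiers expose evaluation results as tibbles", {
  withr::with_seed(82, {
    truth <- matrix(rnorm(30 * 8), 30, 8)
    pred <- truth + matrix(rnorm(30 * 8, sd = 0.5), 30, 8)
  })
  res <- per_sample_pcc(pred, truth)
  expect_s3_class(tidy(res), "tbl_df")
  expect_identical(nrow(glance(res)), 1L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
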