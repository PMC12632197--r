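# Patch extraction, gene-panel selection, label normalization and the
# section filter.

test_that("extract_patch follows the half-open window convention", {
  img <- array(seq(0, 1, length.out = 224 * 224 * 3), c(224, 224, 3))
  # center (112, 112) on a 224x224 image returns the whole image
  p <- extract_patch(img, list(spot_id = "a", x = 112, y = 112))
  expect_identical(p, img)

  # center (500, 300): columns [388, 612), rows [188, 412) — checked
  # against an independent index enumeration
  big <- withr::with_seed(1, array(runif(700 * 700 * 3), c(700, 700, 3)))
  p <- extract_patch(big, list(spot_id = "b", x = 500, y = 300))
  expect_identical(dim(p), c(224L, 224L, 3L))
  rows <- vapply(0:223, function(i) 188 + i + 1, numeric(1))
  cols <- vapply(0:223, function(j) 388 + j + 1, numeric(1))
  expect_identical(p, big[rows, cols, ])
})

test_that("windows that overhang the image are reflect-padded with a warning", {
  big <- withr::with_seed(2, array(runif(400 * 400 * 3), c(400, 400, 3)))
  expect_warning(p <- extract_patch(big, list(spot_id = "edge", x = 50, y = 50)),
                 "reflect")
  expect_identical(dim(p), c(224L, 224L, 3L))
  # interior part of the window is untouched
  expect_identical(p[63:224, 63:224, ], big[1:162, 1:162, ])
})

test_that("a center outside the image errors naming the spot", {
  img <- array(0, c(100, 100, 3))
  expect_error(extract_patch(img, list(spot_id = "spotX", x = 150, y = 10)),
               "spotX")
})

test_that("patch extraction is translation-consistent for interior spots", {
  base <- withr::with_seed(3, array(runif(500 * 500 * 3), c(500, 500, 3)))
  dx <- 7L; dy <- 13L
  shifted <- base[(1 + dy):(400 + dy), (1 + dx):(400 + dx), ]
  p1 <- extract_patch(shifted, list(spot_id = "t", x = 180, y = 170))
  p2 <- extract_patch(base, list(spot_id = "t", x = 180 + dx, y = 170 + dy))
  expect_identical(p1, p2)
})

test_that("gene panel selection ranks by pooled variance and respects the reference", {
  # planted variance structure: two high-variance genes, one flat, one
  # high-variance gene absent from the reference
  genes <- c("flat", "hi1", "hi2", "noref")
  secs <- lapply(1:4, function(s) {
    withr::with_seed(100 + s, {
      n <- 30
      counts <- cbind(flat = rep(50L, n),
                      hi1 = rpois(n, 5) * rbinom(n, 1, 0.5) * 20L,
                      hi2 = rpois(n, 5) * rbinom(n, 1, 0.5) * 15L,
                      noref = rpois(n, 5) * rbinom(n, 1, 0.5) * 30L)
      spots <- tibble::tibble(spot_id = sprintf("s%d_%02d", s, 1:n),
                              x = 1:n * 10L, y = 1:n * 10L,
                              background = FALSE)
      section_data(paste0("sec", s), "p1", spots, counts, genes)
    })
  })
  panel <- select_gene_panel(secs, scr_genes = c("flat", "hi1", "hi2"),
                             top_k = 2)
  expect_setequal(as.character(panel), c("hi1", "hi2"))

  # brute-force variance oracle over the pooled normalized matrix
  pooled <- do.call(rbind, lapply(secs, function(s)
    s$counts[, c("flat", "hi1", "hi2")]))
  target <- median(rowSums(pooled))
  norm <- t(apply(pooled, 1, function(r) {
    if (sum(r) == 0) r * 0 else log1p(r / sum(r) * target)
  }))
  v <- apply(norm, 2, var)
  expect_identical(as.character(panel),
                   names(sort(v, decreasing = TRUE))[1:2])

  # zero-variance gene ranks last; requesting more than available warns
  expect_warning(p4 <- select_gene_panel(secs, c("flat", "hi1", "hi2"), 5),
                 "3 genes")
  expect_identical(as.character(p4)[3], "flat")
})

test_that("gene panel selection is invariant to gene-column permutation", {
  secs <- list(tiny_study()$sections[[1]])
  scr_genes <- tiny_study()$scr$gene_names
  p1 <- select_gene_panel(secs, scr_genes, top_k = 10)
  perm <- withr::with_seed(5, sample(length(secs[[1]]$gene_names)))
  s2 <- secs[[1]]
  s2$counts <- s2$counts[, perm]
  s2$gene_names <- s2$gene_names[perm]
  p2 <- select_gene_panel(list(s2), scr_genes, top_k = 10)
  expect_identical(as.character(p1), as.character(p2))
})

test_that("label normalization scales to the target and log1p-transforms", {
  panel <- scspot:::new_gene_panel(paste0("g", 1:10))
  # all-zero spot maps to all zeros
  zero <- setNames(rep(0L, 10), as.character(panel))
  expect_identical(unname(normalize_labels(zero, panel, 100)), rep(0, 10))
  # one expressed gene: single entry ln(1 + target)
  one <- setNames(c(7L, rep(0L, 9)), as.character(panel))
  out <- normalize_labels(one, panel, target_sum = 50)
  expect_equal(unname(out[1]), log1p(50))
  expect_identical(unname(out[-1]), rep(0, 9))
  # random row matches the two-line reference computation
  row <- withr::with_seed(6, setNames(rpois(10, 8), as.character(panel)))
  expect_equal(unname(normalize_labels(row, panel, 123)),
               log1p(as.numeric(row) / sum(row) * 123))
  # library-depth invariance: scaling the raw row changes nothing
  expect_equal(normalize_labels(row * 13L, panel, 123),
               normalize_labels(row, panel, 123))
  expect_error(normalize_labels(row - 5L, panel, 123), "egative")
})

test_that("sections with fewer than min_spots non-background spots are dropped", {
  s179 <- make_section("near", n_spots = 200, n_background = 21, seed = 7)
  s180 <- make_section("at", n_spots = 200, n_background = 20, seed = 8)
  kept <- filter_sections(list(s179, s180), min_spots = 180)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$section_id, "at")
  expect_identical(filter_sections(list(), 180), list())
  # order preserved
  s_all <- list(s180, s179, make_section("big", n_spots = 200, seed = 9))
  kept2 <- filter_sections(s_all, 180)
  expect_identical(vapply(kept2, `[[`, "", "section_id"), c("at", "big"))
})
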