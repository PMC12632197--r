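# Fully self-contained synthetic studies: a clustered single-cell
# reference with planted subtype structure, nucleus-rendered patches with
# known type counts, and spot expression built as IE + morphology signal
# + noise. The generator carries its own weighted-sum IE implementation
# so it can serve as an independent oracle for the pipeline's IE code.

#' Synthetic study configuration
#'
#' @param n_genes Genes in the panel.
#' @param n_types Non-dead cell types (<= 4).
#' @param cells_per_type Reference cells per type.
#' @param n_sections,spots_per_section Study layout.
#' @param morph_signal_strength Weight `alpha` of the morphology-linked
#'   signal added to the IE when forming labels.
#' @param noise_sd Per-gene Gaussian label noise `sigma`.
#' @param patch_size Rendered patch side in pixels (224 matches the
#'   full-scale pipeline; 64 matches the small backbone).
#' @param dead_cells If `TRUE`, the reference includes a dead-cell group
#'   (which must never influence results).
#' @param dispersion Negative-binomial size parameter for reference
#'   counts (overdispersed, as single-cell counts are).
#' @param marker_fold Expression fold-change of a type's marker block
#'   over baseline (centroid separation).
#' @param mean_cells Mean nuclei per patch (Poisson).
#' @param seed Master seed; every draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 60L, n_types = 4L, cells_per_type = 200L,
                       n_sections = 3L, spots_per_section = 200L,
                       morph_signal_strength = 0.5, noise_sd = 0.3,
                       patch_size = 224L, dead_cells = TRUE,
                       dispersion = 2, marker_fold = 8, mean_cells = 10,
                       seed = 1L) {
  stopifnot(n_genes >= n_types, n_types >= 1, n_types <= 4,
            cells_per_type >= 1, n_sections >= 1, spots_per_section >= 1,
            morph_signal_strength >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a clustered synthetic single-cell reference
#'
#' Each non-dead type gets a distinct mean profile (a marker gene block
#' elevated `marker_fold`-fold over baseline); cells are negative-binomial
#' draws around it. Each type is split into two planted minor subtypes
#' (60% / 40% of cells, the larger named `<type>_major_clone`) so the
#' subtype-selection criterion has a known answer.
#'
#' @param cfg A [sim_config()].
#' @return An [scr_dataset()].
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 1L), {
    genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
    types <- nondead_classes()[seq_len(cfg$n_types)]
    mu <- sim_type_means(cfg)
    rows <- list(); metas <- list()
    for (t in seq_along(types)) {
      n_a <- ceiling(0.6 * cfg$cells_per_type)
      n_b <- cfg$cells_per_type - n_a
      mu_b <- mu[t, ]
      shift <- seq_len(max(1, cfg$n_genes %/% 8))
      mu_b[shift] <- mu_b[shift] * 1.5
      draw <- function(m, n) {
        matrix(rnbinom(n * cfg$n_genes, mu = rep(m, each = n),
                       size = cfg$dispersion), n, cfg$n_genes)
      }
      rows[[t]] <- rbind(draw(mu[t, ], n_a), draw(mu_b, n_b))
      metas[[t]] <- tibble(
        cell_id = sprintf("%s_c%04d", types[t], seq_len(cfg$cells_per_type)),
        major_type = types[t],
        minor_type = rep(paste0(types[t], c("_major_clone", "_minor_clone")),
                         c(n_a, n_b)))
    }
    if (cfg$dead_cells) {
      n_d <- 50L
      rows[[length(rows) + 1]] <-
        matrix(rnbinom(n_d * cfg$n_genes, mu = rep(colMeans(mu) * 0.2,
                                                   each = n_d),
                       size = cfg$dispersion), n_d, cfg$n_genes)
      metas[[length(metas) + 1]] <- tibble(
        cell_id = sprintf("dead_c%04d", seq_len(n_d)),
        major_type = "dead", minor_type = "dead_debris")
    }
    scr_dataset(do.call(rbind, rows), genes, dplyr::bind_rows(metas))
  })
}

# raw-scale mean expression per type: every gene gets a type-specific
# log-normal mean (each cell type has a fully distinct profile, as real
# types do), with a marker block elevated marker_fold-fold on top so each
# type also has unambiguous markers
sim_type_means <- function(cfg) {
  mu <- matrix(exp(log(2) + rnorm(cfg$n_types * cfg$n_genes, sd = 0.8)),
               cfg$n_types, cfg$n_genes)
  block <- max(1L, cfg$n_genes %/% (cfg$n_types + 1L))
  for (t in seq_len(cfg$n_types)) {
    idx <- ((t - 1L) * block + 1L):(t * block)
    mu[t, idx] <- mu[t, idx] * cfg$marker_fold
  }
  mu
}

# nucleus colours for rendering (type -> RGB in [0,1])
sim_type_colors <- function() {
  rbind(neoplastic = c(0.35, 0.15, 0.45),
        inflammatory = c(0.10, 0.20, 0.70),
        connective = c(0.80, 0.30, 0.40),
        epithelial = c(0.90, 0.55, 0.15),
        dead = c(0.25, 0.20, 0.15))
}

SIM_BACKGROUND <- c(0.91, 0.78, 0.83)

#' Render a patch with a known number of nuclei per type
#'
#' Draws one ellipse per nucleus in a type-specific colour on an
#' eosin-pink background with light texture noise. Nuclei are placed on a
#' jittered grid with a guaranteed margin, so the number of connected
#' foreground components equals the requested count exactly.
#'
#' @param counts Named non-negative counts over (a subset of)
#'   [pannuke_classes()].
#' @param cfg A [sim_config()] (only `patch_size` is used).
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return List: `image` array `(patch_size, patch_size, 3)` in `[0, 1]`,
#'   and `counts` (the tally actually drawn).
#' @export
render_patch <- function(counts, cfg, seed = NULL) {
  run <- function() render_patch_impl(counts, cfg)
  if (is.null(seed)) run() else with_seed(seed, run())
}

render_patch_impl <- function(counts, cfg) {
  sz <- cfg$patch_size
  counts <- unlist(counts)
  stopifnot(all(counts >= 0), all(names(counts) %in% pannuke_classes()))
  total <- sum(counts)
  g <- max(2L, ceiling(sqrt(total)))
  box <- sz / g
  if (box < 6) stopf("too many cells (%d) for a %dpx patch", total, sz)
  img <- array(rnorm(sz * sz * 3, sd = 0.02), c(sz, sz, 3))
  img <- sweep(img, 3, SIM_BACKGROUND, `+`)
  cols <- sim_type_colors()
  cells <- rep(names(counts), counts)
  slots <- sample(g * g, total)
  xs <- matrix(seq_len(sz), sz, sz)          # column index per pixel
  ys <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
  for (i in seq_along(cells)) {
    sr <- (slots[i] - 1L) %% g
    sc <- (slots[i] - 1L) %/% g
    r_max <- box / 2 - 1.5
    rx <- runif(1, 0.45, 0.85) * r_max
    ry <- runif(1, 0.45, 0.85) * r_max
    cx <- sr * box + box / 2 + runif(1, -1, 1) * (r_max - rx)
    cy <- sc * box + box / 2 + runif(1, -1, 1) * (r_max - ry)
    mask <- ((ys - cx) / rx)^2 + ((xs - cy) / ry)^2 <= 1
    shade <- runif(1, 0.85, 1.1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- min(1, cols[cells[i], ch] * shade)
      img[, , ch] <- plane
    }
  }
  # snap to the 8-bit grid so PNG round trips are lossless
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  tally <- stats::setNames(integer(length(pannuke_classes())),
                           pannuke_classes())
  tb <- table(cells)
  tally[names(tb)] <- as.integer(tb)
  list(image = img, counts = tally)
}

#' Generate a complete synthetic study
#'
#' Per spot: type counts are drawn from a section-specific Dirichlet
#' composition prior (total nuclei Poisson with mean `mean_cells`); the
#' true label is `IE(counts, reference) + alpha * m(counts) + eps`, where
#' the morphology signal `m` maps the raw per-type count vector through a
#' fixed random linear map (so the image carries total-cellularity
#' information the proportion-based IE does not) and
#' `eps ~ N(0, noise_sd^2)` per gene. The IE is computed here by an
#' independent double loop, not by [compose_initial_expression()].
#'
#' @param cfg A [sim_config()].
#' @return A `sim_study` list: `dataset` (a [as_spot_dataset()] with
#'   patches, IE, labels, metadata, cell counts and the reference),
#'   `scr`, `refs`, `sections` (list of [section_data()] with raw
#'   negative-binomial counts for the preprocessing round trip),
#'   `morph_map`, `morph`, and `cfg`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  scr <- generate_reference(cfg)
  panel <- new_gene_panel(scr$gene_names)
  target <- stats::median(rowSums(scr$counts))
  refs <- build_reference_panel(scr, panel, target)
  types <- colnames(refs$vectors)
  G <- cfg$n_genes

  with_seed(child_seed(cfg$seed, 2L), {
    morph_map <- matrix(rnorm(cfg$n_types * G), cfg$n_types, G) /
      sqrt(cfg$n_types)
    n_total <- cfg$n_sections * cfg$spots_per_section
    patches <- array(0, c(cfg$patch_size, cfg$patch_size, 3, n_total))
    ie <- matrix(0, n_total, G, dimnames = list(NULL, as.character(panel)))
    morph <- matrix(0, n_total, G)
    count_rows <- list()
    meta_rows <- list()
    k <- 0L
    for (s in seq_len(cfg$n_sections)) {
      sec_id <- sprintf("section%02d", s)
      comp <- rgamma(cfg$n_types, shape = 2)
      comp <- comp / sum(comp)
      for (i in seq_len(cfg$spots_per_section)) {
        k <- k + 1L
        n_cells <- max(1L, rpois(1, cfg$mean_cells))
        cts <- stats::setNames(
          as.integer(stats::rmultinom(1, n_cells, comp)), types)
        # independent weighted-sum IE (oracle code path)
        for (g in seq_len(G)) {
          acc <- 0
          for (t in seq_along(types)) {
            acc <- acc + (cts[t] / n_cells) * refs$vectors[g, types[t]]
          }
          ie[k, g] <- acc
        }
        morph[k, ] <- as.numeric(cts %*% morph_map) / cfg$mean_cells
        patches[, , , k] <- render_patch_impl(cts, cfg)$image
        count_rows[[k]] <- tibble(patch_id = sprintf("%s_s%03d", sec_id, i),
                                  !!!as.list(cts))
        grid_n <- ceiling(sqrt(cfg$spots_per_section))
        meta_rows[[k]] <- tibble(
          spot_id = sprintf("%s_s%03d", sec_id, i), section_id = sec_id,
          patient_id = sprintf("patient%02d", (s + 1L) %/% 2L),
          x = ((i - 1L) %% grid_n) * cfg$patch_size + cfg$patch_size %/% 2L,
          y = ((i - 1L) %/% grid_n) * cfg$patch_size + cfg$patch_size %/% 2L,
          background = FALSE)
      }
    }
    labels <- ie + cfg$morph_signal_strength * morph +
      matrix(rnorm(n_total * G, sd = cfg$noise_sd), n_total, G)
    colnames(labels) <- as.character(panel)
    meta <- dplyr::bind_rows(meta_rows)
    cell_counts <- dplyr::bind_rows(count_rows)

    # raw NB counts per spot so the files exercise the preprocessing path
    sections <- lapply(split(seq_len(n_total), meta$section_id), function(idx) {
      mu_raw <- expm1(pmax(labels[idx, , drop = FALSE], 0))
      raw <- matrix(rnbinom(length(mu_raw), mu = as.numeric(mu_raw), size = 5),
                    nrow = length(idx))
      section_data(meta$section_id[idx[1]], meta$patient_id[idx[1]],
                   select(meta[idx, ], "spot_id", "x", "y", "background"),
                   raw, as.character(panel))
    })

    dataset <- as_spot_dataset(patches, ie, labels, meta, panel,
                               cell_counts = cell_counts, reference = refs)
    structure(list(dataset = dataset, scr = scr, refs = refs,
                   sections = unname(sections[unique(meta$section_id)]),
                   morph_map = morph_map, morph = morph, cfg = cfg),
              class = "sim_study")
  })
}
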