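# Training on (patch, IE) -> normalized-expression pairs by Adam on
# mean-squared error, and the leave-one-section-out protocol.

#' Assemble a model-ready spot dataset
#'
#' @param patches Array `(patch_size, patch_size, 3, n_spots)` in `[0, 1]`.
#' @param ie Matrix `(n_spots x n_genes)` of initial-expression priors.
#' @param labels Matrix `(n_spots x n_genes)` of normalized log
#'   expression (the regression target).
#' @param meta Tibble with `spot_id`, `section_id`, `patient_id`.
#' @param panel The `gene_panel` the columns follow.
#' @param cell_counts Optional tibble of per-spot cell-type counts (one
#'   column per type) — needed by the `cellratio_noise` variant.
#' @param reference Optional `reference_panel` used to build `ie` — ditto.
#' @return A `spot_dataset` object.
#' @export
as_spot_dataset <- function(patches, ie, labels, meta, panel,
                            cell_counts = NULL, reference = NULL) {
  meta <- as_tibble(meta)
  stopifnot(all(c("spot_id", "section_id", "patient_id") %in% names(meta)))
  n <- nrow(meta)
  stopifnot(dim(patches)[4] == n, nrow(ie) == n, nrow(labels) == n,
            ncol(ie) == length(panel), ncol(labels) == length(panel))
  rownames(ie) <- rownames(labels) <- meta$spot_id
  structure(list(patches = patches, ie = ie, labels = labels, meta = meta,
                 panel = panel, cell_counts = cell_counts,
                 reference = reference),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("<spot_dataset> %d spots, %d sections, %d genes, %dpx patches\n",
              nrow(x$meta), length(unique(x$meta$section_id)),
              length(x$panel), dim(x$patches)[1]))
  invisible(x)
}

#' Subset a spot dataset by spot index or section
#'
#' @param dataset A `spot_dataset`.
#' @param idx Integer/logical spot indices.
#' @return The subset `spot_dataset`.
#' @export
subset_spots <- function(dataset, idx) {
  if (is.logical(idx)) idx <- which(idx)
  as_spot_dataset(dataset$patches[, , , idx, drop = FALSE],
                  dataset$ie[idx, , drop = FALSE],
                  dataset$labels[idx, , drop = FALSE],
                  dataset$meta[idx, ], dataset$panel,
                  cell_counts = if (!is.null(dataset$cell_counts))
                    dataset$cell_counts[idx, ],
                  reference = dataset$reference)
}

#' Training hyperparameters
#'
#' Defaults follow the full-scale protocol (batch 32, 81 epochs, Adam on
#' mean-squared error); [desk_train_config()] is the short schedule used
#' for the package's small-backbone synthetic studies (30 epochs at
#' learning rate 2e-3 with gradient clipping), sized so a full
#' leave-one-section-out run stays in the minutes range on one CPU.
#'
#' @param batch_size Spots per gradient step.
#' @param epochs Passes over the training split.
#' @param learning_rate Adam step size.
#' @param clip_norm Global gradient-norm clip (`Inf` disables).
#' @param seed Seed driving shuffling (weights are seeded by the model
#'   config).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, epochs = 81L,
                         learning_rate = 1e-4, clip_norm = 1,
                         seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0, clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  modifyList(train_config(epochs = 30L, learning_rate = 2e-3), list(...))
}

# model-dependent IE of a dataset (random_ie / cellratio_noise variants)
prepare_ie <- function(model, dataset) {
  cfg <- model$config
  ie <- apply_ie_variant(model, dataset$ie)
  if (cfg$variant == "cellratio_noise") {
    if (is.null(dataset$cell_counts) || is.null(dataset$reference)) {
      stopf("cellratio_noise needs cell_counts and reference in the dataset")
    }
    ie <- cellratio_noise_ie(dataset$cell_counts, dataset$reference,
                             level = cfg$cellratio_noise_level,
                             seed = child_seed(cfg$seed, 23L))
    rownames(ie) <- dataset$meta$spot_id
  }
  ie
}

#' IE recomposed under Dirichlet-perturbed cell-type ratios
#'
#' Each spot's mixture weights are replaced by
#' `(1 - level) * pi + level * d` with `d` a flat Dirichlet draw, before
#' mixing the reference vectors.
#'
#' @param cell_counts Tibble of per-spot non-dead cell-type counts.
#' @param refs A `reference_panel`.
#' @param level Perturbation scale in `[0, 1]`.
#' @param seed Seed for the Dirichlet draws.
#' @return IE matrix `(n_spots x N_G)`.
#' @export
cellratio_noise_ie <- function(cell_counts, refs, level = 0.3, seed = 1L) {
  types <- colnames(refs$vectors)
  k <- length(types)
  n <- nrow(cell_counts)
  with_seed(seed, {
    out <- matrix(0, n, nrow(refs$vectors),
                  dimnames = list(NULL, rownames(refs$vectors)))
    for (i in seq_len(n)) {
      w <- compute_weights(unlist(cell_counts[i, types]), ref_types = types)
      g <- rgamma(k, shape = 1)
      w2 <- (1 - level) * w$weights + level * g / sum(g)
      out[i, ] <- as.numeric(refs$vectors %*% w2)
    }
    out
  })
}

#' Train a model on a spot dataset
#'
#' Minimizes mean-squared error between predictions and the dataset's
#' normalized labels with Adam. Deterministic given the model and
#' training seeds. Aborts with diagnostics if the loss turns non-finite.
#'
#' @param model A `scspot_model` (weights are consumed and returned
#'   updated).
#' @param dataset A `spot_dataset`.
#' @param cfg A [train_config()].
#' @return A `scspot_fit`: `model` (trained), `history` (tibble `epoch`,
#'   `loss`), `train_config`.
#' @export
train_scspot <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "scspot_model"), inherits(dataset, "spot_dataset"))
  n <- nrow(dataset$meta)
  if (n == 0) stopf("empty training dataset")
  ie <- prepare_ie(model, dataset)
  labels <- dataset$labels
  patches_n <- normalize_patches(dataset$patches)
  opt <- adam_init(model$params, lr = cfg$learning_rate)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(child_seed(cfg$seed, ep), sample(n))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      fw <- forward_scspot(model,
                           patches_n[, , , idx, drop = FALSE],
                           ie[idx, , drop = FALSE], normalized = TRUE)
      resid <- fw$pred - labels[idx, , drop = FALSE]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stopf("training diverged at epoch %d (loss %g)", ep, loss)
      }
      bw <- backward_scspot(2 * resid / length(resid), fw$cache)
      grads <- bw$grads
      if (is.finite(cfg$clip_norm)) {
        gn <- sqrt(tree_sum_sq(grads))
        if (gn > cfg$clip_norm) {
          scl <- cfg$clip_norm / gn
          grads <- tree_map(grads, function(g) g * scl)
        }
      }
      st <- adam_step(opt, model$params, grads)
      opt <- st$state
      model$params <- st$params
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
    }
    losses[ep] <- ep_loss / n_batches
  }
  structure(list(model = model,
                 history = tibble(epoch = seq_len(cfg$epochs), loss = losses),
                 train_config = cfg),
            class = "scspot_fit")
}

#' @export
print.scspot_fit <- function(x, ...) {
  cat(sprintf("<scspot_fit> %d epochs, final loss %.4g (variant %s)\n",
              nrow(x$history), x$history$loss[nrow(x$history)],
              x$model$config$variant))
  invisible(x)
}

#' Leave-one-section-out folds
#'
#' @param sections Character vector of section ids, or a list of
#'   [section_data()] objects.
#' @return List of folds, each `list(train = ids, test = id)`; every
#'   section is held out exactly once, in input order.
#' @export
loso_folds <- function(sections) {
  ids <- if (is.character(sections)) sections else
    vapply(sections, function(s) s$section_id, character(1))
  ids <- unique(ids)
  if (length(ids) < 2) stopf("leave-one-section-out needs >= 2 sections")
  lapply(ids, function(id) list(train = setdiff(ids, id), test = id))
}

#' Run leave-one-section-out training and evaluation
#'
#' For each fold, builds a fresh model from `config`, trains it on the
#' remaining sections and scores per-gene PCC on the held-out section.
#'
#' @param dataset A `spot_dataset` spanning >= 2 sections.
#' @param config A [scspot_config()].
#' @param cfg A [train_config()].
#' @return A `scspot_loso`: `per_section` tibble (`section_id`,
#'   `mean_pcc`, `median_pcc`, `n_undefined`), `per_gene` tibble,
#'   `predictions` (list of matrices), `config`.
#' @export
run_loso <- function(dataset, config, cfg = desk_train_config()) {
  folds <- loso_folds(unique(dataset$meta$section_id))
  rows <- list(); gene_rows <- list(); preds <- list()
  for (f in folds) {
    tr <- subset_spots(dataset, dataset$meta$section_id %in% f$train)
    te <- subset_spots(dataset, dataset$meta$section_id == f$test)
    fit <- train_scspot(make_variant(config), tr, cfg)
    ie_te <- prepare_ie(fit$model, te)
    pred <- predict(fit$model, te$patches, ie_te)
    colnames(pred) <- as.character(dataset$panel)
    res <- per_sample_pcc(pred, te$labels)
    rows[[f$test]] <- tibble(section_id = f$test, mean_pcc = res$mean_pcc,
                             median_pcc = res$median_pcc,
                             n_undefined = res$n_undefined)
    gene_rows[[f$test]] <- mutate(res$per_gene, section_id = f$test)
    preds[[f$test]] <- pred
  }
  structure(list(per_section = dplyr::bind_rows(rows),
                 per_gene = dplyr::bind_rows(gene_rows),
                 predictions = preds, config = config),
            class = "scspot_loso")
}

#' @export
print.scspot_loso <- function(x, ...) {
  cat(sprintf("<scspot_loso> variant %s: held-out mean PCC %.3f (median %.3f) over %d sections\n",
              x$config$variant, mean(x$per_section$mean_pcc),
              mean(x$per_section$median_pcc), nrow(x$per_section)))
  invisible(x)
}
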