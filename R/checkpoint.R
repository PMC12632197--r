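# Model checkpoints: weights plus everything needed to reproduce a
# prediction — configuration, gene panel, normalization target and a
# fingerprint of the reference panel the IE inputs must come from.

# order-sensitive checksum of a numeric matrix (integrity marker, not
# cryptographic)
ref_fingerprint <- function(vectors) {
  v <- as.numeric(vectors)
  sprintf("%015.0f", sum(v * seq_along(v)) %% 1e15)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the weights, the [scspot_config()], the gene
#' panel, the label-normalization target sum and a fingerprint of the
#' reference panel, so a prediction run can verify it is fed IE vectors
#' built from the same reference.
#'
#' @param model A `scspot_model` (or a `scspot_fit`, whose trained model
#'   is taken).
#' @param path Destination `.rds` path.
#' @param panel The `gene_panel` the model predicts.
#' @param target_sum Normalization target frozen with the model.
#' @param reference Optional `reference_panel` used for the IE inputs.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, panel, target_sum = NA_real_,
                            reference = NULL) {
  if (inherits(model, "scspot_fit")) model <- model$model
  stopifnot(inherits(model, "scspot_model"))
  ck <- list(params = model$params, config = model$config,
             gate = model$gate, scramble = model$scramble,
             panel = as.character(panel), target_sum = target_sum,
             reference_fingerprint = if (!is.null(reference))
               ref_fingerprint(reference$vectors))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param reference_check Optional `reference_panel` to verify against
#'   the stored fingerprint (a mismatch errors).
#' @return For `load_checkpoint()`, a `scspot_model` with attributes
#'   `panel` and `target_sum`.
#' @export
load_checkpoint <- function(path, reference_check = NULL) {
  ck <- readRDS(path)
  if (!is.null(reference_check) && !is.null(ck$reference_fingerprint) &&
      !identical(ref_fingerprint(reference_check$vectors),
                 ck$reference_fingerprint)) {
    stopf("checkpoint was trained against a different reference panel")
  }
  model <- structure(list(config = ck$config, params = ck$params,
                          gate = ck$gate, scramble = ck$scramble),
                     class = "scspot_model")
  attr(model, "panel") <- new_gene_panel(ck$panel)
  attr(model, "target_sum") <- ck$target_sum
  model
}
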