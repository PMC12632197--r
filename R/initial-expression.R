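# The biologically informed prior: per-patch cell-type counts are turned
# into mixture weights over the non-dead cell types, and the initial
# expression (IE) is the weight-averaged mixture of reference vectors.

#' Cell-count mixture weights over non-dead cell types
#'
#' `pi_i = N_i / sum_j N_j`, summing over the non-dead types only. When
#' every non-dead count is zero the weights fall back to uniform over
#' `ref_types` and the result is flagged degenerate.
#'
#' @param counts Named non-negative counts; names must cover the non-dead
#'   [pannuke_classes()] present (a `dead` entry is ignored).
#' @param ref_types Types of the reference panel, used for the degenerate
#'   uniform fallback and the output order.
#' @return List with `weights` (named, summing to 1) and `degenerate`.
#' @export
compute_weights <- function(counts, ref_types = nondead_classes()) {
  counts <- unlist(counts)
  if (any(counts < 0)) stopf("negative cell count")
  nd <- counts[setdiff(names(counts), "dead")]
  tot <- sum(nd)
  if (tot == 0) {
    w <- rep(1 / length(ref_types), length(ref_types))
    names(w) <- ref_types
    return(list(weights = w, degenerate = TRUE))
  }
  w <- stats::setNames(rep(0, length(ref_types)), ref_types)
  shared <- intersect(names(nd), ref_types)
  w[shared] <- nd[shared] / tot
  extra <- setdiff(names(nd)[nd > 0], ref_types)
  if (length(extra)) {
    stopf("nonzero count for type(s) missing from the reference: %s",
          paste(extra, collapse = ", "))
  }
  list(weights = w, degenerate = FALSE)
}

#' Compose the initial expression for one patch
#'
#' The IE is the exact weighted sum of the (already log-scale) reference
#' vectors, `sum_i pi_i * Ref_i`, with no renormalization afterwards.
#'
#' @param counts Named non-dead cell counts for the patch (see
#'   [compute_weights()]).
#' @param refs A `reference_panel` from [build_reference_panel()].
#' @return An `initial_expression` list: `values` (length `N_G`),
#'   `weights`, `degenerate`.
#' @export
compose_initial_expression <- function(counts, refs) {
  stopifnot(inherits(refs, "reference_panel"))
  w <- compute_weights(counts, ref_types = colnames(refs$vectors))
  values <- as.numeric(refs$vectors %*% w$weights)
  names(values) <- rownames(refs$vectors)
  structure(list(values = values, weights = w$weights,
                 degenerate = w$degenerate),
            class = "initial_expression")
}

#' Build the IE matrix for a table of per-patch counts
#'
#' @param count_tbl Tibble with a `patch_id` column plus one count column
#'   per cell type (as produced by [parse_segmentation_counts()]).
#' @param refs A `reference_panel`.
#' @return Matrix `(n_patches x N_G)` with `patch_id` rownames; the
#'   `degenerate` attribute flags zero-cell patches.
#' @export
compose_ie_matrix <- function(count_tbl, refs) {
  types <- colnames(refs$vectors)
  stopifnot(all(types %in% names(count_tbl)))
  out <- matrix(0, nrow(count_tbl), nrow(refs$vectors),
                dimnames = list(count_tbl$patch_id, rownames(refs$vectors)))
  degenerate <- logical(nrow(count_tbl))
  for (i in seq_len(nrow(count_tbl))) {
    cts <- unlist(count_tbl[i, types])
    ie <- compose_initial_expression(cts, refs)
    out[i, ] <- ie$values
    degenerate[i] <- ie$degenerate
  }
  attr(out, "degenerate") <- degenerate
  out
}

# instance-type codes used by the common nucleus segmenter's JSON output
HOVERNET_TYPE_CODES <- c("0" = "background", "1" = "neoplastic",
                         "2" = "inflammatory", "3" = "connective",
                         "4" = "dead", "5" = "epithelial")

#' Tally per-patch nucleus counts from segmentation output
#'
#' Accepts either a per-nucleus record table (columns `patch_id`,
#' `class`), a pre-tallied table (`patch_id`, `class`, `count`), or the
#' path to a JSON instance dictionary in the dialect of the common
#' nucleus-segmentation tool (per patch, a `nuc` map whose entries carry a
#' `type` code). Labels outside the five-class vocabulary are tallied in
#' a `rejected` column and reported with a warning.
#'
#' @param seg Data frame or JSON file path as above.
#' @return Tibble with `patch_id`, one column per [pannuke_classes()],
#'   and `rejected`.
#' @export
parse_segmentation_counts <- function(seg) {
  if (is.character(seg) && length(seg) == 1L) {
    recs <- jsonlite::read_json(seg)
    rows <- imap(recs, function(entry, pid) {
      types <- vapply(entry$nuc, function(nu) {
        if (is.null(nu$type)) stopf("malformed nucleus record in patch %s", pid)
        as.character(nu$type)
      }, character(1))
      tibble(patch_id = pid,
             class = unname(HOVERNET_TYPE_CODES[types]) %|NA|%
               paste0("code_", types))
    })
    seg <- dplyr::bind_rows(rows)
  }
  seg <- as_tibble(seg)
  stopifnot(all(c("patch_id", "class") %in% names(seg)))
  if (!"count" %in% names(seg)) seg$count <- 1L
  bad_row <- which(is.na(seg$class) | is.na(seg$patch_id) | seg$count < 0)
  if (length(bad_row)) stopf("malformed segmentation record at row %d", bad_row[1])
  seg$class <- ifelse(seg$class %in% pannuke_classes(), seg$class, "rejected")
  n_rej <- sum(seg$count[seg$class == "rejected"])
  if (n_rej > 0) warnf("%d nuclei with labels outside the five-class vocabulary", n_rej)
  wide <- seg |>
    group_by(.data$patch_id, .data$class) |>
    summarise(n = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cls in c(pannuke_classes(), "rejected")) {
    if (!cls %in% names(wide)) wide[[cls]] <- 0L
  }
  wide[, c("patch_id", pannuke_classes(), "rejected")]
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)
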