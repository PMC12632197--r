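# Building per-cell-type canonical reference vectors from a labelled
# single-cell dataset. Dead cells are excluded from every computation.

#' Bundle a labelled single-cell reference dataset
#'
#' @param counts Non-negative matrix `(n_cells x n_genes)`.
#' @param gene_names Unique gene symbols for the columns.
#' @param meta Tibble with columns `cell_id`, `major_type` (one of
#'   [pannuke_classes()]) and `minor_type` (free-text subtype; may be
#'   `NA` if the atlas provides no subtypes).
#' @return An `scr_dataset` object.
#' @export
scr_dataset <- function(counts, gene_names, meta) {
  meta <- as_tibble(meta)
  stopifnot(all(c("cell_id", "major_type") %in% names(meta)))
  if (!"minor_type" %in% names(meta)) meta$minor_type <- NA_character_
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(meta)) {
    stopf("%d count rows but %d metadata rows", nrow(counts), nrow(meta))
  }
  if (anyDuplicated(gene_names)) stopf("duplicate gene names")
  bad <- setdiff(unique(meta$major_type), pannuke_classes())
  if (length(bad)) {
    stopf("unknown major type(s): %s (expected %s)",
          paste(bad, collapse = ", "),
          paste(pannuke_classes(), collapse = ", "))
  }
  if (any(counts < 0)) stopf("negative counts")
  dimnames(counts) <- list(meta$cell_id, gene_names)
  structure(list(counts = counts, gene_names = as.character(gene_names),
                 meta = meta),
            class = "scr_dataset")
}

#' Pick the representative minor subtype within a major cell type
#'
#' Returns the minor subtype with the largest cell count within
#' `major_type` (ties broken lexicographically). If the dataset provides
#' no minor labels for the group, the whole major group is used and the
#' result is flagged (`whole_group` attribute).
#'
#' @param scr An [scr_dataset()].
#' @param major_type One of the non-dead [pannuke_classes()].
#' @return The chosen subtype label (character scalar).
#' @export
select_representative_subtype <- function(scr, major_type) {
  stopifnot(inherits(scr, "scr_dataset"))
  if (identical(major_type, "dead")) {
    stopf("dead cells are excluded from all computations")
  }
  sub <- scr$meta[scr$meta$major_type == major_type, ]
  if (nrow(sub) == 0) {
    stopf("no cells with major type '%s' (available: %s)", major_type,
          paste(unique(scr$meta$major_type), collapse = ", "))
  }
  if (all(is.na(sub$minor_type))) {
    out <- major_type
    attr(out, "whole_group") <- TRUE
    return(out)
  }
  tab <- table(sub$minor_type[!is.na(sub$minor_type)])
  lab <- sort(names(tab)[tab == max(tab)])[1]
  attr(lab, "whole_group") <- FALSE
  lab
}

#' Build one canonical reference vector from selected cells
#'
#' Restricts to the panel genes, library-size-normalizes each cell to
#' `target_sum` (the same target-sum rule used for spot labels, so the
#' prior and the regression target share a scale), averages over cells,
#' then applies the natural `log1p`.
#'
#' @param scr An [scr_dataset()].
#' @param cell_ids Cells to average over (non-empty).
#' @param panel A `gene_panel`; every panel gene must be present in `scr`.
#' @param target_sum Library-size target.
#' @return Named numeric vector of length `length(panel)`.
#' @export
build_reference_vector <- function(scr, cell_ids, panel, target_sum) {
  stopifnot(inherits(scr, "scr_dataset"), length(cell_ids) >= 1)
  genes <- as.character(panel)
  missing <- setdiff(genes, scr$gene_names)
  if (length(missing)) {
    stopf("panel gene(s) missing from the reference: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  x <- scr$counts[cell_ids, genes, drop = FALSE]
  s <- rowSums(x)
  s[s == 0] <- 1  # all-zero cells contribute an all-zero profile
  norm <- x / s * target_sum
  log1p(colMeans(norm)) |> stats::setNames(genes)
}

#' Build the full reference panel over non-dead cell types
#'
#' For every non-dead major type present in the dataset, selects the
#' representative minor subtype ([select_representative_subtype()]) and
#' builds its canonical vector ([build_reference_vector()]). Dead cells
#' never contribute.
#'
#' @inheritParams build_reference_vector
#' @return A `reference_panel`: list with `panel` (gene_panel), `vectors`
#'   (matrix genes x cell types), `target_sum`, and `provenance` (tibble
#'   naming the chosen subtype and cell count per type).
#' @export
build_reference_panel <- function(scr, panel, target_sum) {
  stopifnot(inherits(scr, "scr_dataset"))
  types <- intersect(nondead_classes(), unique(scr$meta$major_type))
  if (length(types) == 0) stopf("reference contains no non-dead cells")
  genes <- as.character(panel)
  vectors <- matrix(0, length(genes), length(types),
                    dimnames = list(genes, types))
  prov <- vector("list", length(types))
  for (i in seq_along(types)) {
    ty <- types[i]
    sub <- select_representative_subtype(scr, ty)
    whole <- isTRUE(attr(sub, "whole_group"))
    sel <- scr$meta$major_type == ty &
      (whole | (!is.na(scr$meta$minor_type) & scr$meta$minor_type == sub))
    ids <- scr$meta$cell_id[sel]
    vectors[, i] <- build_reference_vector(scr, ids, panel, target_sum)
    prov[[i]] <- tibble(cell_type = ty, subtype = as.character(sub),
                        whole_group = whole, n_cells = length(ids))
  }
  structure(list(panel = new_gene_panel(genes), vectors = vectors,
                 target_sum = target_sum,
                 provenance = dplyr::bind_rows(prov)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d genes x %d cell types (%s)\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(colnames(x$vectors), collapse = ", ")))
  invisible(x)
}
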