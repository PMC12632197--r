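# Section preprocessing: patch extraction around spot centers, gene-panel
# selection by pooled variance, spot-level label normalization, and the
# minimum-spot section filter.

#' Bundle one tissue section's spots and counts
#'
#' @param section_id,patient_id Identifiers.
#' @param spots Tibble with columns `spot_id`, `x`, `y` (pixel center
#'   coordinates, 0-based, non-negative) and `background` (logical or 0/1;
#'   spots without tissue/expression).
#' @param counts Non-negative integer matrix `(n_spots x n_genes)`, rows
#'   aligned with `spots`.
#' @param gene_names Unique gene symbols for the count columns.
#' @return A `section_data` object.
#' @export
section_data <- function(section_id, patient_id, spots, counts, gene_names) {
  spots <- as_tibble(spots)
  stopifnot(all(c("spot_id", "x", "y", "background") %in% names(spots)))
  spots$background <- as.logical(spots$background)
  if (anyDuplicated(spots$spot_id)) {
    stopf("duplicate spot_id in section %s", section_id)
  }
  if (any(spots$x < 0) || any(spots$y < 0)) {
    stopf("negative spot center coordinates in section %s", section_id)
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(spots)) {
    stopf("section %s: %d count rows but %d spots", section_id,
          nrow(counts), nrow(spots))
  }
  if (anyDuplicated(gene_names)) stopf("duplicate gene names")
  if (ncol(counts) != length(gene_names)) {
    stopf("section %s: %d count columns but %d gene names", section_id,
          ncol(counts), length(gene_names))
  }
  if (any(counts < 0)) stopf("negative counts in section %s", section_id)
  dimnames(counts) <- list(spots$spot_id, gene_names)
  structure(list(section_id = as.character(section_id),
                 patient_id = as.character(patient_id),
                 spots = spots, counts = counts,
                 gene_names = as.character(gene_names)),
            class = "section_data")
}

#' Extract a fixed-size patch around a spot center
#'
#' The window is half-open in 0-based pixel coordinates:
#' `[center - half_size, center + half_size)` along both axes, with
#' `(row, col) = (y, x)` and the origin at the image's top-left — so the
#' default `half_size = 112` yields an exact 224x224 patch. Windows that
#' overhang the image are reflect-padded with a warning; a center outside
#' the image is an error.
#'
#' @param image Numeric array `(H, W, 3)` (values in `[0, 1]`) or `(H, W)`.
#' @param spot One-row data frame or list with `spot_id`, `x`, `y`
#'   (0-based center pixel coordinates).
#' @param half_size Half window side in pixels.
#' @return Array `(2 * half_size, 2 * half_size, 3)`.
#' @export
extract_patch <- function(image, spot, half_size = 112L) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  cx <- as.integer(spot$x); cy <- as.integer(spot$y)
  id <- as.character(spot$spot_id %||% "?")
  if (cx < 0 || cx >= W || cy < 0 || cy >= H) {
    stopf("spot %s center (x=%d, y=%d) lies outside the %dx%d image",
          id, cx, cy, W, H)
  }
  rows <- (cy - half_size + 1L):(cy + half_size)  # 1-based row indices
  cols <- (cx - half_size + 1L):(cx + half_size)
  if (any(rows < 1L) || any(rows > H) || any(cols < 1L) || any(cols > W)) {
    warnf("spot %s: window extends outside the image; reflect-padding", id)
    rows <- reflect_index(rows, H)
    cols <- reflect_index(cols, W)
  }
  if (length(d) == 2L) image[rows, cols] else image[rows, cols, , drop = FALSE]
}

# mirror out-of-range indices about the image edges
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  if (any(i < 1L | i > n)) stopf("window overhang exceeds image size")
  i
}

#' Select the gene panel by pooled cross-section variance
#'
#' Genes are ranked by the variance of their library-size-normalized,
#' log1p-transformed expression pooled over every spot of every section,
#' restricted to genes also present in the single-cell reference. Ties are
#' broken lexicographically, so the result is deterministic.
#'
#' @param sections List of [section_data()] objects.
#' @param scr_genes Gene symbols available in the single-cell reference.
#' @param top_k Panel size (if fewer genes intersect, all are returned
#'   with a warning).
#' @return A character vector of class `gene_panel`, ordered by rank.
#' @export
select_gene_panel <- function(sections, scr_genes, top_k = 785L) {
  stopifnot(top_k >= 1, length(sections) >= 1)
  common <- Reduce(intersect, c(lapply(sections, function(s) s$gene_names),
                                list(scr_genes)))
  if (length(common) == 0) stopf("no genes shared between sections and the reference")
  pooled <- do.call(rbind, lapply(sections, function(s) {
    s$counts[, common, drop = FALSE]
  }))
  target <- stats::median(rowSums(pooled))
  norm <- t(apply(pooled, 1, scale_log1p, target = target))
  v <- apply(norm, 2, stats::var)
  ord <- order(-v, common)
  if (length(common) < top_k) {
    warnf("only %d genes shared with the reference (requested %d)",
          length(common), top_k)
    top_k <- length(common)
  }
  new_gene_panel(common[ord][seq_len(top_k)])
}

new_gene_panel <- function(genes) {
  if (anyDuplicated(genes)) stopf("duplicate genes in panel")
  structure(as.character(genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes: %s%s\n", length(x),
              paste(head(unclass(x), 5), collapse = ", "),
              if (length(x) > 5) ", ..." else ""))
  invisible(x)
}

#' Median panel-gene library size across sections
#'
#' The normalization target frozen with a trained model: the median of
#' per-spot total counts over the panel genes, pooled over the supplied
#' (training) sections.
#'
#' @param sections List of [section_data()] objects.
#' @param panel A `gene_panel`.
#' @return A scalar target sum.
#' @export
median_panel_libsize <- function(sections, panel) {
  libs <- unlist(lapply(sections, function(s) {
    rowSums(s$counts[, as.character(panel), drop = FALSE])
  }))
  stats::median(libs)
}

#' Normalize one spot's counts into model labels
#'
#' Restricts the raw count row to the panel genes, scales it so the
#' panel-gene sum equals `target_sum`, and applies the natural `log1p`.
#' All-zero rows map to all-zero output.
#'
#' @param counts_row Named non-negative count vector covering the panel
#'   genes.
#' @param panel A `gene_panel`.
#' @param target_sum Library-size target (see [median_panel_libsize()]).
#' @return Numeric vector of length `length(panel)`.
#' @export
normalize_labels <- function(counts_row, panel, target_sum) {
  genes <- as.character(panel)
  x <- counts_row[genes]
  if (anyNA(x)) stopf("count row is missing panel genes")
  if (any(x < 0)) stopf("negative count entry")
  scale_log1p(as.numeric(x), target_sum) |> stats::setNames(genes)
}

#' @rdname normalize_labels
#' @param counts Count matrix `(n_spots x n_genes)` with gene columns.
#' @return For `normalize_label_matrix()`, a `(n_spots x length(panel))`
#'   matrix.
#' @export
normalize_label_matrix <- function(counts, panel, target_sum) {
  genes <- as.character(panel)
  if (!all(genes %in% colnames(counts))) stopf("counts lack panel genes")
  x <- counts[, genes, drop = FALSE]
  if (any(x < 0)) stopf("negative count entry")
  out <- t(apply(x, 1, scale_log1p, target = target_sum))
  dimnames(out) <- list(rownames(counts), genes)
  out
}

#' Drop sections with too few non-background spots
#'
#' Sections whose non-background spot count is strictly below `min_spots`
#' are excluded; input order is preserved.
#'
#' @param sections List of [section_data()] objects.
#' @param min_spots Minimum number of non-background spots (default 180).
#' @return The retained sublist.
#' @export
filter_sections <- function(sections, min_spots = 180L) {
  keep <- vapply(sections, function(s) sum(!s$spots$background) >= min_spots,
                 logical(1))
  sections[keep]
}
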