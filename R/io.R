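# Readers and writers for the pipeline's on-disk dialects: spot tables
# (TSV), expression (matrix-market sparse or dense TSV), gene panels
# (one-column text), reference panels (genes x cell types TSV), IE
# matrices (TSV), segmentation tallies (TSV), and PNG patches.

#' Read and write spot tables
#'
#' TSV with columns `spot_id`, `section_id`, `patient_id`, `x`, `y`,
#' `background` (0/1).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_spot_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    spot_id = "c", section_id = "c", patient_id = "c",
                    x = "i", y = "i", background = "i")) |>
    mutate(background = as.logical(.data$background))
}

#' @rdname read_spot_table
#' @param spots Tibble as above.
#' @export
write_spot_table <- function(spots, path) {
  spots |>
    mutate(background = as.integer(.data$background)) |>
    readr::write_tsv(path)
}

#' Read/write a count matrix (matrix-market sparse with sidecars)
#'
#' `write_counts_mtx()` writes `<stem>.mtx` plus `<stem>.genes.txt` and
#' `<stem>.barcodes.txt`; `read_counts_mtx()` reads them back into a
#' dense matrix with barcode rownames and gene colnames. A dense TSV
#' (genes in columns, `spot_id` first column) is also supported.
#'
#' @param stem Path stem (without extension).
#' @return For readers, a numeric matrix.
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readr::read_lines(paste0(stem, ".barcodes.txt"))
  colnames(m) <- readr::read_lines(paste0(stem, ".genes.txt"))
  m
}

#' @rdname read_counts_mtx
#' @param counts Matrix `(spots/cells x genes)` with dimnames.
#' @export
write_counts_mtx <- function(counts, stem) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(stem, ".mtx"))
  readr::write_lines(rownames(counts), paste0(stem, ".barcodes.txt"))
  readr::write_lines(colnames(counts), paste0(stem, ".genes.txt"))
  invisible(stem)
}

#' @rdname read_counts_mtx
#' @param path TSV path for the dense dialect.
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_counts_mtx
#' @export
write_counts_tsv <- function(counts, path) {
  tibble(spot_id = rownames(counts)) |>
    dplyr::bind_cols(as_tibble(counts)) |>
    readr::write_tsv(path)
}

#' Read/write a gene panel as a one-column text file
#'
#' @param path File path.
#' @return A `gene_panel`.
#' @export
read_gene_panel <- function(path) new_gene_panel(readr::read_lines(path))

#' @rdname read_gene_panel
#' @param panel A `gene_panel`.
#' @export
write_gene_panel <- function(panel, path) {
  readr::write_lines(as.character(panel), path)
  invisible(path)
}

#' Read/write a reference panel (genes x cell types TSV)
#'
#' The TSV carries one `gene` column plus one column per cell type; the
#' normalization target sum is stored in a `# target_sum:` header line,
#' and provenance in a sibling `<path>.provenance.tsv`.
#'
#' @param path File path.
#' @return A `reference_panel`.
#' @export
read_reference_panel <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  target <- as.numeric(sub("^# target_sum:\\s*", "", first))
  df <- readr::read_tsv(path, skip = 1, show_col_types = FALSE)
  vectors <- as.matrix(df[, -1])
  rownames(vectors) <- df$gene
  prov_path <- paste0(path, ".provenance.tsv")
  prov <- if (file.exists(prov_path)) {
    readr::read_tsv(prov_path, show_col_types = FALSE)
  }
  structure(list(panel = new_gene_panel(df$gene), vectors = vectors,
                 target_sum = target, provenance = prov),
            class = "reference_panel")
}

#' @rdname read_reference_panel
#' @param refs A `reference_panel`.
#' @export
write_reference_panel <- function(refs, path) {
  readr::write_lines(sprintf("# target_sum: %.10g", refs$target_sum), path)
  tibble(gene = rownames(refs$vectors)) |>
    dplyr::bind_cols(as_tibble(refs$vectors)) |>
    readr::write_tsv(path, append = TRUE, col_names = TRUE)
  if (!is.null(refs$provenance)) {
    readr::write_tsv(refs$provenance, paste0(path, ".provenance.tsv"))
  }
  invisible(path)
}

#' Read/write an IE (or label/prediction) matrix as TSV
#'
#' Spots in rows (first column `spot_id`), panel genes in columns.
#'
#' @param path File path.
#' @return A numeric matrix with spot rownames.
#' @export
read_matrix_tsv <- function(path) read_counts_tsv(path)

#' @rdname read_matrix_tsv
#' @param m Matrix with spot rownames and gene colnames.
#' @export
write_matrix_tsv <- function(m, path) write_counts_tsv(m, path)

#' Read/write an RGB patch as PNG
#'
#' @param path File path.
#' @return Array `(H, W, 3)` in `[0, 1]`.
#' @export
read_patch_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_patch_png
#' @param img Array `(H, W, 3)` in `[0, 1]`.
#' @export
write_patch_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Write or read a complete synthetic study directory
#'
#' Emits every file dialect the pipeline consumes: `spots.tsv`,
#' per-section raw counts (`counts_<section>.mtx` + sidecars),
#' `labels.tsv`, `ie.tsv`, `gene_panel.txt`, `reference_panel.tsv`,
#' the single-cell reference (`scr.mtx` + sidecars, `scr_meta.tsv`),
#' `segmentation.tsv` (long patch_id/class/count), per-spot PNG patches
#' under `patches/`, and a `manifest.tsv` linking spot to patch file and
#' label row.
#'
#' @param study A `sim_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(file.path(dir, "patches"), recursive = TRUE,
             showWarnings = FALSE)
  ds <- study$dataset
  write_spot_table(ds$meta, file.path(dir, "spots.tsv"))
  for (sec in study$sections) {
    write_counts_mtx(sec$counts,
                     file.path(dir, paste0("counts_", sec$section_id)))
  }
  write_matrix_tsv(ds$labels, file.path(dir, "labels.tsv"))
  write_matrix_tsv(ds$ie, file.path(dir, "ie.tsv"))
  write_gene_panel(ds$panel, file.path(dir, "gene_panel.txt"))
  write_reference_panel(study$refs, file.path(dir, "reference_panel.tsv"))
  write_counts_mtx(study$scr$counts, file.path(dir, "scr"))
  readr::write_tsv(study$scr$meta, file.path(dir, "scr_meta.tsv"))
  ds$cell_counts |>
    tidyr::pivot_longer(-"patch_id", names_to = "class",
                        values_to = "count") |>
    readr::write_tsv(file.path(dir, "segmentation.tsv"))
  patch_files <- file.path("patches", paste0(ds$meta$spot_id, ".png"))
  for (i in seq_len(nrow(ds$meta))) {
    write_patch_png(ds$patches[, , , i], file.path(dir, patch_files[i]))
  }
  ds$meta |>
    mutate(patch_file = patch_files, label_row = dplyr::row_number()) |>
    select("spot_id", "section_id", "patch_file", "label_row") |>
    readr::write_tsv(file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_study
#' @return For `read_study()`, a list with `meta`, `sections`, `labels`,
#'   `ie`, `panel`, `refs`, `scr`, `cell_counts`, `patches`.
#' @export
read_study <- function(dir) {
  meta <- read_spot_table(file.path(dir, "spots.tsv"))
  panel <- read_gene_panel(file.path(dir, "gene_panel.txt"))
  refs <- read_reference_panel(file.path(dir, "reference_panel.tsv"))
  scr_counts <- read_counts_mtx(file.path(dir, "scr"))
  scr_meta <- readr::read_tsv(file.path(dir, "scr_meta.tsv"),
                              show_col_types = FALSE)
  scr <- scr_dataset(scr_counts, colnames(scr_counts), scr_meta)
  sections <- lapply(unique(meta$section_id), function(sid) {
    m <- meta[meta$section_id == sid, ]
    counts <- read_counts_mtx(file.path(dir, paste0("counts_", sid)))
    section_data(sid, m$patient_id[1],
                 select(m, "spot_id", "x", "y", "background"),
                 counts, colnames(counts))
  })
  seg <- readr::read_tsv(file.path(dir, "segmentation.tsv"),
                         show_col_types = FALSE)
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  patches <- NULL
  if (nrow(manifest) > 0 &&
      file.exists(file.path(dir, manifest$patch_file[1]))) {
    p1 <- read_patch_png(file.path(dir, manifest$patch_file[1]))
    patches <- array(0, c(dim(p1), nrow(manifest)))
    for (i in seq_len(nrow(manifest))) {
      patches[, , , i] <- read_patch_png(file.path(dir,
                                                   manifest$patch_file[i]))
    }
  }
  list(meta = meta, sections = sections,
       labels = read_matrix_tsv(file.path(dir, "labels.tsv")),
       ie = read_matrix_tsv(file.path(dir, "ie.tsv")),
       panel = panel, refs = refs, scr = scr,
       cell_counts = parse_segmentation_counts(seg),
       patches = patches, manifest = manifest)
}
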