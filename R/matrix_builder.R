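# gffcompare-style class codes treated as exonic, as in the droplet
# single-cell convention the pipeline mirrors
EXONIC_CLASS_CODES <- c("=", "c", "k", "m", "n", "j", "e", "o")

# shared front half of both matrix builders: validate, filter, UMI-filter,
# count reads per (cell, feature, umi) and deduplicate UMIs per group
prepare_molecules <- function(records, feature_col, config,
                              class_filter = TRUE) {
  if (anyDuplicated(records[c("read_id", "segment_index")]) > 0) {
    abort("duplicate (read_id, segment_index) rows in record stream")
  }
  if (class_filter) {
    exonic <- records$class_code %in% EXONIC_CLASS_CODES
    if (any(exonic & (is.na(records$gene_id) | !nzchar(records$gene_id)))) {
      abort("record with exonic class_code but missing gene_id (corrupt feature assignment)")
    }
    records <- records[exonic, , drop = FALSE]
  }
  records <- records |>
    filter(!is.na(.data$corrected_barcode),
           !is.na(.data[[feature_col]]), nzchar(.data[[feature_col]]))
  umi_q <- if ("umi_qual" %in% names(records)) records$umi_qual else
    NA_character_
  keep <- filter_umi(records$raw_umi, umi_q, config$umi_min_qual)$pass
  records <- records[keep, , drop = FALSE]
  molecules <- records |>
    count(cell = .data$corrected_barcode, feature = .data[[feature_col]],
          umi = .data$raw_umi, name = "count")
  dedup_umi_groups(molecules)
}

entries_to_matrix <- function(entries) {
  feats <- sort(unique(entries$feature))
  cells <- sort(unique(entries$cell))
  Matrix::sparseMatrix(
    i = match(entries$feature, feats),
    j = match(entries$cell, cells),
    x = entries$n_umi,
    dims = c(length(feats), length(cells)),
    dimnames = list(feats, cells)
  )
}

#' Build the single-cell gene UMI-count matrix
#'
#' Records whose class code is outside the exonic set
#' (`= c k m n j e o`) are excluded; UMIs are quality-filtered and
#' deduplicated within each (cell, gene) group; each matrix entry is the
#' number of distinct corrected UMIs. Features (rows) and cells (columns) are
#' ordered lexicographically.
#'
#' @param records joined record stream: one row per demultiplexed unit with
#'   `read_id`, `segment_index`, `corrected_barcode` (`NA` = unassigned,
#'   dropped), `raw_umi`, optional `umi_qual`, `gene_id`, `class_code`.
#' @param config a [demux_config()].
#' @return a sparse `dgCMatrix`, genes x cells.
#' @export
build_gene_matrix <- function(records, config = demux_config()) {
  mol <- prepare_molecules(records, "gene_id", config)
  entries <- mol |> count(.data$cell, .data$feature, name = "n_umi")
  entries_to_matrix(entries)
}

#' Build the single-cell isoform UMI-count matrix
#'
#' As [build_gene_matrix()] but keyed by `isoform_id`, with the two abundance
#' filters applied: (cell, isoform) entries supported by fewer than
#' `min_umi_count` distinct corrected UMIs are dropped, and isoforms then
#' detected in fewer than `min_cells` cells are removed entirely.
#'
#' @inheritParams build_gene_matrix
#' @param min_umi_count minimum distinct-UMI count per retained entry.
#' @param min_cells minimum number of cells an isoform must be detected in.
#' @export
build_isoform_matrix <- function(records, min_umi_count = 3L, min_cells = 5L,
                                 config = demux_config()) {
  mol <- prepare_molecules(records, "isoform_id", config)
  entries <- mol |>
    count(.data$cell, .data$feature, name = "n_umi") |>
    filter(.data$n_umi >= min_umi_count) |>
    group_by(.data$feature) |>
    filter(dplyr::n_distinct(.data$cell) >= min_cells) |>
    ungroup()
  entries_to_matrix(entries)
}

#' Write a count matrix in Matrix Market exchange layout
#'
#' Writes `matrix.mtx` (1-based triplets) with `features.tsv` and
#' `barcodes.tsv` sidecars, the de-facto single-cell exchange layout.
#'
#' @param mat sparse matrix from [build_gene_matrix()] /
#'   [build_isoform_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat, file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  mat <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(mat) <- list(readLines(file.path(dir, "features.tsv")),
                        readLines(file.path(dir, "barcodes.tsv")))
  mat
}

#' Per-cell summaries of a count matrix
#'
#' @param mat sparse features x cells matrix.
#' @return tibble: `cell`, `n_features`, `n_umi`.
#' @export
per_cell_stats <- function(mat) {
  tibble(cell = colnames(mat),
         n_features = unname(Matrix::colSums(mat > 0)),
         n_umi = unname(Matrix::colSums(mat)))
}

#' Scatter of per-cell gene and UMI totals
#'
#' @param object sparse count matrix (features x cells).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_cell_totals <- function(object, ...) {
  df <- per_cell_stats(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_features, y = .data$n_umi)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "features detected per cell", y = "UMIs per cell")
}
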