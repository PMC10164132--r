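#' Full demultiplexing pipeline
#'
#' Convenience wrapper running segmentation ([demux_reads()]), read-QV
#' filtering, whitelist frequency counting, posterior barcode correction and -
#' when a feature-assignment table is supplied - gene and isoform count-matrix
#' construction.
#'
#' Records with `read_qv` below `config$qv_cutoff` are excluded from barcode
#' counting and assignment (the priors are computed on the same record set
#' being corrected). Reads without a read-level QV are kept.
#'
#' @param reads tibble from [read_fastq()] or [simulate_library()]`$reads`.
#' @param wl a [whitelist()].
#' @param primers a [primer_set()].
#' @param config a [demux_config()].
#' @param feature_assignments optional tibble standing in for the external
#'   alignment + annotation-comparison step: `read_id`, `segment_index`,
#'   `gene_id`, `isoform_id`, `class_code`.
#' @return a `demux_result` list: `run` (see [demux_reads()]),
#'   `assignments` (QV-passing FLNC records with barcode assignment columns),
#'   `whitelist` (with observed counts), `report`, and - with features -
#'   `gene_matrix` and `isoform_matrix`.
#' @export
demultiplex <- function(reads, wl, primers = primer_set(),
                        config = demux_config(),
                        feature_assignments = NULL) {
  run <- demux_reads(reads, primers, config)
  flnc <- run$flnc
  pass <- is.na(flnc$read_qv) | flnc$read_qv >= config$qv_cutoff
  flnc <- flnc[pass, , drop = FALSE]
  wl <- count_whitelist_freq(flnc, wl)
  assignments <- correct_barcodes(flnc, wl, config$bc_threshold)
  out <- list(run = run, assignments = assignments, whitelist = wl,
              config = config)
  if (!is.null(feature_assignments)) {
    records <- assignments |>
      inner_join(feature_assignments, by = c("read_id", "segment_index"))
    out$gene_matrix <- build_gene_matrix(records, config)
    out$isoform_matrix <- build_isoform_matrix(
      records, config$min_umi_count, config$min_cells, config)
  }
  out$report <- run_report(run, assignments, config$qv_cutoff)
  structure(out, class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  print(x$run)
  n <- nrow(x$assignments)
  st <- table(factor(x$assignments$status,
                     levels = c("EXACT", "CORRECTED", "UNASSIGNED")))
  cat(sprintf("barcodes: %d QV-passing FLNC records; EXACT %d, CORRECTED %d, UNASSIGNED %d\n",
              n, st["EXACT"], st["CORRECTED"], st["UNASSIGNED"]))
  if (!is.null(x$gene_matrix)) {
    cat(sprintf("gene matrix: %d genes x %d cells; isoform matrix: %d x %d\n",
                nrow(x$gene_matrix), ncol(x$gene_matrix),
                nrow(x$isoform_matrix), ncol(x$isoform_matrix)))
  }
  invisible(x)
}
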