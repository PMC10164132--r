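#' Read long reads from FASTQ or FASTA
#'
#' Reads a (optionally gzipped) FASTQ or FASTA file into a tibble of long
#' reads. FASTA input is accepted as a degenerate case with qualities absent.
#' Qualities are kept as Phred+33 strings; a read-level quality value
#' (`read_qv`, predicted accuracy in `[0, 1]`) is derived from the mean
#' per-base error probability when qualities are present.
#'
#' @param path path to a FASTQ/FASTA file (`.gz` accepted).
#' @return a tibble with columns `read_id`, `sequence`, `qualities`
#'   (`NA` for FASTA) and `read_qv` (`NA` when qualities are absent).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- read_first_char(path)
  if (identical(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    return(tibble(
      read_id = sub("\\s.*$", "", names(ss)),
      sequence = unname(as.character(ss)),
      qualities = NA_character_,
      read_qv = NA_real_
    ))
  }
  # a light structural pre-check: Biostrings does not diagnose malformed
  # records itself, and the contract requires the record index in the error
  idx <- locate_bad_fastq_record(path)
  if (!is.na(idx)) {
    abort(paste0("malformed FASTQ record at record index ", idx, " in ", path))
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  quals <- unname(as.character(S4Vectors::mcols(ss)$qualities))
  tibble(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = unname(as.character(ss)),
    qualities = quals,
    read_qv = read_qv_from_quals(quals)
  )
}

read_first_char <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  ln <- readLines(con, n = 1L)
  if (length(ln) == 0) abort(paste0("empty input file: ", path))
  substr(ln, 1L, 1L)
}

# structural scan over 4-line FASTQ records; returns the index of the first
# malformed record, or NA when the file is well-formed
locate_bad_fastq_record <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  idx <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (length(rec) == 0) return(NA_integer_)
    idx <- idx + 1L
    if (length(rec) < 4L || !startsWith(rec[1], "@") ||
        !startsWith(rec[3], "+") || nchar(rec[2]) != nchar(rec[4]) ||
        grepl("[^ACGTNacgtn]", rec[2])) {
      return(idx)
    }
  }
}

read_qv_from_quals <- function(quals) {
  vapply(quals, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    1 - mean(10^(-(utf8ToInt(q) - 33) / 10))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write reads to FASTQ
#'
#' Reads lacking qualities are written with a uniform default Phred score
#' (30), the package-wide fallback wherever a quality is needed.
#'
#' @param reads tibble with `read_id`, `sequence` and optionally `qualities`.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param default_phred Phred score used when `qualities` is `NA`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, default_phred = 30L) {
  quals <- if ("qualities" %in% names(reads)) reads$qualities else
    rep(NA_character_, nrow(reads))
  miss <- is.na(quals)
  if (any(miss)) {
    quals[miss] <- vapply(nchar(reads$sequence[miss]), function(n) {
      strrep(intToUtf8(33L + default_phred), n)
    }, character(1))
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Load a cell-barcode whitelist
#'
#' One barcode per line, uniform length, A/C/G/T alphabet. Duplicate lines are
#' collapsed; observed-frequency counts are initialised to zero.
#'
#' @param path path to a plain-text whitelist file.
#' @return a `whitelist` tibble with columns `barcode` and `count`.
#' @export
load_whitelist <- function(path) {
  bc <- readLines(path)
  bc <- bc[nzchar(bc)]
  if (length(bc) == 0) abort("whitelist file contains no barcodes")
  whitelist(bc)
}

#' Construct a whitelist from barcodes
#'
#' @param barcodes character vector of same-length A/C/G/T barcodes.
#' @param counts optional non-negative observed frequencies, recycled to zero.
#' @return a `whitelist` tibble with columns `barcode` and `count`.
#' @export
whitelist <- function(barcodes, counts = 0L) {
  lens <- unique(nchar(barcodes))
  if (length(lens) != 1) {
    abort(paste0("whitelist barcodes have mixed lengths: ",
                 paste(sort(lens), collapse = ", ")))
  }
  if (any(grepl("[^ACGT]", barcodes))) {
    abort("whitelist barcodes contain non-ACGT characters")
  }
  wl <- tibble(barcode = barcodes, count = as.integer(counts)) |>
    distinct(.data$barcode, .keep_all = TRUE) |>
    arrange(.data$barcode)
  class(wl) <- c("whitelist", class(wl))
  wl
}

#' @export
print.whitelist <- function(x, ...) {
  cat("Cell-barcode whitelist:", nrow(x), "barcodes of length",
      nchar(x$barcode[1]), "\n")
  NextMethod()
}

#' Write a whitelist to disk
#' @param wl a `whitelist` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(wl, path) {
  writeLines(wl$barcode, path)
  invisible(path)
}

#' Demultiplexing configuration
#'
#' All tunable thresholds of the pipeline in one structured object. Defaults
#' follow the published tool settings where stated (`min_primerlen 16`,
#' `min_seqlen 50`, barcode posterior threshold 0.975, UMI base quality 10,
#' read-level QV cutoff 0.95) and declared package choices elsewhere
#' (`min_identity 0.9`; poly(A) window 10, A-fraction 0.8, minimum tail 10;
#' default Phred 30 for quality-less reads).
#'
#' @param min_primerlen minimum aligned primer length for a reported hit.
#' @param min_identity minimum primer alignment identity.
#' @param min_seqlen minimum transcript (insert) length for a segment/FLNC.
#' @param max_overlap maximum tolerated overlap (bases) between primer hits.
#' @param polya_window sliding window size for poly(A) detection.
#' @param polya_min_frac_a minimum A fraction per window.
#' @param min_polya_len minimum tail length for a poly(A) call.
#' @param bc_threshold posterior probability needed to correct a barcode.
#' @param qv_cutoff read-level QV below which records are excluded from
#'   barcode counting/assignment (set to 0 to disable).
#' @param umi_min_qual minimum per-base Phred score inside a UMI.
#' @param min_umi_count minimum distinct-UMI count for an isoform-matrix entry.
#' @param min_cells minimum number of cells an isoform must be detected in.
#' @param default_phred Phred score assumed for reads without qualities.
#' @return a `demux_config` list.
#' @export
demux_config <- function(min_primerlen = 16L, min_identity = 0.9,
                         min_seqlen = 50L, max_overlap = 5L,
                         polya_window = 10L, polya_min_frac_a = 0.8,
                         min_polya_len = 10L, bc_threshold = 0.975,
                         qv_cutoff = 0.95, umi_min_qual = 10L,
                         min_umi_count = 3L, min_cells = 5L,
                         default_phred = 30L) {
  cfg <- list(
    min_primerlen = as.integer(min_primerlen), min_identity = min_identity,
    min_seqlen = as.integer(min_seqlen), max_overlap = as.integer(max_overlap),
    polya_window = as.integer(polya_window),
    polya_min_frac_a = polya_min_frac_a,
    min_polya_len = as.integer(min_polya_len), bc_threshold = bc_threshold,
    qv_cutoff = qv_cutoff, umi_min_qual = as.integer(umi_min_qual),
    min_umi_count = as.integer(min_umi_count), min_cells = as.integer(min_cells),
    default_phred = as.integer(default_phred)
  )
  structure(cfg, class = "demux_config")
}

#' Read/write a demultiplexing configuration file (JSON key/value)
#'
#' @param path path of the JSON configuration file.
#' @return `read_demux_config()` returns a `demux_config`;
#'   `write_demux_config()` returns `path` invisibly.
#' @export
read_demux_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(demux_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(demux_config, vals)
}

#' @rdname read_demux_config
#' @param config a `demux_config` object.
#' @export
write_demux_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read/write tab-separated sidecar tables
#'
#' Thin readr wrappers used for every TSV the pipeline exchanges (FLNC
#' sidecars, barcode assignments, feature assignments, truth tables).
#'
#' @param path path to a TSV file.
#' @param col_types optional readr column specification.
#' @return `read_tsv_table()` returns a tibble; `write_tsv_table()` returns
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

#' @rdname read_tsv_table
#' @param x a data frame.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
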