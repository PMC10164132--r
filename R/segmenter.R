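#' Split reads into cDNA segments at primer boundaries
#'
#' Consecutive resolved primer hits delimit segments: one segment is emitted
#' for every maximal inter-primer interval whose interior length is at least
#' `min_seqlen`. Terminal labels record the flanking primer (id + strand, e.g.
#' `5p+`, `3p-`) or `NONE` at a read end without a primer. Residual
#' ligation-junction bases between back-to-back primers form intervals far
#' shorter than `min_seqlen` and are assigned to no segment.
#'
#' @param reads tibble with `read_id` and `sequence`.
#' @param hits resolved (non-conflicting, ordered) hits from [resolve_hits()].
#' @param min_seqlen minimum interior length of an emitted segment.
#' @return tibble: `read_id`, `segment_index` (1-based within read), `start`,
#'   `end` (0-based half-open interior coordinates), `left_terminal`,
#'   `right_terminal`.
#' @export
segment_reads <- function(reads, hits, min_seqlen = 50L) {
  lens <- setNames(nchar(reads$sequence), reads$read_id)
  empty <- tibble(read_id = character(), segment_index = integer(),
                  start = integer(), end = integer(),
                  left_terminal = character(), right_terminal = character())
  if (nrow(hits) > 0) {
    h <- hits |>
      mutate(label = paste0(ifelse(.data$primer_id == "P5", "5p", "3p"),
                            .data$strand)) |>
      arrange(match(.data$read_id, reads$read_id), .data$start)
    pre <- h |>
      group_by(.data$read_id) |>
      mutate(seg_start = lag(.data$end, default = 0L),
             seg_end = .data$start,
             left_terminal = lag(.data$label, default = "NONE"),
             right_terminal = .data$label) |>
      ungroup() |>
      select("read_id", start = "seg_start", end = "seg_end",
             "left_terminal", "right_terminal")
    tail_seg <- h |>
      group_by(.data$read_id) |>
      slice_tail(n = 1) |>
      ungroup() |>
      transmute(.data$read_id, start = .data$end,
                end = unname(lens[.data$read_id]),
                left_terminal = .data$label, right_terminal = "NONE")
  } else {
    pre <- tail_seg <- empty
  }
  nohit <- reads |>
    filter(!.data$read_id %in% hits$read_id) |>
    transmute(.data$read_id, start = 0L, end = nchar(.data$sequence),
              left_terminal = "NONE", right_terminal = "NONE")
  bind_rows(pre, tail_seg, nohit) |>
    filter(.data$end - .data$start >= min_seqlen) |>
    arrange(match(.data$read_id, reads$read_id), .data$start) |>
    group_by(.data$read_id) |>
    mutate(segment_index = row_number()) |>
    ungroup() |>
    select("read_id", "segment_index", "start", "end",
           "left_terminal", "right_terminal")
}

#' Trim a poly(A) tail with a sliding window
#'
#' Starting from the 3' end, a window of size `window` slides inward while its
#' A-fraction stays at or above `min_frac_a`; the candidate tail is the
#' maximal such extent (suffixes shorter than one window must themselves pass
#' the A-fraction rule), then retracted so that the innermost trimmed base is
#' an A. A tail shorter than `min_polya_len` is reported but `has_polya` is
#' `FALSE`.
#'
#' @param seq character vector of transcript-sense sequences (tail at 3' end).
#' @param window sliding window size.
#' @param min_frac_a minimum A fraction per window.
#' @param min_polya_len minimum tail length for a positive poly(A) call.
#' @return tibble: `sequence` (trimmed), `polya_len`, `has_polya`.
#' @export
#' @examples
#' trim_polya(paste0("ACGT", strrep("A", 30)))
trim_polya <- function(seq, window = 10L, min_frac_a = 0.8,
                       min_polya_len = 10L) {
  polya_len <- .trim_polya_cpp(seq, as.integer(window), min_frac_a)
  tibble(sequence = substr(seq, 1L, nchar(seq) - polya_len),
         polya_len = polya_len,
         has_polya = polya_len >= min_polya_len)
}

#' Classify cDNA segments as FLNC, NFL or artifact
#'
#' A segment is full-length non-chimeric (`FLNC`) only when its terminals are
#' a proper opposite-strand primer pair (`5p+`/`3p-` or `3p+`/`5p-`) *and* a
#' poly(A) tail, a complete 28 bp barcode+UMI block and a transcript of at
#' least `min_seqlen` bases are present. A segment with neither a 3'-primer
#' terminal nor a poly(A) signal is an `ARTIFACT` (the signature of
#' template-switching by-products); everything else is non-full-length
#' (`NFL`).
#'
#' @param left_terminal,right_terminal terminal labels
#'   (`5p+`, `5p-`, `3p+`, `3p-`, `NONE`).
#' @param has_polya logical; poly(A) tail of at least the minimum length.
#' @param has_bcumi logical; complete 28 bp barcode+UMI block recovered.
#' @param transcript_ok logical; trimmed transcript length >= `min_seqlen`.
#' @return character vector of categories (`FLNC`, `NFL`, `ARTIFACT`).
#' @export
classify_segments <- function(left_terminal, right_terminal, has_polya,
                              has_bcumi, transcript_ok = TRUE) {
  proper <- (left_terminal == "5p+" & right_terminal == "3p-") |
    (left_terminal == "3p+" & right_terminal == "5p-")
  has_3p <- left_terminal %in% c("3p+", "3p-") |
    right_terminal %in% c("3p+", "3p-")
  dplyr::case_when(
    proper & has_polya & has_bcumi & transcript_ok ~ "FLNC",
    !has_3p & !has_polya ~ "ARTIFACT",
    TRUE ~ "NFL"
  )
}

# which segments expose the barcode+UMI block inside their interior:
# P3 reading forward immediately left of the interior ("3p+" left terminal),
# or P3 on the minus strand immediately right of it ("3p-" right terminal).
extractable_3p <- function(left_terminal, right_terminal) {
  left_terminal == "3p+" | right_terminal == "3p-"
}

#' Orient segments and extract barcode, UMI and transcript
#'
#' Re-expresses each segment on the strand where the 3' primer reads forward;
#' the 16 bases immediately after the primer are the raw cell barcode and the
#' following 12 bases the raw UMI (base qualities carried along). The
#' remainder is re-complemented to transcript sense and the poly(A) tail is
#' trimmed with [trim_polya()]. Segments failing a requirement are returned
#' with a rejection reason (`BC_UMI_TRUNCATED`, `NO_POLYA`, `TOO_SHORT`)
#' instead of being dropped.
#'
#' @param reads tibble with `read_id`, `sequence`, optional `qualities` and
#'   `read_qv`.
#' @param segments segment rows (from [segment_reads()]) that all carry an
#'   extractable 3'-primer terminal; anything else is a contract violation.
#' @param primers a [primer_set()].
#' @param config a [demux_config()].
#' @return tibble: `read_id`, `segment_index`, `status` (`OK` or rejection
#'   reason), `transcript`, `transcript_qual`, `raw_barcode`, `bc_qual`,
#'   `raw_umi`, `umi_qual`, `polya_len`, `has_polya`, `read_qv`.
#' @export
extract_flnc <- function(reads, segments, primers = primer_set(),
                         config = demux_config()) {
  ok3p <- extractable_3p(segments$left_terminal, segments$right_terminal)
  if (!all(ok3p)) {
    abort("extract_flnc() called on a segment without a 3'-primer terminal")
  }
  quals <- if ("qualities" %in% names(reads)) reads$qualities else
    rep(NA_character_, nrow(reads))
  miss <- is.na(quals)
  quals[miss] <- strrep(intToUtf8(33L + config$default_phred),
                        nchar(reads$sequence[miss]))
  seq_of <- setNames(reads$sequence, reads$read_id)
  qual_of <- setNames(quals, reads$read_id)
  qv_of <- if ("read_qv" %in% names(reads)) {
    setNames(reads$read_qv, reads$read_id)
  } else {
    setNames(rep(NA_real_, nrow(reads)), reads$read_id)
  }

  sseq <- substr(seq_of[segments$read_id], segments$start + 1L, segments$end)
  squal <- substr(qual_of[segments$read_id], segments$start + 1L, segments$end)
  rc <- segments$left_terminal != "3p+"   # then right_terminal == "3p-"
  oriented <- ifelse(rc, revcomp(sseq), sseq)
  oqual <- ifelse(rc, str_rev(squal), squal)
  n <- nchar(oriented)
  blk <- primers$bc_len + primers$umi_len

  raw_barcode <- substr(oriented, 1L, primers$bc_len)
  bc_qual <- substr(oqual, 1L, primers$bc_len)
  raw_umi <- substr(oriented, primers$bc_len + 1L, blk)
  umi_qual <- substr(oqual, primers$bc_len + 1L, blk)
  rest <- substr(oriented, blk + 1L, n)
  restq <- substr(oqual, blk + 1L, n)
  transcript <- revcomp(rest)
  tqual <- str_rev(restq)

  tr <- trim_polya(transcript, config$polya_window, config$polya_min_frac_a,
                   config$min_polya_len)
  transcript_trim <- tr$sequence
  tqual_trim <- substr(tqual, 1L, nchar(tqual) - tr$polya_len)

  status <- dplyr::case_when(
    n < blk ~ "BC_UMI_TRUNCATED",
    !tr$has_polya ~ "NO_POLYA",
    nchar(transcript_trim) < config$min_seqlen ~ "TOO_SHORT",
    TRUE ~ "OK"
  )
  tibble(
    read_id = segments$read_id,
    segment_index = segments$segment_index,
    status = status,
    transcript = transcript_trim,
    transcript_qual = tqual_trim,
    raw_barcode = raw_barcode,
    bc_qual = bc_qual,
    raw_umi = raw_umi,
    umi_qual = umi_qual,
    polya_len = tr$polya_len,
    has_polya = tr$has_polya,
    read_qv = unname(qv_of[segments$read_id])
  )
}

# poly(A) signal at either end / strand of a segment that lacks an
# extractable 3' terminal (used only for the ARTIFACT/NFL distinction)
detect_polya_any <- function(seq, config) {
  fwd <- .trim_polya_cpp(seq, config$polya_window, config$polya_min_frac_a)
  rev <- .trim_polya_cpp(revcomp(seq), config$polya_window,
                         config$polya_min_frac_a)
  pmax(fwd, rev) >= config$min_polya_len
}

#' Demultiplex concatenated reads into classified cDNA segments
#'
#' Runs the segmentation half of the pipeline: primer scan, hit resolution,
#' segmentation, orientation, barcode/UMI extraction, poly(A) trimming and
#' FLNC/NFL/artifact classification.
#'
#' @param reads tibble from [read_fastq()] (or a simulator `reads` table).
#' @param primers a [primer_set()].
#' @param config a [demux_config()].
#' @return a list of class `demux_run`:
#'   `hits` (resolved primer hits), `segments` (all segments with `category`,
#'   `has_polya`, `has_bcumi`, `polya_len`), and `flnc` (one row per FLNC
#'   record with transcript, raw barcode/UMI, qualities and `read_qv`).
#' @export
demux_reads <- function(reads, primers = primer_set(),
                        config = demux_config()) {
  hits <- find_primer_hits(reads, primers, config$min_primerlen,
                           config$min_identity)
  hits <- resolve_hits(hits, config$max_overlap)
  segs <- segment_reads(reads, hits, config$min_seqlen)

  can_extract <- extractable_3p(segs$left_terminal, segs$right_terminal)
  ext <- extract_flnc(reads, segs[can_extract, , drop = FALSE], primers, config)

  has_polya <- logical(nrow(segs))
  has_bcumi <- logical(nrow(segs))
  transcript_ok <- logical(nrow(segs))
  polya_len <- integer(nrow(segs))
  has_polya[can_extract] <- ext$has_polya
  has_bcumi[can_extract] <- ext$status != "BC_UMI_TRUNCATED"
  transcript_ok[can_extract] <- ext$status == "OK"
  polya_len[can_extract] <- ext$polya_len
  if (any(!can_extract)) {
    sseq <- substr(setNames(reads$sequence, reads$read_id)[segs$read_id[!can_extract]],
                   segs$start[!can_extract] + 1L, segs$end[!can_extract])
    has_polya[!can_extract] <- detect_polya_any(sseq, config)
  }
  segs$category <- classify_segments(segs$left_terminal, segs$right_terminal,
                                     has_polya, has_bcumi, transcript_ok)
  segs$has_polya <- has_polya
  segs$has_bcumi <- has_bcumi
  segs$polya_len <- polya_len

  flnc_keys <- segs |>
    filter(.data$category == "FLNC") |>
    select("read_id", "segment_index")
  flnc <- ext |>
    inner_join(flnc_keys, by = c("read_id", "segment_index")) |>
    select(-"status")
  structure(list(hits = hits, segments = segs, flnc = flnc),
            class = "demux_run")
}

#' @export
print.demux_run <- function(x, ...) {
  tab <- table(factor(x$segments$category,
                      levels = c("FLNC", "NFL", "ARTIFACT")))
  cat("demux_run:", length(unique(x$segments$read_id)), "reads,",
      nrow(x$segments), "cDNA segments\n")
  cat(sprintf("  FLNC %d (%.2f%%)  NFL %d (%.2f%%)  ARTIFACT %d (%.2f%%)\n",
              tab[1], 100 * tab[1] / nrow(x$segments),
              tab[2], 100 * tab[2] / nrow(x$segments),
              tab[3], 100 * tab[3] / nrow(x$segments)))
  invisible(x)
}

#' Write FLNC records to FASTQ plus a TSV sidecar
#'
#' @param run a `demux_run` from [demux_reads()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_flnc <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fl <- run$flnc
  write_fastq(tibble(read_id = paste0(fl$read_id, "/", fl$segment_index),
                     sequence = fl$transcript,
                     qualities = fl$transcript_qual),
              file.path(dir, "flnc.fastq"))
  sidecar <- run$segments |>
    left_join(fl |> select("read_id", "segment_index", "raw_barcode",
                           "raw_umi", "polya_len", "read_qv"),
              by = c("read_id", "segment_index"),
              suffix = c("", ".flnc"))
  write_tsv_table(sidecar, file.path(dir, "segments.tsv"))
  invisible(dir)
}
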