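#' cDNA primer set
#'
#' The 5' and 3' cDNA PCR primers, the ligation-junction sequence left between
#' concatenated units, and the barcode/UMI geometry. Uracil (`U`) in configured
#' sequences is mapped to `T` on load: the synthesised oligos carry
#' deoxyuracil at the junction but sequenced molecules contain T.
#'
#' @param p5 5' primer sequence (template-switch oligo side).
#' @param p3 3' primer sequence (oligo-dT side; the 16 bp cell barcode and
#'   12 bp UMI follow it on the barcode strand).
#' @param junction ligation junction sequence between concatenated units.
#' @param bc_len cell barcode length (bases).
#' @param umi_len UMI length (bases).
#' @return a `primer_set` list.
#' @export
#' @examples
#' primer_set()
primer_set <- function(p5 = "AAGCAGTGGTATCAACGCAGAG",
                       p3 = "CTACACGACGCTCTTCCGATCT",
                       junction = "ACTAGT",
                       bc_len = 16L, umi_len = 12L) {
  clean <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))
  p5 <- clean(p5); p3 <- clean(p3); junction <- clean(junction)
  if (identical(p5, p3)) abort("p5 and p3 primers must differ")
  if (bc_len + umi_len != 28L) {
    abort("bc_len + umi_len must equal 28 (the trimmed barcode+UMI block)")
  }
  structure(list(p5 = p5, p3 = p3, junction = junction,
                 bc_len = as.integer(bc_len), umi_len = as.integer(umi_len)),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat("primer_set\n  p5:", x$p5, "\n  p3:", x$p3,
      "\n  junction:", x$junction,
      sprintf("\n  barcode %d bp + UMI %d bp\n", x$bc_len, x$umi_len))
  invisible(x)
}

# alignment scoring shared by the scanner and the test oracle
SW_MATCH <- 1L
SW_MISMATCH <- -1L
SW_GAP <- -2L

#' Locate primer hits on reads
#'
#' Seed-and-extend local alignment (seed length 5, matching the word size of
#' the external aligner the pipeline replaces) of both primers against both
#' strands of every read, rescored with Smith-Waterman (match +1, mismatch -1,
#' gap -2). Reverse-strand occurrences are reported in the read's coordinate
#' frame. Coordinates are 0-based, half-open.
#'
#' @param reads tibble with `read_id` and `sequence` (as from [read_fastq()]),
#'   or a character vector of sequences.
#' @param primers a [primer_set()].
#' @param min_primerlen minimum alignment length for a reported hit.
#' @param min_identity minimum `matches / aligned_len` for a reported hit.
#' @return tibble of hits: `read_id`, `primer_id` (`P5`/`P3`), `strand`
#'   (`+`/`-`), `start`, `end`, `matches`, `aligned_len`, `identity`, `score`,
#'   ordered by read and ascending `start`.
#' @export
find_primer_hits <- function(reads, primers = primer_set(),
                             min_primerlen = 16L, min_identity = 0.9) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)),
                    sequence = reads)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (any(!nzchar(reads$sequence))) abort("empty read sequence")
  scan_seqs <- c(primers$p5, revcomp(primers$p5),
                 primers$p3, revcomp(primers$p3))
  key <- tibble(primer = 1:4,
                primer_id = c("P5", "P5", "P3", "P3"),
                strand = c("+", "-", "+", "-"))
  raw <- .scan_primers_cpp(reads$sequence, scan_seqs,
                           seed_len = 5L, min_len = as.integer(min_primerlen),
                           min_identity = min_identity,
                           match = SW_MATCH, mismatch = SW_MISMATCH,
                           gap = SW_GAP)
  as_tibble(raw) |>
    left_join(key, by = "primer") |>
    mutate(read_id = reads$read_id[.data$read],
           identity = .data$matches / .data$aligned_len) |>
    select("read_id", "primer_id", "strand", "start", "end",
           "matches", "aligned_len", "identity", "score") |>
    arrange(match(.data$read_id, reads$read_id), .data$start, .data$end,
            .data$primer_id, .data$strand)
}

#' Resolve conflicting primer hits
#'
#' Among hits on one read that overlap by more than `max_overlap` bases, only
#' the highest-scoring hit survives; score order is `matches`, then
#' `identity`, then leftmost `start` (a deterministic greedy rule).
#'
#' @param hits tibble as returned by [find_primer_hits()].
#' @param max_overlap overlaps of at most this many bases are tolerated.
#' @return tibble of non-conflicting hits, sorted by read and `start`.
#' @export
resolve_hits <- function(hits, max_overlap = 5L) {
  if (nrow(hits) == 0) return(hits)
  st <- hits$start; en <- hits$end; mt <- hits$matches; idt <- hits$identity
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$read_id), function(ix) {
    ord <- ix[order(-mt[ix], -idt[ix], st[ix])]
    acc <- integer(0)
    for (i in ord) {
      if (length(acc) == 0 ||
          all(pmin(en[acc], en[i]) - pmax(st[acc], st[i]) <= max_overlap)) {
        acc <- c(acc, i)
      }
    }
    acc
  }), use.names = FALSE)
  hits[sort(keep), ] |>
    arrange(match(.data$read_id, unique(hits$read_id)), .data$start)
}
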