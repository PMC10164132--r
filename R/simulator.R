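#' Simulation configuration for synthetic concatemer libraries
#'
#' The generator emulates the concatenated-cDNA library structure: each
#' full-length unit is `p5 + transcript + polyA + revcomp(UMI) +
#' revcomp(barcode) + revcomp(p3)`; template-switching artifact units carry
#' 5'-primer-type terminals on both sides and no poly(A)/barcode/UMI; units
#' are joined by the ligation junction with an independent 50/50 orientation
#' flip per unit. Per-base substitutions/insertions/deletions are applied
#' i.i.d.; emitted base qualities reflect the substitution rate
#' (`Phred = -10 log10(max(sub_rate, 1e-4))` with small jitter) and the
#' read-level QV is `1 - observed per-read error fraction`.
#'
#' @param n_reads number of concatemer reads.
#' @param n_cells number of simulated cells (drawn from the whitelist).
#' @param whitelist_size whitelist size; members are mutually >= 3
#'   substitutions apart so 1-substitution correction is unambiguous.
#' @param spike_in_barcode barcode of the spike-in "known cell"; it is kept
#'   off the whitelist but the whitelist contains a member at edit distance 1
#'   from it (the deliberately hard case).
#' @param spike_in_fraction fraction of full-length units carrying the
#'   spike-in barcode (0 disables spiking).
#' @param units_per_read integer set of allowed units per read, sampled
#'   uniformly.
#' @param artifact_fraction fraction of units that are TSO artifacts (about
#'   0.08 for capture-cleaned libraries; about 0.5 for uncleaned ones).
#' @param transcript_len_mean,transcript_len_sd,transcript_len_min gamma
#'   transcript-length model for the toy transcriptome (desk-scaled).
#' @param polya_mean mean (Poisson) poly(A) tail length.
#' @param sub_rate,ins_rate,del_rate per-base error rates.
#' @param n_genes,max_isoforms_per_gene toy transcriptome size.
#' @param seed integer seed fixing the entire output byte-for-byte.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_reads = 1000L, n_cells = 100L,
                       whitelist_size = 1000L,
                       spike_in_barcode = "AAGTCCTTCCAGTCTT",
                       spike_in_fraction = 0,
                       units_per_read = c(3L, 4L),
                       artifact_fraction = 0.08,
                       transcript_len_mean = 500, transcript_len_sd = 200,
                       transcript_len_min = 60L,
                       polya_mean = 30,
                       sub_rate = 0.005, ins_rate = 0.001, del_rate = 0.001,
                       n_genes = 60L, max_isoforms_per_gene = 3L,
                       seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate, artifact_fraction,
             spike_in_fraction)
  if (any(rates < 0 | rates > 1)) abort("rates/fractions must lie in [0, 1]")
  if (n_cells > whitelist_size) abort("n_cells exceeds whitelist_size")
  structure(list(
    n_reads = as.integer(n_reads), n_cells = as.integer(n_cells),
    whitelist_size = as.integer(whitelist_size),
    spike_in_barcode = spike_in_barcode,
    spike_in_fraction = spike_in_fraction,
    units_per_read = as.integer(units_per_read),
    artifact_fraction = artifact_fraction,
    transcript_len_mean = transcript_len_mean,
    transcript_len_sd = transcript_len_sd,
    transcript_len_min = as.integer(transcript_len_min),
    polya_mean = polya_mean,
    sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
    n_genes = as.integer(n_genes),
    max_isoforms_per_gene = as.integer(max_isoforms_per_gene),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# generate `size` barcodes mutually >= min_dist substitutions apart;
# `fixed` barcodes are pre-accepted, `avoid` sequences must also be
# >= min_dist away from every new member
spaced_barcodes <- function(size, len = 16L, min_dist = 3L,
                            fixed = character(0), avoid = character(0),
                            max_tries = 60L) {
  acc_mat <- NULL
  add_rows <- function(mat, s) rbind(mat, t(vapply(s, utf8ToInt, integer(len))))
  accepted <- fixed
  if (length(c(fixed, avoid)) > 0) acc_mat <- add_rows(NULL, c(fixed, avoid))
  tries <- 0L
  while (length(accepted) < size) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("cannot satisfy whitelist spacing constraint at this size")
    }
    cand <- unique(random_dna(2L * (size - length(accepted)), len))
    for (b in cand) {
      if (length(accepted) >= size) break
      v <- utf8ToInt(b)
      if (!is.null(acc_mat)) {
        d <- rowSums(acc_mat != matrix(v, nrow(acc_mat), len, byrow = TRUE))
        if (min(d) < min_dist) next
      }
      accepted <- c(accepted, b)
      acc_mat <- add_rows(acc_mat, b)
    }
  }
  accepted
}

rand_kmers <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

make_transcriptome <- function(cfg) {
  n_iso <- sample.int(cfg$max_isoforms_per_gene, cfg$n_genes, replace = TRUE)
  gene_id <- rep(sprintf("G%04d", seq_len(cfg$n_genes)), n_iso)
  isoform_id <- paste0(gene_id, ".I",
                       sequence(n_iso))
  spike_gene <- sprintf("SPIKE%d", 1:7)
  gene_id <- c(gene_id, spike_gene)
  isoform_id <- c(isoform_id, paste0(spike_gene, ".I1"))
  n <- length(gene_id)
  shape <- (cfg$transcript_len_mean / cfg$transcript_len_sd)^2
  rate <- cfg$transcript_len_mean / cfg$transcript_len_sd^2
  len <- pmax(cfg$transcript_len_min, as.integer(round(rgamma(n, shape, rate))))
  # the last three bases are non-A so the poly(A) boundary is identifiable:
  # the sliding window can overrun a tail by at most two bases and the
  # retraction step then restores the exact boundary
  seqs <- vapply(len, function(L) {
    paste(c(sample(DNA_BASES, L - 3, replace = TRUE),
            sample(c("C", "G", "T"), 3, replace = TRUE)), collapse = "")
  }, character(1))
  tibble(gene_id = gene_id, isoform_id = isoform_id,
         length = len, sequence = seqs,
         spike = gene_id %in% spike_gene)
}

#' Simulate a concatenated single-cell isoform library with ground truth
#'
#' @param cfg a [sim_config()].
#' @param primers a [primer_set()].
#' @return a `sim_library` list: `reads` (tibble ready for [demux_reads()]),
#'   `truth_units` (one row per simulated cDNA unit, including pre-error
#'   `unit_start`/`unit_end` read coordinates for truth matching),
#'   `truth_features` (per-unit gene/isoform assignment, class code `=`),
#'   `whitelist`, `transcriptome` and the `config`.
#' @export
simulate_library <- function(cfg = sim_config(), primers = primer_set()) {
  with_seed(cfg$seed, {
    spiking <- cfg$spike_in_fraction > 0
    if (spiking) {
      pos <- sample.int(nchar(cfg$spike_in_barcode), 1L)
      cur <- substr(cfg$spike_in_barcode, pos, pos)
      neighbour <- cfg$spike_in_barcode
      substr(neighbour, pos, pos) <- sample(setdiff(DNA_BASES, cur), 1L)
      wl_bc <- spaced_barcodes(cfg$whitelist_size, nchar(cfg$spike_in_barcode),
                               fixed = neighbour,
                               avoid = cfg$spike_in_barcode)
    } else {
      neighbour <- NA_character_
      wl_bc <- spaced_barcodes(cfg$whitelist_size, 16L)
    }
    wl <- whitelist(wl_bc)
    cells <- sample(setdiff(wl_bc, neighbour), cfg$n_cells)
    txome <- make_transcriptome(cfg)
    main_iso <- which(!txome$spike)
    spike_iso <- which(txome$spike)

    n_units <- if (length(cfg$units_per_read) == 1) {
      rep(cfg$units_per_read, cfg$n_reads)
    } else {
      sample(cfg$units_per_read, cfg$n_reads, replace = TRUE)
    }
    U <- sum(n_units)
    read_idx <- rep(seq_len(cfg$n_reads), n_units)
    unit_index <- sequence(n_units)

    is_artifact <- runif(U) < cfg$artifact_fraction
    is_spike <- !is_artifact & runif(U) < cfg$spike_in_fraction
    iso <- integer(U)
    iso[!is_spike] <- sample(main_iso, sum(!is_spike), replace = TRUE)
    if (any(is_spike)) {
      iso[is_spike] <- sample(spike_iso, sum(is_spike), replace = TRUE)
    }
    barcode <- rep(NA_character_, U)
    expected <- rep(NA_character_, U)
    umi <- rep(NA_character_, U)
    flnc <- !is_artifact
    cell_pick <- sample(cells, sum(flnc & !is_spike), replace = TRUE)
    barcode[flnc & !is_spike] <- cell_pick
    expected[flnc & !is_spike] <- cell_pick
    barcode[is_spike] <- cfg$spike_in_barcode
    expected[is_spike] <- neighbour
    umi[flnc] <- rand_kmers(sum(flnc), 12L)
    # floor 12: a designed full-length unit must carry a detectable tail
    # (Poisson(30) dips below the 10-base minimum ~1 in 1e5 draws)
    polya <- pmax(12L, as.integer(rpois(U, cfg$polya_mean)))
    polya[is_artifact] <- 0L

    tseq <- txome$sequence[iso]
    unit_seq <- character(U)
    unit_seq[flnc] <- paste0(primers$p5, tseq[flnc],
                             strrep("A", polya[flnc]),
                             revcomp(umi[flnc]), revcomp(barcode[flnc]),
                             revcomp(primers$p3))
    unit_seq[is_artifact] <- paste0(primers$p5, tseq[is_artifact],
                                    revcomp(primers$p5))
    flipped <- runif(U) < 0.5
    unit_out <- unit_seq
    unit_out[flipped] <- revcomp(unit_seq[flipped])

    ulen <- nchar(unit_out)
    jlen <- nchar(primers$junction)
    offset <- stats::ave(ulen, read_idx, FUN = function(x) cumsum(x) - x)
    unit_start <- offset + (unit_index - 1L) * jlen
    unit_end <- unit_start + ulen

    read_seq <- vapply(split(unit_out, read_idx), paste,
                       character(1), collapse = primers$junction)
    mean_q <- -10 * log10(max(cfg$sub_rate, 1e-4))
    mut <- .mutate_seqs_cpp(unname(read_seq), cfg$sub_rate, cfg$ins_rate,
                            cfg$del_rate, mean_q)
    read_id <- sprintf("sim%06d", seq_len(cfg$n_reads))
    reads <- tibble(
      read_id = read_id,
      sequence = mut$sequence,
      qualities = mut$qualities,
      read_qv = 1 - mut$n_errors / nchar(unname(read_seq))
    )
    truth_units <- tibble(
      read_id = read_id[read_idx],
      unit_index = unit_index,
      unit_type = ifelse(is_artifact, "TSO_ARTIFACT", "FLNC"),
      is_spike = is_spike,
      barcode = barcode,
      expected_barcode = expected,
      umi = umi,
      gene_id = ifelse(is_artifact, NA_character_, txome$gene_id[iso]),
      isoform_id = ifelse(is_artifact, NA_character_, txome$isoform_id[iso]),
      transcript_length = txome$length[iso],
      polya_length = polya,
      flipped = flipped,
      unit_start = unit_start,
      unit_end = unit_end
    )
    truth_features <- truth_units |>
      filter(.data$unit_type == "FLNC") |>
      transmute(.data$read_id, segment_index = .data$unit_index,
                .data$gene_id, .data$isoform_id, class_code = "=")
    structure(list(reads = reads, truth_units = truth_units,
                   truth_features = truth_features, whitelist = wl,
                   transcriptome = txome,
                   spike_whitelist_neighbour = neighbour,
                   config = cfg),
              class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", nrow(x$reads), "reads,", nrow(x$truth_units),
      "cDNA units,", nrow(x$whitelist), "whitelist barcodes\n")
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Emits `reads.fastq(.gz)`, `truth_units.tsv`, `truth_features.tsv` and
#' `whitelist.txt`.
#'
#' @param sim a `sim_library` from [simulate_library()].
#' @param dir output directory (created if needed).
#' @param gzip compress the FASTQ.
#' @return `dir`, invisibly.
#' @export
write_sim_library <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads,
              file.path(dir, if (gzip) "reads.fastq.gz" else "reads.fastq"))
  write_tsv_table(sim$truth_units, file.path(dir, "truth_units.tsv"))
  write_tsv_table(sim$truth_features, file.path(dir, "truth_features.tsv"))
  write_whitelist(sim$whitelist, file.path(dir, "whitelist.txt"))
  invisible(dir)
}
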