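ps <- primer_set()

test_that("an error-free two-unit concatemer yields two FLNC segments", {
  set.seed(21)
  bc <- rand_seq(16); umi <- rand_seq(12)
  t1 <- paste0(rand_seq(97), "CGT")
  t2 <- paste0(rand_seq(137), "GTC")
  u1 <- make_unit(ps, t1, bc, umi)
  u2 <- make_unit(ps, t2, bc, umi)
  read <- tibble::tibble(read_id = "cc1",
                         sequence = paste0(u1, ps$junction, revcomp(u2)))
  run <- demux_reads(read)
  segs <- run$segments
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$category, c("FLNC", "FLNC"))
  # forward unit reads (5p+, 3p-); the flipped unit (3p+, 5p-)
  expect_equal(segs$left_terminal, c("5p+", "3p+"))
  expect_equal(segs$right_terminal, c("3p-", "5p-"))
  # identical records regardless of unit orientation in the concatemer
  expect_equal(run$flnc$raw_barcode, c(bc, bc))
  expect_equal(run$flnc$raw_umi, c(umi, umi))
  expect_equal(run$flnc$transcript, c(t1, t2))
  expect_equal(run$flnc$polya_len, c(30L, 30L))
})

test_that("a lone 5' primer at position 0 leaves one (5p+, NONE) segment", {
  set.seed(22)
  read <- tibble::tibble(read_id = "r",
                         sequence = paste0(ps$p5, rand_seq(120)))
  hits <- resolve_hits(find_primer_hits(read, ps))
  segs <- segment_reads(read, hits)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$left_terminal, "5p+")
  expect_equal(segs$right_terminal, "NONE")
  expect_equal(segs$start, 22L)
})

test_that("short inter-primer intervals (junction residue) are dropped", {
  set.seed(23)
  read <- tibble::tibble(
    read_id = "r",
    sequence = paste0(ps$p5, rand_seq(80), revcomp(ps$p3), ps$junction,
                      ps$p5, rand_seq(90), revcomp(ps$p3)))
  hits <- resolve_hits(find_primer_hits(read, ps))
  segs <- segment_reads(read, hits)
  # the 6-base junction interval between the back-to-back primers vanishes
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$end - segs$start, c(80L, 90L))
})

test_that("poly(A) trimming matches its specification cases", {
  out <- trim_polya(paste0("ACGT", strrep("A", 30)))
  expect_equal(out$sequence, "ACGT")
  expect_equal(out$polya_len, 30L)
  expect_true(out$has_polya)

  # one interruption inside the tail: the whole tail is trimmed
  seq2 <- paste0("TCCGTCCGTC", strrep("A", 14), "G", strrep("A", 15))
  out2 <- trim_polya(seq2)
  expect_equal(out2$polya_len, 30L)
  expect_equal(out2$sequence, "TCCGTCCGTC")

  out3 <- trim_polya("TTTGCAACGTCG")
  expect_equal(out3$polya_len, 0L)
  expect_false(out3$has_polya)
})

test_that("poly(A) extent equals the brute-force suffix oracle", {
  set.seed(24)
  seqs <- character(0)
  for (i in 1:120) {
    # A-rich tails with random interruptions appended to random sequence
    tail_len <- sample(0:40, 1)
    tail <- sample(c("A", "C", "G", "T"), tail_len, replace = TRUE,
                   prob = c(0.85, 0.05, 0.05, 0.05))
    seqs <- c(seqs, paste0(rand_seq(sample(5:40, 1)),
                           paste(tail, collapse = "")))
  }
  got <- trim_polya(seqs)$polya_len
  ref <- vapply(seqs, oracle_polya, integer(1), USE.NAMES = FALSE)
  expect_equal(got, ref)
})

test_that("segment classification follows the terminal/poly(A) rules", {
  expect_equal(classify_segments("5p+", "3p-", TRUE, TRUE, TRUE), "FLNC")
  expect_equal(classify_segments("3p+", "5p-", TRUE, TRUE, TRUE), "FLNC")
  expect_equal(classify_segments("5p+", "5p-", FALSE, FALSE, FALSE), "ARTIFACT")
  expect_equal(classify_segments("5p+", "3p-", FALSE, TRUE, TRUE), "NFL")
  expect_equal(classify_segments("NONE", "3p-", TRUE, TRUE, TRUE), "NFL")
  expect_equal(classify_segments("NONE", "NONE", TRUE, FALSE, TRUE), "NFL")
  expect_equal(classify_segments("NONE", "NONE", FALSE, FALSE, TRUE), "ARTIFACT")
})

test_that("extraction recovers truth and rejects truncated blocks", {
  set.seed(25)
  bc <- rand_seq(16); umi <- rand_seq(12)
  tx <- paste0(rand_seq(77), "GCT")
  unit <- make_unit(ps, tx, bc, umi)
  for (flip in c(FALSE, TRUE)) {
    seq <- if (flip) revcomp(unit) else unit
    read <- tibble::tibble(read_id = "r", sequence = seq)
    run <- demux_reads(read)
    expect_equal(run$flnc$raw_barcode, bc)
    expect_equal(run$flnc$raw_umi, umi)
    expect_equal(run$flnc$transcript, tx)
  }
  # fewer than 28 bases after the 3' primer: BC_UMI_TRUNCATED
  short <- paste0(ps$p5, rand_seq(20), revcomp(ps$p3))
  read <- tibble::tibble(read_id = "r", sequence = short)
  seg <- tibble::tibble(read_id = "r", segment_index = 1L,
                        start = 22L, end = 42L,
                        left_terminal = "5p+", right_terminal = "3p-")
  ext <- extract_flnc(read, seg, ps)
  expect_equal(ext$status, "BC_UMI_TRUNCATED")
  # calling extraction without a 3' terminal violates the contract
  seg_no3p <- seg
  seg_no3p$right_terminal <- "NONE"
  expect_error(extract_flnc(read, seg_no3p, ps), "3'-primer terminal")
})

test_that("error-free simulation round-trips exactly", {
  sim <- simulate_library(sim_config(n_reads = 150, sub_rate = 0,
                                     ins_rate = 0, del_rate = 0, seed = 7))
  run <- demux_reads(sim$reads)
  tu <- sim$truth_units
  # segment count per read equals simulator truth for every read
  expect_equal(nrow(run$segments), nrow(tu))
  seg_n <- table(run$segments$read_id)
  tru_n <- table(tu$read_id)
  expect_true(all(seg_n[names(tru_n)] == tru_n))
  # category partition matches truth
  joined <- dplyr::inner_join(run$segments, tu,
                              by = c("read_id", segment_index = "unit_index"))
  expect_equal(nrow(joined), nrow(tu))
  expect_equal(joined$category == "ARTIFACT",
               joined$unit_type == "TSO_ARTIFACT")
  # FLNC payloads equal truth exactly
  fl <- dplyr::inner_join(run$flnc, tu,
                          by = c("read_id", segment_index = "unit_index"))
  expect_equal(fl$raw_barcode, fl$barcode)
  expect_equal(fl$raw_umi, fl$umi)
  expect_equal(fl$polya_len, fl$polya_length)
  expect_equal(nchar(fl$transcript), fl$transcript_length)
  # FLNC + NFL + ARTIFACT partitions all segments
  expect_equal(sum(table(run$segments$category)), nrow(run$segments))
})

test_that("demultiplexing is invariant under reverse-complementing reads", {
  sim <- simulate_library(sim_config(n_reads = 60, seed = 8))
  fwd <- demux_reads(sim$reads)
  rc_reads <- sim$reads
  rc_reads$sequence <- revcomp(rc_reads$sequence)
  rc_reads$qualities <- vapply(rc_reads$qualities, function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, character(1), USE.NAMES = FALSE)
  rev <- demux_reads(rc_reads)
  key <- function(run) {
    dplyr::arrange(run$flnc[c("read_id", "transcript", "raw_barcode",
                              "raw_umi", "polya_len")],
                   .data$read_id, .data$transcript, .data$raw_umi)
  }
  expect_equal(key(fwd), key(rev))
  expect_equal(table(fwd$segments$category), table(rev$segments$category))
})
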