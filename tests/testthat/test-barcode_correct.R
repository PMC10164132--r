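wl3 <- whitelist(c("AAAACCCCGGGGTTTT", "CCCCGGGGTTTTAAAA", "GGGGTTTTAAAACCCC"))
q30 <- strrep(intToUtf8(33 + 30), 16)

test_that("whitelist frequencies count exact matches only", {
  recs <- tibble::tibble(
    raw_barcode = c(rep("AAAACCCCGGGGTTTT", 7), rep("CCCCGGGGTTTTAAAA", 3),
                    "TAAACCCCGGGGTTTT"))   # Hamming 1 from the first: ignored
  wl <- count_whitelist_freq(recs, wl3)
  expect_equal(setNames(wl$count, wl$barcode)[c(
    "AAAACCCCGGGGTTTT", "CCCCGGGGTTTTAAAA", "GGGGTTTTAAAACCCC")],
    c(AAAACCCCGGGGTTTT = 7L, CCCCGGGGTTTTAAAA = 3L, GGGGTTTTAAAACCCC = 0L))
})

test_that("exact whitelist barcodes are confirmed unchanged", {
  out <- correct_barcode("AAAACCCCGGGGTTTT", rep(30L, 16), wl3)
  expect_equal(out$status, "EXACT")
  expect_equal(out$corrected_barcode, "AAAACCCCGGGGTTTT")
})

test_that("a single Hamming-1 candidate normalises to posterior 1", {
  out <- correct_barcode("TAAACCCCGGGGTTTT", rep(30L, 16), wl3)
  expect_equal(out$status, "CORRECTED")
  expect_equal(out$corrected_barcode, "AAAACCCCGGGGTTTT")
  expect_equal(out$posterior, 1.0)
})

test_that("posterior arithmetic matches the stated formula exactly", {
  # two candidates differing at the same-quality base; priors decide
  wl <- whitelist(c("AAAAAAAAAAAAAAAA", "CAAAAAAAAAAAAAAA"),
                  counts = c(99L, 1L))
  raw <- "GAAAAAAAAAAAAAAA"   # Hamming 1 from both, differing at position 1
  out <- correct_barcode(raw, rep(30L, 16), wl)
  # posterior of the count-99 candidate = (99+1) / (99+1 + 1+1) = 100/102
  expect_equal(out$posterior, 100 / 102, tolerance = 1e-9)
  expect_equal(out$status, "CORRECTED")
  expect_equal(out$corrected_barcode, "AAAAAAAAAAAAAAAA")

  wl2 <- whitelist(c("AAAAAAAAAAAAAAAA", "CAAAAAAAAAAAAAAA"),
                   counts = c(60L, 40L))
  out2 <- correct_barcode(raw, rep(30L, 16), wl2)
  expect_equal(out2$posterior, 61 / 102, tolerance = 1e-9)
  expect_equal(out2$status, "UNASSIGNED")
  expect_true(is.na(out2$corrected_barcode))
})

test_that("base quality at the differing position weights the posterior", {
  wl <- whitelist(c(strrep("A", 16), paste0("CC", strrep("A", 14))),
                  counts = c(5L, 5L))
  # raw differs from candidate 1 at position 1 (q=40) and from candidate 2 at
  # position 2 (q=10): the sequencing error is far likelier at the q=10 base
  raw <- paste0("CA", strrep("A", 14))
  quals <- c(40L, 10L, rep(30L, 14))
  out <- correct_barcode(raw, quals, wl)
  # score1 = 0.5 * 10^-4, score2 = 0.5 * 10^-1
  expect_equal(out$posterior, 0.1 / (0.1 + 1e-4), tolerance = 1e-9)
  expect_equal(out$corrected_barcode, paste0("CC", strrep("A", 14)))
})

test_that("no candidate or ties leave the barcode unassigned", {
  out <- correct_barcode("TTTTTTTTTTTTTTTT", rep(30L, 16), wl3)
  expect_equal(out$status, "UNASSIGNED")
  # a perfect two-way tie can never exceed the threshold
  wl <- whitelist(c("AAAAAAAAAAAAAAAA", "CAAAAAAAAAAAAAAA"), counts = c(5L, 5L))
  out2 <- correct_barcode("GAAAAAAAAAAAAAAA", rep(30L, 16), wl)
  expect_equal(out2$status, "UNASSIGNED")
  expect_equal(out2$posterior, 0.5)
})

test_that("corrections never leave the whitelist", {
  set.seed(31)
  wl_bc <- unique(replicate(400, rand_seq(16)))
  wl <- whitelist(wl_bc, counts = sample(0:50, length(wl_bc), replace = TRUE))
  raws <- c(sample(wl_bc, 50),
            vapply(sample(wl_bc, 100, replace = TRUE), function(b) {
              mutate_bases(b, sample(16, 1))
            }, character(1), USE.NAMES = FALSE),
            replicate(50, rand_seq(16)))
  recs <- tibble::tibble(raw_barcode = raws, bc_qual = strrep("?", 16))
  out <- correct_barcodes(recs, wl, threshold = 0)
  assigned <- !is.na(out$corrected_barcode)
  expect_true(all(out$corrected_barcode[assigned] %in% wl_bc))
  expect_true(all(out$status[out$raw_barcode %in% wl_bc] == "EXACT"))
})

test_that("indexed Hamming-1 lookup equals a whole-whitelist scan", {
  set.seed(32)
  wl_bc <- unique(replicate(2000, rand_seq(16)))
  for (raw in c(replicate(30, rand_seq(16)),
                vapply(sample(wl_bc, 30), function(b) {
                  mutate_bases(b, sample(16, 1))
                }, character(1), USE.NAMES = FALSE))) {
    got <- sort(scisodemux:::hamming1_candidates(raw, wl_bc)$candidate)
    ref <- sort(oracle_hamming1(raw, wl_bc))
    expect_equal(got, ref)
  }
})

test_that("length mismatches are rejected", {
  expect_error(
    correct_barcodes(tibble::tibble(raw_barcode = "ACGT", bc_qual = "IIII"),
                     wl3),
    "length")
})
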