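# Independent oracles and small fixture builders used across the suite.
# Each oracle is written without reference to the package's own code paths.

# best local alignment of primer vs read under the package's scoring
# (match +1, mismatch -1, linear gap -2), via Biostrings as an independent
# reference implementation
oracle_best_local <- function(read, primer) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(pattern = primer, subject = read,
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  list(score = Biostrings::score(pa),
       start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       end = Biostrings::end(Biostrings::subject(pa)),
       matches = Biostrings::nmatch(pa),
       width = Biostrings::nchar(pa))
}

# greedy maximum-score non-conflicting hit subset (matches, identity,
# leftmost), written as a plain row loop over a data frame
oracle_resolve <- function(h, max_overlap = 5L) {
  h <- h[order(-h$matches, -h$identity, h$start), ]
  acc <- h[0, ]
  for (r in seq_len(nrow(h))) {
    row <- h[r, ]
    if (nrow(acc) == 0) { acc <- row; next }
    ov <- pmin(acc$end, row$end) - pmax(acc$start, row$start)
    if (all(ov <= max_overlap)) acc <- rbind(acc, row)
  }
  acc[order(acc$start), ]
}

# exhaustive suffix maximisation for the poly(A) tail: longest suffix whose
# every length-w window (or the suffix itself when shorter) is >= f A,
# then retracted to the innermost A
oracle_polya <- function(seq, w = 10L, f = 0.8) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  passes <- function(L) {
    suf <- ch[(n - L + 1):n]
    if (L < w) {
      mean(suf == "A") >= f - 1e-9
    } else {
      all(vapply(seq_len(L - w + 1), function(i) {
        mean(suf[i:(i + w - 1)] == "A") >= f - 1e-9
      }, logical(1)))
    }
  }
  L <- 0L
  for (cand in rev(seq_len(n))) {
    if (passes(cand)) { L <- cand; break }
  }
  while (L > 0 && ch[n - L + 1] != "A") L <- L - 1L
  L
}

# whole-whitelist scan for Hamming-1 neighbours
oracle_hamming1 <- function(raw, wl_barcodes) {
  rv <- utf8ToInt(raw)
  wl_barcodes[vapply(wl_barcodes,
                     function(b) sum(utf8ToInt(b) != rv) == 1L,
                     logical(1), USE.NAMES = FALSE)]
}

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# one-pass merge rule on a UMI group, independent row-loop implementation
oracle_dedup <- function(umis, counts) {
  o <- order(-counts, umis)
  umis <- umis[o]; counts <- counts[o]
  accepted <- character(0)
  map <- setNames(umis, umis)
  for (u in umis) {
    nb <- accepted[vapply(accepted, function(a) hamming(a, u) == 1L,
                          logical(1), USE.NAMES = FALSE)]
    if (length(nb) > 0) map[u] <- nb[1] else accepted <- c(accepted, u)
  }
  agg <- tapply(counts, map[umis], sum)
  out <- data.frame(umi = names(agg), count = as.integer(agg))
  out[order(-out$count, out$umi), ]
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute `k` distinct positions of a sequence
mutate_bases <- function(seq, pos) {
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  seq
}

# a full-length cDNA unit in forward orientation
make_unit <- function(ps, transcript, barcode, umi, polya = 30L) {
  paste0(ps$p5, transcript, strrep("A", polya),
         revcomp(umi), revcomp(barcode), revcomp(ps$p3))
}

# pool of 12-mer UMIs mutually >= 4 substitutions apart (repeat 3-mers)
umi_pool <- function() {
  kmers <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("C", "G", "T")), 1, paste, collapse = "")
  kmers <- kmers[!kmers %in% c("CCC", "GGG", "TTT")]   # no homopolymer UMIs
  vapply(kmers, function(k) strrep(k, 4), character(1), USE.NAMES = FALSE)
}
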