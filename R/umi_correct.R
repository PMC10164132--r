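#' Quality-filter UMIs
#'
#' A usable UMI must not be a homopolymer, must not contain `N`, and must not
#' contain any base with Phred quality below `min_qual`.
#'
#' @param umi character vector of UMIs.
#' @param quals Phred+33 quality strings matching `umi` (or `NA` to skip the
#'   quality rule).
#' @param min_qual minimum per-base Phred score.
#' @return tibble: `umi`, `pass`, `reason`
#'   (`HOMOPOLYMER`/`CONTAINS_N`/`LOW_QUAL`/`NA`).
#' @export
filter_umi <- function(umi, quals = NA_character_, min_qual = 10L) {
  quals <- rep_len(quals, length(umi))
  homo <- umi == strrep(substr(umi, 1L, 1L), nchar(umi))
  hasn <- stringr::str_detect(umi, "N")
  mq <- min_phred(quals)
  lowq <- !is.na(mq) & mq < min_qual
  reason <- dplyr::case_when(homo ~ "HOMOPOLYMER",
                             hasn ~ "CONTAINS_N",
                             lowq ~ "LOW_QUAL",
                             TRUE ~ NA_character_)
  tibble(umi = umi, pass = is.na(reason), reason = reason)
}

# Hamming distance matrix between equal-length strings (small groups only)
hamming_matrix <- function(x) {
  m <- do.call(rbind, lapply(x, utf8ToInt))
  n <- length(x)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    out[i, ] <- as.integer(colSums(t(m) != m[i, ]))
  }
  out
}

#' Deduplicate UMIs within one (cell, feature) group
#'
#' UMIs are processed in descending count order (ties: lexicographically
#' ascending). Each UMI within Hamming distance 1 (substitutions only) of an
#' already-accepted UMI of equal-or-higher pre-merge count is corrected to the
#' first such accepted UMI, its reads reassigned (counts add); otherwise it is
#' accepted itself. Merging is single-link: a merged UMI never absorbs others.
#'
#' @param umi_counts named integer vector, or a tibble with `umi` and `count`.
#' @return list with `counts` (tibble `umi`, `count` of surviving UMIs) and
#'   `mapping` (tibble `umi`, `corrected_umi`).
#' @export
dedup_umis <- function(umi_counts) {
  if (is.data.frame(umi_counts)) {
    umis <- umi_counts$umi
    cnt <- umi_counts$count
  } else {
    umis <- names(umi_counts)
    cnt <- as.integer(umi_counts)
  }
  ord <- order(-cnt, umis)
  umis <- umis[ord]
  cnt <- cnt[ord]
  n <- length(umis)
  target <- seq_len(n)
  if (n > 1) {
    hd <- hamming_matrix(umis)
    accepted <- logical(n)
    for (i in seq_len(n)) {
      hit <- which(accepted & hd[i, ] == 1L)
      if (length(hit) > 0) {
        target[i] <- hit[1]           # first accepted neighbour in order
      } else {
        accepted[i] <- TRUE
      }
    }
  }
  new_cnt <- tapply(cnt, target, sum)
  surv <- as.integer(names(new_cnt))
  counts <- tibble(umi = umis[surv], count = as.integer(new_cnt)) |>
    arrange(desc(.data$count), .data$umi)
  mapping <- tibble(umi = umis, corrected_umi = umis[target])
  list(counts = counts, mapping = mapping)
}

#' Deduplicate UMIs across all (cell, feature) groups
#'
#' Applies [dedup_umis()] independently within every (cell, feature) group of
#' a molecule table.
#'
#' @param molecules tibble with `cell`, `feature`, `umi`, `count` columns.
#' @return tibble with the same columns, UMIs corrected and counts merged.
#' @export
dedup_umi_groups <- function(molecules) {
  key <- paste(molecules$cell, molecules$feature, sep = "\r")
  parts <- split(seq_len(nrow(molecules)), key)
  cells <- molecules$cell
  feats <- molecules$feature
  umis <- molecules$umi
  cnts <- molecules$count
  res <- lapply(parts, function(ix) {
    if (length(ix) == 1) {
      return(list(umi = umis[ix], count = cnts[ix], i = ix[1]))
    }
    dd <- dedup_umis(tibble(umi = umis[ix], count = cnts[ix]))
    list(umi = dd$counts$umi, count = dd$counts$count, i = ix[1])
  })
  tibble(
    cell = cells[unlist(lapply(res, function(r) rep(r$i, length(r$umi))))],
    feature = feats[unlist(lapply(res, function(r) rep(r$i, length(r$umi))))],
    umi = unlist(lapply(res, `[[`, "umi")),
    count = as.integer(unlist(lapply(res, `[[`, "count")))
  )
}
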