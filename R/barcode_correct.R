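#' Count whitelist barcode frequencies
#'
#' The observed frequency of every whitelist barcode in the record set: exact
#' raw-barcode matches only; non-whitelist raw barcodes contribute nothing.
#' These frequencies are the priors of the posterior correction.
#'
#' @param records tibble with a `raw_barcode` column (e.g. `flnc` from
#'   [demux_reads()]).
#' @param wl a [whitelist()].
#' @return the whitelist with its `count` column filled in.
#' @export
count_whitelist_freq <- function(records, wl) {
  tab <- table(records$raw_barcode[records$raw_barcode %in% wl$barcode])
  wl$count <- as.integer(tab[wl$barcode])
  wl$count[is.na(wl$count)] <- 0L
  wl
}

# Phred score at position `pos` of each Phred+33 string (vectorised)
qual_at <- function(qual, pos) {
  ch <- substr(qual, pos, pos)
  if (any(!nzchar(ch))) abort("quality string shorter than barcode")
  utf8ToInt(paste(ch, collapse = "")) - 33L
}

# all Hamming-1 neighbours of `raw` that are whitelist members, with the
# differing position; vectorised over unique raw barcodes
hamming1_candidates <- function(raws, wl_barcodes) {
  if (length(raws) == 0) {
    return(tibble(raw_barcode = character(), candidate = character(),
                  pos = integer()))
  }
  L <- nchar(raws[1])
  grid <- tidyr::expand_grid(raw_barcode = raws, pos = seq_len(L),
                             base = DNA_BASES)
  cur <- substr(grid$raw_barcode, grid$pos, grid$pos)
  grid <- grid[cur != grid$base, ]
  variant <- paste0(substr(grid$raw_barcode, 1L, grid$pos - 1L), grid$base,
                    substr(grid$raw_barcode, grid$pos + 1L, L))
  hit <- variant %in% wl_barcodes
  tibble(raw_barcode = grid$raw_barcode[hit], candidate = variant[hit],
         pos = grid$pos[hit])
}

#' Correct cell barcodes against a whitelist
#'
#' Whitelist members are confirmed as-is (`EXACT`). An off-whitelist barcode
#' is compared with every whitelist barcode at Hamming distance 1
#' (substitutions only); for a candidate `c` differing at position `i`, the
#' posterior that the observation arose from `c` through a sequencing error at
#' `i` is proportional to `prior(c) * 10^(-q_i / 10)`, where `q_i` is the base
#' Phred score at the differing position and `prior(c)` is the
#' pseudocounted observed frequency `(count(c) + 1) / sum(count + 1)` over the
#' candidate set. The barcode is replaced by the candidate with the highest
#' posterior when that posterior exceeds `threshold`; otherwise (or with no
#' candidate, or a tied argmax) it stays `UNASSIGNED`.
#'
#' @param records tibble with `raw_barcode` and `bc_qual` columns (plus
#'   `read_id`/`segment_index`, carried through).
#' @param wl a [whitelist()] with counts (see [count_whitelist_freq()]); zero
#'   counts are valid.
#' @param threshold posterior probability an assignment must exceed.
#' @return the records with `corrected_barcode` (`NA` when unassigned),
#'   `status` (`EXACT`/`CORRECTED`/`UNASSIGNED`) and `posterior` (`NA` where
#'   not applicable) appended.
#' @export
correct_barcodes <- function(records, wl, threshold = 0.975) {
  bad <- nchar(records$raw_barcode) != nchar(wl$barcode[1])
  if (any(bad)) {
    abort(paste0("raw barcode length differs from whitelist length for ",
                 sum(bad), " record(s)"))
  }
  out <- records
  out$corrected_barcode <- NA_character_
  out$status <- "UNASSIGNED"
  out$posterior <- NA_real_

  exact <- records$raw_barcode %in% wl$barcode
  out$corrected_barcode[exact] <- records$raw_barcode[exact]
  out$status[exact] <- "EXACT"

  raws <- unique(records$raw_barcode[!exact])
  cand <- hamming1_candidates(raws, wl$barcode)
  if (nrow(cand) > 0) {
    counts <- setNames(wl$count, wl$barcode)
    cand <- cand |>
      mutate(weight = counts[.data$candidate] + 1L) |>
      group_by(.data$raw_barcode) |>
      mutate(prior = .data$weight / sum(.data$weight)) |>
      ungroup()
    idx <- which(!exact & records$raw_barcode %in% cand$raw_barcode)
    if (length(idx) > 0) {
      scored <- tibble(.row = idx,
                       raw_barcode = records$raw_barcode[idx],
                       bc_qual = records$bc_qual[idx]) |>
        inner_join(cand, by = "raw_barcode",
                   relationship = "many-to-many") |>
        mutate(q = qual_at(.data$bc_qual, .data$pos),
               score = .data$prior * 10^(-.data$q / 10)) |>
        group_by(.data$.row) |>
        mutate(posterior = .data$score / sum(.data$score)) |>
        ungroup()
      best <- scored |>
        group_by(.data$.row) |>
        summarise(
          n_best = sum(.data$posterior >= max(.data$posterior) - 1e-15),
          candidate = .data$candidate[which.max(.data$posterior)],
          posterior = max(.data$posterior),
          .groups = "drop")
      assign <- best$posterior > threshold & best$n_best == 1L
      out$posterior[best$.row] <- best$posterior
      out$corrected_barcode[best$.row[assign]] <- best$candidate[assign]
      out$status[best$.row[assign]] <- "CORRECTED"
    }
  }
  out
}

#' Correct one barcode (scalar convenience over [correct_barcodes()])
#'
#' @param raw a raw barcode string.
#' @param quals integer per-base Phred scores (or a Phred+33 string).
#' @param wl a [whitelist()] with counts.
#' @param threshold posterior probability an assignment must exceed.
#' @return one-row tibble: `raw_barcode`, `corrected_barcode`, `status`,
#'   `posterior`.
#' @export
correct_barcode <- function(raw, quals, wl, threshold = 0.975) {
  q <- if (is.character(quals)) quals else intToUtf8(as.integer(quals) + 33L)
  correct_barcodes(tibble(raw_barcode = raw, bc_qual = q), wl, threshold) |>
    select("raw_barcode", "corrected_barcode", "status", "posterior")
}
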