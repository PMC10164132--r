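#' Attach simulator truth to demultiplexed records
#'
#' Matches each demultiplexed segment to the simulated cDNA unit with which it
#' overlaps most (truth units carry pre-error read coordinates), then joins
#' the truth columns onto the barcode-assignment table. Overlap matching is
#' robust to segment-index shifts caused by error-destroyed primers.
#'
#' @param assignments barcode assignments (from [correct_barcodes()]) carrying
#'   `read_id` and `segment_index`.
#' @param segments segment table of the same run (for coordinates).
#' @param truth_units `truth_units` table of a [simulate_library()] run.
#' @return `assignments` with truth columns appended (`unit_type`,
#'   `is_spike`, `barcode` as `true_barcode`, `expected_barcode`, `umi` as
#'   `true_umi`, ...). Records whose segment matches no truth unit are an
#'   error: every scored record must have a truth row.
#' @export
annotate_truth <- function(assignments, segments, truth_units) {
  seg <- assignments |>
    left_join(segments |> select("read_id", "segment_index", "start", "end"),
              by = c("read_id", "segment_index"))
  cand <- seg |>
    mutate(.row = dplyr::row_number()) |>
    inner_join(truth_units, by = "read_id",
               relationship = "many-to-many",
               suffix = c("", ".truth")) |>
    mutate(overlap = pmin(.data$end, .data$unit_end) -
             pmax(.data$start, .data$unit_start)) |>
    filter(.data$overlap > 0) |>
    group_by(.data$.row) |>
    slice_max(.data$overlap, n = 1, with_ties = FALSE) |>
    ungroup()
  if (nrow(cand) < nrow(assignments)) {
    abort("scored record without a matching truth unit")
  }
  cand |>
    arrange(.data$.row) |>
    rename(true_barcode = "barcode", true_umi = "umi") |>
    select(-".row", -"overlap")
}

#' Per-barcode assignment accuracy
#'
#' Fraction of assigned full-length units whose corrected barcode equals the
#' barcode the pipeline should assign. By default the comparison target is the
#' truth `expected_barcode` - the cell's own whitelist barcode, or, for
#' spike-in units, the whitelist member at edit distance 1 that represents the
#' spike-in "known cell" (the off-whitelist spike oligo itself can never be
#' emitted by whitelist-constrained correction). `strict = TRUE` compares
#' against the raw synthesised oligo instead.
#'
#' @param scored assignment table annotated with truth ([annotate_truth()]).
#' @param strict compare against `true_barcode` instead of
#'   `expected_barcode`.
#' @return a fraction in `[0, 1]`.
#' @export
per_barcode_accuracy <- function(scored, strict = FALSE) {
  ref <- if (strict) scored$true_barcode else scored$expected_barcode
  keep <- scored$unit_type == "FLNC" & scored$status != "UNASSIGNED"
  mean(scored$corrected_barcode[keep] == ref[keep])
}

#' Score spike-in barcode assignment (confusion matrix)
#'
#' Positives are spike-in units; `TP` counts spike units assigned the
#' spike-in's whitelist label, `FN` spike units assigned otherwise or left
#' unassigned (optionally excluded), `FP` non-spike units assigned the label,
#' and `TN` the remaining non-spike units. Accuracy, specificity and
#' sensitivity follow the usual definitions.
#'
#' @param scored assignment table annotated with truth ([annotate_truth()]).
#' @param spike_label the whitelist barcode representing the spike-in (for a
#'   simulated library, `sim$spike_whitelist_neighbour`); the assignment the
#'   pipeline is expected to produce for spike units.
#' @param unassigned_fn count unassigned spike units as `FN` (default) or
#'   drop them from scoring.
#' @return a `confusion_counts` object.
#' @export
score_spikein <- function(scored, spike_label, unassigned_fn = TRUE) {
  if (any(is.na(scored$unit_type))) {
    abort("scored record without a matching truth unit")
  }
  if (!unassigned_fn) {
    scored <- scored[!(scored$is_spike & scored$status == "UNASSIGNED"), ]
  }
  pos <- scored$is_spike
  hit <- !is.na(scored$corrected_barcode) &
    scored$corrected_barcode == spike_label
  confusion_counts(TP = sum(pos & hit), FN = sum(pos & !hit),
                   FP = sum(!pos & hit), TN = sum(!pos & !hit))
}

#' Confusion counts and derived metrics
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return a `confusion_counts` list with `accuracy = (TP+TN)/total`,
#'   `specificity = TN/(TN+FP)` and `sensitivity = TP/(TP+FN)` (NA when a
#'   denominator is zero).
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  total <- TP + FP + TN + FN
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    accuracy = if (total > 0) (TP + TN) / total else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP %d  FP %d  TN %d  FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy %.5f  specificity %.5f  sensitivity %.5f\n",
              x$accuracy, x$specificity, x$sensitivity))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.confusion_counts <- function(x, ...) {
  tibble(metric = c("TP", "FP", "TN", "FN",
                    "accuracy", "specificity", "sensitivity"),
         value = c(x$TP, x$FP, x$TN, x$FN,
                   x$accuracy, x$specificity, x$sensitivity))
}

#' @exportS3Method generics::glance
glance.confusion_counts <- function(x, ...) {
  tibble(TP = x$TP, FP = x$FP, TN = x$TN, FN = x$FN,
         accuracy = x$accuracy, specificity = x$specificity,
         sensitivity = x$sensitivity)
}

#' @exportS3Method ggplot2::autoplot
autoplot.confusion_counts <- function(object, ...) {
  df <- tibble(metric = c("accuracy", "specificity", "sensitivity"),
               value = c(object$accuracy, object$specificity,
                         object$sensitivity))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_cartesian(ylim = c(min(0.99, min(df$value, na.rm = TRUE)), 1)) +
    ggplot2::labs(x = NULL, y = "barcode assignment metric")
}

#' Run-level accounting report
#'
#' Deterministic summary of one demultiplexing run, mirroring the standard
#' per-sample accounting of concatemer libraries: linked cDNA count,
#' FLNC/NFL/artifact counts and percentages, mean lengths, and the
#' assigned fraction at the read-QV cutoff.
#'
#' @param run a `demux_run` from [demux_reads()].
#' @param assignments optional barcode assignments for the same run.
#' @param qv_cutoff read-level QV cutoff used for the assigned fraction.
#' @return a `demux_report` list (JSON-ready; see [write_report()]).
#' @export
run_report <- function(run, assignments = NULL, qv_cutoff = 0.95) {
  segs <- run$segments
  n <- nrow(segs)
  tab <- table(factor(segs$category, levels = c("FLNC", "NFL", "ARTIFACT")))
  rep <- list(
    definitions = paste(
      "positives = spike-in units;",
      "TP = spike units assigned the spike-in whitelist label;",
      "FN = spike units assigned otherwise or unassigned;",
      "FP = non-spike units assigned the label; TN = remainder"),
    n_reads = length(unique(segs$read_id)),
    linked_cdna_count = n,
    flnc_count = unname(tab["FLNC"]),
    nfl_count = unname(tab["NFL"]),
    artifact_count = unname(tab["ARTIFACT"]),
    flnc_pct = unname(100 * tab["FLNC"] / n),
    nfl_pct = unname(100 * tab["NFL"] / n),
    artifact_pct = unname(100 * tab["ARTIFACT"] / n),
    mean_segment_len = mean(segs$end - segs$start),
    mean_flnc_transcript_len =
      if (nrow(run$flnc) > 0) mean(nchar(run$flnc$transcript)) else NA_real_
  )
  if (!is.null(assignments)) {
    qv <- assignments$read_qv
    at_qv <- is.na(qv) | qv >= qv_cutoff
    rep$qv_cutoff <- qv_cutoff
    rep$records_at_qv <- sum(at_qv)
    rep$assigned_count <- sum(assignments$status != "UNASSIGNED" & at_qv)
    rep$assigned_fraction <-
      rep$assigned_count / max(1L, rep$records_at_qv)
  }
  structure(rep, class = "demux_report")
}

#' @export
print.demux_report <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.demux_report <- function(x, ...) {
  vals <- unclass(x)
  vals <- vals[vapply(vals, is.numeric, logical(1))]
  tibble(statistic = names(vals), value = unlist(vals))
}

#' @rdname run_report
#' @param report a `demux_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
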