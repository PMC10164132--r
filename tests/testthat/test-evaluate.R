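test_that("confusion metrics follow their closed-form definitions", {
  cc <- confusion_counts(TP = 10L, FP = 0L, TN = 90L, FN = 0L)
  expect_equal(cc$accuracy, 1.0)
  expect_equal(cc$specificity, 1.0)
  expect_equal(cc$sensitivity, 1.0)
  cc2 <- confusion_counts(TP = 9L, FP = 1L, TN = 89L, FN = 1L)
  expect_equal(cc2$accuracy, 98 / 100)
  expect_equal(cc2$specificity, 89 / 90)
  expect_equal(cc2$sensitivity, 9 / 10)
  expect_equal(cc2$TP + cc2$FP + cc2$TN + cc2$FN, 100L)
  td <- tidy(cc2)
  expect_equal(td$value[td$metric == "specificity"], 89 / 90)
  expect_equal(glance(cc2)$accuracy, 0.98)
})

test_that("spike-in scoring and accuracy agree with a brute-force recount", {
  set.seed(51)
  n <- 50
  label <- "AAAAAAAAAAAAAAAA"
  scored <- tibble::tibble(
    unit_type = "FLNC",
    is_spike = c(rep(TRUE, 10), rep(FALSE, 40)),
    expected_barcode = c(rep(label, 10), rand_seq(16) |> rep(40)),
    status = "EXACT"
  )
  scored$true_barcode <- scored$expected_barcode
  scored$corrected_barcode <- scored$expected_barcode
  # one FN among the spikes, one FP among the negatives
  scored$corrected_barcode[1] <- rand_seq(16)
  scored$corrected_barcode[11] <- label
  cc <- score_spikein(scored, label)
  expect_equal(cc$TP, 9L); expect_equal(cc$FN, 1L)
  expect_equal(cc$FP, 1L); expect_equal(cc$TN, 39L)
  expect_equal(cc$accuracy, 48 / 50)
  expect_equal(cc$specificity, 39 / 40)
  # independent recount of per-barcode accuracy
  acc <- per_barcode_accuracy(scored)
  ref <- 0
  for (i in seq_len(n)) {
    ref <- ref + (scored$corrected_barcode[i] == scored$expected_barcode[i])
  }
  expect_equal(acc, ref / n)
  # 1 wrong row in 1000 gives 0.999
  big <- tibble::tibble(unit_type = "FLNC", status = "EXACT",
                        expected_barcode = rep(label, 1000),
                        corrected_barcode = rep(label, 1000))
  big$corrected_barcode[500] <- rand_seq(16)
  expect_equal(per_barcode_accuracy(big), 0.999)
})

test_that("unassigned spike units count as FN unless excluded", {
  scored <- tibble::tibble(
    unit_type = "FLNC",
    is_spike = c(TRUE, TRUE, FALSE),
    corrected_barcode = c("AAAACCCCGGGGTTTT", NA, "CCCCGGGGTTTTAAAA"),
    status = c("EXACT", "UNASSIGNED", "EXACT"))
  cc <- score_spikein(scored, "AAAACCCCGGGGTTTT")
  expect_equal(cc$FN, 1L)
  cc2 <- score_spikein(scored, "AAAACCCCGGGGTTTT", unassigned_fn = FALSE)
  expect_equal(cc2$FN, 0L)
  expect_equal(cc2$TP + cc2$FP + cc2$TN + cc2$FN, 2L)
})

test_that("run reports add up and re-derive from their inputs", {
  sim <- simulate_library(sim_config(n_reads = 80, seed = 52))
  res <- demultiplex(sim$reads, sim$whitelist)
  rep <- res$report
  expect_equal(rep$flnc_pct + rep$nfl_pct + rep$artifact_pct, 100,
               tolerance = 1e-9)
  expect_equal(rep$flnc_count + rep$nfl_count + rep$artifact_count,
               rep$linked_cdna_count)
  expect_equal(rep$linked_cdna_count, nrow(res$run$segments))
  expect_equal(rep$flnc_count, sum(res$run$segments$category == "FLNC"))
  expect_equal(rep$assigned_count,
               sum(res$assignments$status != "UNASSIGNED"))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$flnc_count, rep$flnc_count)
  td <- tidy(rep)
  expect_true("flnc_pct" %in% td$statistic)
})

test_that("assignment accuracy does not improve with the error rate", {
  rates <- c(0.002, 0.015, 0.04)
  acc <- numeric(0)
  n_assigned <- numeric(0)
  for (r in seq_along(rates)) {
    ok <- 0; tot <- 0
    for (s in 1:3) {
      sim <- simulate_library(sim_config(
        n_reads = 120, sub_rate = rates[r], ins_rate = 0.001,
        del_rate = 0.001, seed = 60 + 10 * r + s))
      res <- demultiplex(sim$reads, sim$whitelist,
                         config = demux_config(qv_cutoff = 0))
      scored <- annotate_truth(res$assignments, res$run$segments,
                               sim$truth_units)
      keep <- scored$unit_type == "FLNC" & scored$status != "UNASSIGNED"
      ok <- ok + sum(scored$corrected_barcode[keep] ==
                       scored$expected_barcode[keep])
      tot <- tot + sum(keep)
    }
    acc <- c(acc, ok / tot)
    n_assigned <- c(n_assigned, tot)
  }
  # one-sided binomial slack at alpha ~ 0.01 for adjacent error levels
  for (k in 1:2) {
    p <- acc[k]
    slack <- 2.6 * sqrt(max(p * (1 - p), 1e-6) / n_assigned[k + 1])
    expect_lte(acc[k + 1], acc[k] + slack + 1e-12)
  }
})
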