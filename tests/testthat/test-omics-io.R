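test_that("TSV reading round-trips well-formed tables and drops bad numerics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("analyte_id\tlog2fc", "A\t1.0", "B\t-2.0", "C\t0.0"), path)
  tab <- read_measurement_table(path, "transcript")
  expect_equal(tab$analyte_id, c("A", "B", "C"))
  expect_equal(tab$log2fc, c(1, -2, 0))
  expect_equal(attr(tab, "layer"), "transcript")

  writeLines(c("analyte_id\tlog2fc", "A\t1.0", "B\tnot_a_number", "C\t0.0"), path)
  expect_message(tab2 <- read_measurement_table(path, "transcript"),
                 "dropped 1 row")
  expect_equal(tab2$analyte_id, c("A", "C"))

  # writer round trip preserves every field
  out <- withr::local_tempfile(fileext = ".tsv")
  tab$p_value <- c(0.01, 0.5, NA)
  write_measurement_table(tab, out)
  back <- read_measurement_table(out, "transcript")
  expect_equal(back$analyte_id, tab$analyte_id)
  expect_equal(back$log2fc, tab$log2fc)
  expect_equal(back$p_value, tab$p_value)
})

test_that("phosphosite keys are parsed into host protein and residue", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("analyte_id\tlog2fc", "WEE1_S139\t-1.2"), path)
  tab <- read_measurement_table(path, "phosphosite")
  expect_equal(tab$host_protein, "WEE1")
  expect_equal(tab$residue, "S139")
  expect_equal(tab$log2fc, -1.2)
  # multi-site keys keep the full residue string
  tab2 <- mt("CDK1_T14;Y15", 0.5, layer = "phosphosite")
  expect_equal(tab2$residue, "T14;Y15")
  expect_equal(tab2$host_protein, "CDK1")
})

test_that("reader errors name missing columns and list duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfc", "A\t1"), path)
  expect_error(read_measurement_table(path, "transcript"), "analyte_id")
  tab <- read_measurement_table(path, "transcript",
                                col_map = list(analyte_id = "id", log2fc = "fc"))
  expect_equal(tab$analyte_id, "A")
  writeLines(c("analyte_id\tlog2fc", "A\t1", "A\t2"), path)
  expect_error(read_measurement_table(path, "transcript"), "duplicate.*A")
})

test_that("replicate columns are collected via the column map prefixes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("analyte_id\tlog2fc\tcontrol_1\tcontrol_2\ttreated_1\ttreated_2",
               "A\t0\t1\t2\t3\t4"), path)
  tab <- read_measurement_table(path, "protein")
  expect_equal(tab$reps_control[[1]], c(1, 2))
  expect_equal(tab$reps_treated[[1]], c(3, 4))
})

test_that("Welch test handles zero variance and matches the BH rank formula", {
  ctrl <- rbind(c(0, 0, 0), c(0, 0, 0))
  trt <- rbind(c(0, 0, 0), c(3, 3, 3))
  tab <- differential_stats(mt_reps(c("flat", "shift"), ctrl, trt))
  expect_equal(tab$p_value, c(1, 0))
  expect_equal(tab$log2fc, c(0, 3))

  # BH oracle: explicit p * m / rank with monotonicity fix
  p <- c(0.01, 0.02, 0.04)
  bh_oracle <- rev(cummin(rev(p * length(p) / rank(p))))
  expect_equal(bh_oracle, c(0.03, 0.03, 0.04))
  expect_equal(p.adjust(p, "BH"), bh_oracle)
})

test_that("differential calls recover planted shifts and match the t-test oracle", {
  set.seed(42)
  n_null <- 100; n_true <- 20; k <- 4; sdv <- 1
  ids <- c(paste0("null", seq_len(n_null)), paste0("hit", seq_len(n_true)))
  shift <- c(rep(0, n_null), rep(3 * sdv, n_true))
  ctrl <- matrix(rnorm((n_null + n_true) * k, 0, sdv), ncol = k)
  trt <- matrix(rnorm((n_null + n_true) * k, shift, sdv), ncol = k)
  tab <- differential_stats(mt_reps(ids, ctrl, trt), fdr_threshold = 0.1)
  # independent oracle: per-row stats::t.test + stats::p.adjust
  p_oracle <- vapply(seq_len(n_null + n_true),
                     function(i) stats::t.test(trt[i, ], ctrl[i, ])$p.value,
                     numeric(1))
  expect_equal(tab$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(tab$fdr, p.adjust(p_oracle, "BH"), tolerance = 1e-12)
  # planted 3-sigma shifts dominate the detections
  hits <- sum(tab$significant[tab$analyte_id %in% paste0("hit", 1:20)])
  nulls <- sum(tab$significant[tab$analyte_id %in% paste0("null", 1:100)])
  expect_gte(hits, 8)
  expect_lt(nulls, hits)

  thin <- mt_reps("solo", matrix(c(1, 2), 1), matrix(c(5, 6), 1))
  thin$reps_control[[1]] <- 1
  expect_warning(out <- differential_stats(thin), "fewer than 2")
  expect_true(is.na(out$p_value))
})

test_that("BH output is invariant to input row order", {
  set.seed(7)
  k <- 3
  ctrl <- matrix(rnorm(30 * k), ncol = k)
  trt <- matrix(rnorm(30 * k, 0.5), ncol = k)
  ids <- paste0("a", 1:30)
  t1 <- differential_stats(mt_reps(ids, ctrl, trt))
  perm <- sample(30)
  t2 <- differential_stats(mt_reps(ids[perm], ctrl[perm, ], trt[perm, ]))
  expect_equal(t2$fdr[match(ids, t2$analyte_id)], t1$fdr)
})

test_that("phospho normalization subtracts hosts, flags orphans, preserves order", {
  ph <- mt(c("A_S1", "B_S2", "C_S3"), c(2, 2, -1), layer = "phosphosite")
  pr <- mt(c("A", "C"), c(2, 0.5), layer = "protein")
  out <- suppressMessages(normalize_phospho_by_protein(ph, pr))
  expect_equal(out$log2fc, c(0, 2, -1.5))
  expect_equal(out$flags, c(NA, "uncorrected", NA))
  expect_equal(out$analyte_id, ph$analyte_id)
  # subtract-then-add restores the input exactly
  pr_neg <- mt(c("A", "C"), -c(2, 0.5), layer = "protein")
  back <- suppressMessages(normalize_phospho_by_protein(out, pr_neg))
  expect_equal(back$log2fc, ph$log2fc)
})
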