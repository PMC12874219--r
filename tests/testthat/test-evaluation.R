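test_that("metric formulas match their worked values and conventions", {
  expect_equal(f1_score(confusion_counts(2, 0, 0, 0)), 1.0)
  expect_equal(f1_score(confusion_counts(1, 1, 0, 1)), 0.5)
  expect_equal(f1_score(confusion_counts(0, 3, 0, 2)), 0.0)
  expect_equal(f1_score(confusion_counts(0, 0, 5, 0)), 0)   # degenerate -> 0

  expect_equal(mcc(confusion_counts(5, 0, 5, 0)), 1.0)
  expect_equal(mcc(confusion_counts(0, 5, 0, 5)), -1.0)
  expect_equal(mcc(confusion_counts(1, 1, 1, 1)), 0.0)
  expect_equal(mcc(confusion_counts(3, 0, 0, 0)), 0)        # zero factor -> 0

  expect_equal(recall(confusion_counts(8, 0, 0, 1)), 8 / 9)
  expect_equal(recall(confusion_counts(0, 2, 3, 0)), 0)
  expect_equal(precision(confusion_counts(5, 3, 0, 0)), 0.625)
  expect_equal(precision(confusion_counts(0, 0, 3, 2)), 0)

  expect_error(confusion_counts(-1, 0, 0, 0), class = "mzadapt_error_validation")
})

test_that("metrics agree with independent oracles on the exhaustive 0..6 grid", {
  grid <- expand.grid(tp = 0:6, fp = 0:6, tn = 0:6, fn = 0:6)
  for (r in seq_len(nrow(grid))) {
    tp <- grid$tp[r]; fp <- grid$fp[r]; tn <- grid$tn[r]; fn <- grid$fn[r]
    if (tp + fp + tn + fn == 0) next
    cc <- confusion_counts(tp, fp, tn, fn)
    lab <- labels_from_counts(tp, fp, tn, fn)
    expect_equal(mcc(cc), oracle_mcc(lab$truth, lab$pred, "P"), tolerance = 1e-12)
    expect_equal(f1_score(cc), oracle_f1(lab$truth, lab$pred, "P"), tolerance = 1e-12)
    expect_true(f1_score(cc) >= 0 && f1_score(cc) <= 1)
    expect_true(mcc(cc) >= -1 && mcc(cc) <= 1)
    # simultaneous positive/negative swap preserves MCC
    swapped <- confusion_counts(tn, fn, tp, fp)
    expect_equal(mcc(swapped), mcc(cc), tolerance = 1e-12)
  }
})

test_that("confusion_from_labels counts correctly and validates input", {
  cc <- confusion_from_labels(c("+", "+", "-", "-"), c("+", "+", "-", "-"),
                              positive = "+")
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(2, 0, 2, 0))
  inv <- confusion_from_labels(c("+", "+", "-", "-"), c("-", "-", "+", "+"),
                               positive = "+")
  expect_equal(c(inv$tp, inv$fp, inv$tn, inv$fn), c(0, 2, 0, 2))
  expect_error(confusion_from_labels(character(), character()),
               class = "mzadapt_error_validation")
  expect_error(confusion_from_labels(c("a", "b"), c("a")),
               class = "mzadapt_error_validation")
  expect_error(confusion_from_labels(c("a", "b", "c"), c("a", "b", "c")),
               class = "mzadapt_error_validation")
})

test_that("weighted F1 averages per-class scores by support", {
  perfect <- confusion_counts(5, 0, 5, 0)
  worthless <- confusion_counts(0, 3, 0, 3)
  expect_equal(weighted_f1(list(perfect, worthless), c(1, 1)), 0.5)
  expect_equal(weighted_f1(list(perfect), 7), 1.0)
  expect_equal(weighted_f1(list(perfect, worthless), c(3, 1)), 0.75)
  expect_error(weighted_f1(list(perfect, worthless), c(0, 0)),
               class = "mzadapt_error_validation")
})

test_that("recovery taxonomy classifies the canonical cases", {
  buckets <- tibble::tibble(lower = c(199.99, 300.99), upper = c(200.01, 301.01),
                            apex = c(200, 301), n_members = c(1L, 1L))
  # members average exactly to the truth: recovered
  peaks <- peak_tbl(c(199.9999, 200.0001), c(1, 1))
  rep1 <- recovery_analysis(buckets, peaks, tibble::tibble(name = "A", mz = 200))
  expect_identical(as.character(rep1$features$status), "recovered")
  expect_equal(rep1$recovery_rate, 1.0)

  # two truth features sharing one bucket: both aggregated
  rep2 <- recovery_analysis(buckets, peaks,
                            tibble::tibble(name = c("A", "B"), mz = c(200, 200.0003)))
  expect_true(all(rep2$features$status == "aggregated"))
  expect_equal(rep2$recovery_rate, 0.0)

  # one feature split across two adjacent buckets: clipped
  grid <- tibble::tibble(lower = c(199.9, 200.0), upper = c(200.0, 200.1),
                         apex = c(199.95, 200.05), n_members = c(1L, 1L))
  split_peaks <- peak_tbl(c(199.9996, 200.0004), c(1, 1))
  rep3 <- recovery_analysis(grid, split_peaks, tibble::tibble(name = "A", mz = 200))
  expect_identical(as.character(rep3$features$status), "clipped")

  # apex displaced beyond tolerance by co-binned extraneous peaks: aggregated
  wide <- tibble::tibble(lower = 199.9, upper = 200.1, apex = 200, n_members = 1L)
  displaced <- peak_tbl(c(200, 200.09), c(1, 10))
  rep4 <- recovery_analysis(wide, displaced, tibble::tibble(name = "A", mz = 200))
  expect_identical(as.character(rep4$features$status), "aggregated")

  # nothing anywhere near: missed
  rep5 <- recovery_analysis(buckets, peaks, tibble::tibble(name = "Z", mz = 450))
  expect_identical(as.character(rep5$features$status), "missed")

  expect_error(recovery_analysis(buckets, peaks,
                                 tibble::tibble(name = c("A", "B"), mz = c(200, 200))),
               class = "mzadapt_error_validation")
  expect_error(recovery_analysis(buckets, peaks,
                                 tibble::tibble(name = "A", mz = 200), match_tol_ppm = 0),
               class = "mzadapt_error_validation")
})

test_that("recovery_analysis agrees with a brute-force all-pairs matcher", {
  withr::with_seed(31, {
    for (i in 1:15) {
      nb <- sample(5:40, 1)
      buckets <- random_buckets(nb, 100, 1000)
      npk <- sample(20:80, 1)
      peaks <- peak_tbl(runif(npk, 100, 1000), runif(npk, 1, 100))
      nt <- sample(2:20, 1)
      truth <- tibble::tibble(name = sprintf("T%02d", seq_len(nt)),
                              mz = runif(nt, 100, 1000))
      # nudge some truths onto actual peaks so every status arises
      truth$mz[1] <- peaks$mz[1]
      rep <- recovery_analysis(buckets, peaks, truth, match_tol_ppm = 100)
      expect_identical(as.character(rep$features$status),
                       brute_recovery(buckets, peaks, truth, 100))
    }
  })
})

test_that("recovery report accessors and plot work", {
  buckets <- tibble::tibble(lower = 199.99, upper = 200.01, apex = 200, n_members = 1L)
  rep <- recovery_analysis(buckets, peak_tbl(200, 1),
                           tibble::tibble(name = "A", mz = 200))
  expect_identical(nrow(tidy(rep)), 1L)
  gl <- glance(rep)
  expect_equal(gl$recovery_rate, 1)
  expect_identical(gl$recovered, 1L)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("the linear-classifier harness separates an easy two-class matrix", {
  withr::with_seed(5, {
    n <- 40
    obs <- tibble::tibble(
      observation_id = sprintf("o%02d", 1:n), batch_id = "batch1",
      label = rep(c("case", "control"), each = n / 2))
    x1 <- c(rnorm(n / 2, 10), rnorm(n / 2, 2))
    x2 <- c(rnorm(n / 2, 1), rnorm(n / 2, 8))
    peaks <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(observation_id = obs$observation_id[i], batch_id = "batch1",
                     label = obs$label[i], mz = c(150.0, 250.0),
                     intensity = pmax(c(x1[i], x2[i]), 0.01))
    }))
    buckets <- tibble::tibble(lower = c(149, 249), upper = c(151, 251),
                              apex = c(150, 250), n_members = c(1L, 1L))
    fm <- bin_spectra(peaks, buckets)
    idx <- rep(c(TRUE, FALSE), n / 2)
    pred <- linear_classifier(fm[idx, ], fm[!idx, ], positive = "case")
    cc <- confusion_from_labels(fm$label[!idx], pred, positive = "case")
    expect_gte(f1_score(cc), 0.9)
  })
})
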