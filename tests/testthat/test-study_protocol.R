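test_that("case segment selection windows on the 24 h before onset", {
  s <- constant_series(36, patient_id = "C1")
  rec <- patient_record("C1", group = "I", series = s, onset_s = 30.5 * 3600)
  segs <- select_case_segments(rec)
  idx <- vapply(segs, function(x) x$segment_index, 0L)
  expect_equal(idx, 6:29)

  rec2 <- patient_record("C2", group = "I",
                         series = constant_series(12, patient_id = "C2"),
                         onset_s = 10 * 3600 + 5)
  idx2 <- vapply(select_case_segments(rec2), function(x) x$segment_index, 0L)
  expect_equal(idx2, 0:9) # "up to 24": shorter recordings give fewer

  rec3 <- patient_record("C3", group = "I",
                         series = constant_series(2, patient_id = "C3"),
                         onset_s = -10)
  expect_error(select_case_segments(rec3), "protocol error")
  expect_error(select_case_segments(
    patient_record("C4", group = "II",
                   series = constant_series(1, patient_id = "C4"))),
    "protocol error")
})

test_that("selected case segments never overlap the AF episode", {
  pr <- patient_profile("GT", group = "I", onset_day = 1, onset_hour = 20.4,
                        pac_base_rate = 15, af_duration = 3600)
  rec <- simulate_patient(pr, seed = 61, recording_days = 2)
  segs <- select_case_segments(rec)
  last_end <- max(vapply(segs, function(s) max(s$beats$t), 0))
  expect_lt(last_end, rec$truth$af_start)
})

test_that("control selection takes analyzable day-2 hours", {
  s <- constant_series(5 * 24, patient_id = "K1")
  rec <- patient_record("K1", group = "II", series = s)
  segs <- select_control_segments(rec)
  idx <- vapply(segs, function(x) x$segment_index, 0L)
  expect_equal(idx, 24:47)
  expect_true(all(idx %/% 24 == 1)) # all on postoperative day 2

  # a recording covering only part of day 2 yields only covered hours
  s2 <- constant_series(30, patient_id = "K2")
  idx2 <- vapply(select_control_segments(
    patient_record("K2", group = "II", series = s2)),
    function(x) x$segment_index, 0L)
  expect_equal(idx2, 24:29)

  s3 <- constant_series(3, patient_id = "K3")
  expect_warning(
    out <- select_control_segments(patient_record("K3", group = "II",
                                                  series = s3)),
    "excluded")
  expect_length(out, 0L)
})

test_that("window_call implements the two-or-more rule", {
  expect_true(window_call(c(TRUE, TRUE, FALSE))$call)
  expect_false(window_call(c(TRUE, FALSE, FALSE))$call)
  c3 <- window_call(c(TRUE, TRUE, TRUE))
  expect_true(c3$call)
  expect_equal(c3$n_positive, 3L)
  und <- window_call(c(TRUE, NA, TRUE))
  expect_false(und$defined)
  expect_true(is.na(und$call))
  expect_equal(window_call(c(TRUE, FALSE, FALSE), min_positives = 1)$call,
               TRUE)
})

test_that("segment_contingency reproduces the published stretch counts", {
  cases <- data.frame(
    patient_id = rep("I", 660),
    positive = rep(c(TRUE, FALSE), c(458, 202)))
  controls <- data.frame(
    patient_id = rep("II", 1288),
    positive = rep(c(TRUE, FALSE), c(206, 1082)))
  ct <- segment_contingency(cases, controls)
  expect_equal(ct$tp, 458L)
  expect_equal(ct$fn, 202L)
  expect_equal(ct$fp, 206L)
  expect_equal(ct$tn, 1082L)

  empty <- data.frame(patient_id = character(), positive = logical())
  ct0 <- segment_contingency(empty, empty)
  expect_equal(ct0$tp + ct0$fp + ct0$fn + ct0$tn, 0L)

  both <- data.frame(patient_id = "P1", positive = TRUE)
  expect_error(segment_contingency(both, both), "overlap")
})

test_that("patient_contingency reproduces the published patient tables", {
  t4 <- data.frame(
    patient_id = sprintf("P%03d", 1:112),
    group = rep(c("I", "II"), c(31, 81)),
    call = rep(c(TRUE, FALSE, TRUE, FALSE), c(19, 12, 15, 66)))
  ct4 <- patient_contingency(t4)
  expect_equal(unlist(ct4[c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(19L, 12L, 15L, 66L))

  t5 <- data.frame(
    patient_id = sprintf("P%03d", 1:112),
    group = rep(c("I", "II"), c(31, 81)),
    call = rep(c(TRUE, FALSE, TRUE, FALSE), c(26, 5, 14, 67)))
  ct5 <- patient_contingency(t5)
  expect_equal(unlist(ct5[c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(26L, 5L, 14L, 67L))

  none <- data.frame(patient_id = c("a", "b"), group = c("I", "II"),
                     call = FALSE)
  ctn <- patient_contingency(none)
  expect_equal(ctn$tp + ctn$fp, 0L)

  expect_error(patient_contingency(
    data.frame(patient_id = c("a", "a"), group = "I", call = TRUE)),
    "duplicate")
})

test_that("window_positivity_rates pools segments and reports differences", {
  wr <- data.frame(
    patient_id = rep(sprintf("p%d", 1:10), each = 3),
    group = "I", window = "FIRST3",
    positive = rep(c(TRUE, FALSE), c(10, 20)))
  wr2 <- wr
  wr2$window <- "LAST3"
  rates <- window_positivity_rates(rbind(wr, wr2))
  gi <- rates[rates$group == "I", ]
  expect_equal(gi$first3_rate, 1 / 3, tolerance = 1e-12)
  expect_equal(gi$difference, 0)
})

test_that("cohort evaluation conserves segment counts and bookkeeps exclusions", {
  cfg <- cohort_config(n_patients = 6, recording_days = 2,
                       master_seed = 424242)
  rep6 <- evaluate_cohort(cfg, classifier_config(), spectral = FALSE)
  ct <- rep6$segment_table
  expect_equal(ct$tp + ct$fn,
               sum(!is.na(rep6$case_results$positive)))
  expect_equal(ct$fp + ct$tn,
               sum(!is.na(rep6$control_results$positive)))
  expect_s3_class(rep6$excluded, "data.frame")
  expect_true(all(c("patient_id", "reason") %in% names(rep6$excluded)))
  # deterministic rerun
  rep6b <- evaluate_cohort(cfg, classifier_config(), spectral = FALSE)
  expect_identical(rep6$case_results, rep6b$case_results)
  expect_identical(rep6$rates, rep6b$rates)
})
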