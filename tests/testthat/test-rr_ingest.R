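test_that("read_rr_table reconstructs time, converts units, defaults labels", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr_ms", "800", "810", "790"), tmp)
  s <- read_rr_table(tmp)
  expect_s3_class(s, "beat_series")
  expect_equal(s$t, c(0, 0.81, 1.60))
  expect_equal(s$rr, c(800, 810, 790))
  expect_equal(s$label, rep("U", 3))

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr_ms", "0.8", "0.81", "0.79"), tmp2)
  s2 <- read_rr_table(tmp2, units = "s")
  expect_equal(s2$t, s$t)
  expect_equal(s2$rr, s$rr)
})

test_that("read_rr_table rejects bad rows and flags corrupt files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr_ms", rep("800", 40), "-5"), tmp)
  expect_warning(s <- read_rr_table(tmp), "rejected 1")
  expect_equal(nrow(s), 40)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr_ms", rep("800", 10), rep("-1", 2)), tmp2)
  expect_error(read_rr_table(tmp2), "corrupt series")
  expect_error(read_rr_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write/read round trip is lossless and write is deterministic", {
  s <- simulate_sinus(sinus_params(), 2 * 3600, seed = 7, patient_id = "RT")
  s <- inject_pacs(s, 20, seed = 8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_rr_table(s, f1)
  expect_equal(length(readLines(f1)), nrow(s) + 1L) # header + one per beat
  back <- read_rr_table(f1, patient_id = "RT")
  expect_equal(back$t, s$t)
  expect_equal(back$rr, s$rr)
  expect_equal(back$label, s$label)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rr_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("clean_artifacts applies the range, label and jump rules", {
  rr <- rep(800, 200)
  rr[100] <- 150 # below min_rr
  s <- beat_series(rr = rr, label = "N", validate = FALSE)
  out <- clean_artifacts(s)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false(150 %in% out$rr)

  clean <- beat_series(rr = rep(c(790, 810), 100), label = "N")
  out2 <- clean_artifacts(clean)
  expect_equal(attr(out2, "n_removed"), 0L)
  expect_equal(out2$rr, clean$rr)

  # X labels and median jumps are removed; ground-truth count recovered
  rr3 <- rep(800, 400)
  bad <- c(50, 120, 200, 280, 350)
  rr3[bad] <- c(2500, 250, 800, 1400, 260) # 200 is X-labeled, rr normal
  lab <- rep("N", 400)
  lab[200] <- "X"
  s3 <- beat_series(rr = rr3, label = lab, validate = FALSE)
  out3 <- clean_artifacts(s3)
  expect_equal(attr(out3, "n_removed"), 5L)
  expect_equal(nrow(out3), 395L)
})

test_that("clean_artifacts is idempotent and flags heavily corrupted hours", {
  s <- simulate_sinus(sinus_params(), 3600, seed = 11)
  rr <- s$rr
  set.seed(12)
  idx <- sample(seq(20, nrow(s) - 20), 10)
  rr[idx] <- c(rep(250, 5), rep(2400, 5))
  noisy <- beat_series(rr = rr, label = "N", validate = FALSE)
  once <- clean_artifacts(noisy)
  expect_equal(attr(once, "n_removed"), 10L)
  twice <- clean_artifacts(once)
  expect_equal(attr(twice, "n_removed"), 0L)
  expect_equal(twice$rr, once$rr)

  # an hour losing > 20% of beats is flagged, and segment_hours honors it
  rr2 <- rep(800, 4500)
  rr2[seq(10, 1500, by = 1)] <- 100
  bad_hr <- beat_series(rr = rr2, label = "N", validate = FALSE)
  cleaned <- clean_artifacts(bad_hr)
  expect_true(0 %in% attr(cleaned, "unanalyzable_hours"))
  segs <- segment_hours(cleaned)
  expect_false(segs[[1]]$analyzable)
})

test_that("segment_hours partitions beats into half-open hourly bins", {
  s <- constant_series(2)
  segs <- segment_hours(s)
  expect_equal(sum(vapply(segs, function(x) x$analyzable, TRUE)), 2L)

  # boundary beat at exactly 3600 s goes to segment 1
  b <- beat_series(t = c(3599.2, 3600.0, 3600.8), rr = rep(800, 3),
                   label = "N", validate = FALSE)
  segs2 <- segment_hours(b, min_beats = 1)
  idx <- vapply(segs2, function(x) x$segment_index, 0L)
  expect_equal(idx, c(0L, 1L))
  expect_equal(segs2[[2]]$n_beats, 2L)

  expect_identical(segment_hours(
    structure(data.frame(t = numeric(), rr = numeric(), label = character()),
              class = c("beat_series", "data.frame"))), list())
})

test_that("segment partition property holds on synthetic recordings", {
  for (seed in c(1, 2)) {
    s <- simulate_sinus(sinus_params(mean_rr = 700 + 100 * seed),
                        3.5 * 3600, seed = seed)
    s <- inject_pacs(s, 15, seed = seed + 10)
    segs <- segment_hours(s, min_beats = 1)
    expect_equal(sum(vapply(segs, function(x) x$n_beats, 0L)), nrow(s))
    all_t <- unlist(lapply(segs, function(x) x$beats$t))
    expect_equal(sort(all_t), s$t) # every beat exactly once
    for (seg in segs) {
      expect_true(all(floor(seg$beats$t / 3600) == seg$segment_index))
    }
  }
})

test_that("label_premature_beats follows the prematurity/pause rule", {
  rr <- rep(800, 60)
  rr[30] <- 520
  rr[31] <- 1050
  s <- beat_series(rr = rr, label = "U", validate = FALSE)
  out <- label_premature_beats(s)
  expect_equal(which(out$label == "A"), 30L)

  const <- beat_series(rr = rep(800, 100), label = "N")
  expect_equal(sum(label_premature_beats(const)$label == "A"), 0L)

  # premature beat without compensatory pause is not relabeled
  rr2 <- rep(800, 60)
  rr2[30] <- 520
  s2 <- beat_series(rr = rr2, label = "U", validate = FALSE)
  expect_equal(sum(label_premature_beats(s2)$label == "A"), 0L)
})

test_that("injected PACs are recovered with few false labels", {
  found_tot <- 0L
  inj_tot <- 0L
  false_tot <- 0L
  hours <- 3L
  for (k in seq_len(hours)) {
    s <- simulate_sinus(sinus_params(), 3600, seed = 100 + k)
    s <- inject_pacs(s, 10, seed = 200 + k)
    truth <- attr(s, "pac_truth")
    unl <- beat_series(s$t, s$rr, "U", validate = FALSE)
    lab <- label_premature_beats(unl)
    found <- which(lab$label == "A")
    found_tot <- found_tot + sum(truth$index %in% found)
    inj_tot <- inj_tot + nrow(truth)
    false_tot <- false_tot + sum(!(found %in% truth$index))
  }
  expect_gte(inj_tot, 20L)
  expect_gte(found_tot / inj_tot, 0.9)
  expect_lte(false_tot / hours, 2) # at most 2 false labels per hour
})
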