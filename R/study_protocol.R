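#' Construct a patient record
#'
#' @param patient_id identifier.
#' @param group `"I"` (developed postoperative AF) or `"II"` (control).
#' @param series the patient's [beat_series()].
#' @param onset_s AF onset in seconds from recording start (group I
#'   only); alternatively give `onset_day` (1-5) and `onset_hour`.
#' @param onset_day,onset_hour onset as postoperative day + hour of day.
#' @return A `patient_record` list.
#' @export
patient_record <- function(patient_id, group = c("II", "I"), series,
                           onset_s = NULL, onset_day = NULL,
                           onset_hour = NULL) {
  group <- match.arg(group)
  if (is.null(onset_s) && !is.null(onset_day)) {
    onset_s <- ((onset_day - 1) * 24 + onset_hour) * 3600
  }
  if (group == "I" && is.null(onset_s)) {
    stop("group I records need an AF onset time")
  }
  if (group == "II") onset_s <- NA_real_
  structure(list(patient_id = patient_id, group = group,
                 onset_s = onset_s, series = series, truth = NULL),
            class = "patient_record")
}

# clean, label and segment a record's series with the classifier's
# preprocessing settings
protocol_segments <- function(record, config = classifier_config()) {
  series <- clean_artifacts(record$series, config$min_rr, config$max_rr,
                            config$jump_fraction)
  if (!any(series$label == "A")) {
    series <- label_premature_beats(series, config$prematurity, config$pause)
  }
  segment_hours(series, min_beats = config$min_beats)
}

#' Select the case (pre-onset) segments of a POAF patient
#'
#' The analyzable hourly segments in the 24-hour window ending at AF
#' onset (fewer when the recording is shorter). The hour containing the
#' onset is excluded, so no AF ever contaminates a selected segment, and
#' segments after onset are never selected.
#'
#' @param record a group-I `patient_record`.
#' @param config a [classifier_config()] (preprocessing + minimum beat
#'   count).
#' @param segments optionally, precomputed output of the internal
#'   segmentation (to avoid re-cleaning).
#' @return List of analyzable `hour_segment`s, ordered by hour.
#' @export
select_case_segments <- function(record, config = classifier_config(),
                                 segments = NULL) {
  stopifnot(inherits(record, "patient_record"))
  if (record$group != "I" || is.na(record$onset_s)) {
    stop("protocol error: case selection needs a group I record with onset")
  }
  if (record$onset_s <= 0) {
    stop("protocol error: AF onset before recording start")
  }
  segs <- segments %||% protocol_segments(record, config)
  onset_hour <- floor(record$onset_s / 3600)
  window <- seq(max(0, onset_hour - 24), onset_hour - 1)
  Filter(function(s) s$analyzable && s$segment_index %in% window, segs)
}

#' Select the control (day 2) segments of a non-POAF patient
#'
#' The analyzable hourly segments of the second postoperative day
#' (recording hours 24-47 for a recording starting at 00:00 of day 1) --
#' the day with the highest POAF incidence, hence the most informative
#' control day.
#'
#' @inheritParams select_case_segments
#' @return List of analyzable `hour_segment`s; empty (with a warning)
#'   when the recording has no day-2 coverage, in which case the patient
#'   is excluded upstream.
#' @export
select_control_segments <- function(record, config = classifier_config(),
                                    segments = NULL) {
  stopifnot(inherits(record, "patient_record"))
  if (record$group != "II") {
    stop("protocol error: control selection needs a group II record")
  }
  segs <- segments %||% protocol_segments(record, config)
  out <- Filter(function(s) s$analyzable && s$segment_index %in% 24:47, segs)
  if (length(out) == 0L) {
    warning("patient ", record$patient_id, " has no analyzable day-2 ",
            "coverage; excluded")
  }
  out
}

#' Patient-level call from a three-hour window
#'
#' A window is called positive when at least `min_positives` of its
#' three hourly risk results are positive. Fewer than three analyzable
#' results gives an undefined call and the patient is excluded from that
#' analysis (mirroring signal-loss exclusions).
#'
#' @param positive logical vector of per-hour positivity (ideally length
#'   3); `NA`s count as missing.
#' @param min_positives required positives (default 2).
#' @return A `window_call` list: `n_positive`, `call`, `n_hours`,
#'   `defined`.
#' @export
window_call <- function(positive, min_positives = 2) {
  positive <- positive[!is.na(positive)]
  if (length(positive) < 3L) {
    return(structure(list(n_positive = NA_integer_, call = NA,
                          n_hours = length(positive), defined = FALSE),
                     class = "window_call"))
  }
  positive <- positive[seq_len(3L)]
  structure(list(n_positive = sum(positive),
                 call = sum(positive) >= min_positives,
                 n_hours = 3L, defined = TRUE),
            class = "window_call")
}

#' 2x2 contingency table
#'
#' @param tp,fp,fn,tn non-negative counts (cases positive, controls
#'   positive, cases negative, controls negative).
#' @param level `"segment"` or `"patient"`.
#' @return A `contingency_table` list.
#' @export
contingency_table <- function(tp, fp, fn, tn, level = c("segment", "patient")) {
  level <- match.arg(level)
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn), level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> (%s level)\n", x$level))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test +", "test -"),
                              c("cases", "controls")))
  print(m)
  invisible(x)
}

#' Segment-level contingency table from case and control risk results
#'
#' True positives are positive case segments, false negatives negative
#' case segments, false positives positive control segments, true
#' negatives negative control segments. Unanalyzable (`NA`) segments are
#' excluded from the counts, never imputed.
#'
#' @param case_results,control_results data frames with columns
#'   `patient_id` and `positive` (as produced by [classify_series()]).
#' @return A segment-level [contingency_table()].
#' @export
segment_contingency <- function(case_results, control_results) {
  if (length(intersect(unique(case_results$patient_id),
                       unique(control_results$patient_id)))) {
    stop("protocol error: case and control patient sets overlap")
  }
  cp <- case_results$positive[!is.na(case_results$positive)]
  kp <- control_results$positive[!is.na(control_results$positive)]
  contingency_table(tp = sum(cp), fn = sum(!cp),
                    fp = sum(kp), tn = sum(!kp), level = "segment")
}

#' Patient-level contingency table from window calls
#'
#' @param calls data frame with one row per patient: `patient_id`,
#'   `group` (`"I"`/`"II"`) and `call` (logical; `NA` = undefined,
#'   excluded).
#' @return A patient-level [contingency_table()]; attribute
#'   `n_excluded` counts undefined calls.
#' @export
patient_contingency <- function(calls) {
  if (anyDuplicated(calls$patient_id)) {
    stop("protocol error: duplicate patient in window calls")
  }
  ok <- !is.na(calls$call)
  g <- calls$group[ok]
  cl <- calls$call[ok]
  out <- contingency_table(tp = sum(g == "I" & cl), fn = sum(g == "I" & !cl),
                           fp = sum(g == "II" & cl), tn = sum(g == "II" & !cl),
                           level = "patient")
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Pooled positivity rates per group and window
#'
#' Fraction of positive segments pooled over patients, per group and
#' window (first three recorded hours vs the three hours preceding onset
#' for cases / closing day 2 for controls), with the within-group
#' last-minus-first difference. The per-patient mean proportion is also
#' reported for transparency (pooling weights patients by analyzable
#' hours; the mean does not).
#'
#' @param window_results data frame with columns `patient_id`, `group`,
#'   `window` (`"FIRST3"`/`"LAST3"`) and `positive`.
#' @return Data frame with one row per group: pooled rates, per-patient
#'   mean rates and differences.
#' @export
window_positivity_rates <- function(window_results) {
  wr <- window_results[!is.na(window_results$positive), , drop = FALSE]
  out <- lapply(c("I", "II"), function(g) {
    gi <- wr[wr$group == g, , drop = FALSE]
    pool <- function(w) {
      x <- gi$positive[gi$window == w]
      if (length(x)) mean(x) else NA_real_
    }
    pmean <- function(w) {
      x <- gi[gi$window == w, , drop = FALSE]
      if (nrow(x)) mean(tapply(x$positive, x$patient_id, mean)) else NA_real_
    }
    data.frame(group = g,
               first3_rate = pool("FIRST3"), last3_rate = pool("LAST3"),
               difference = pool("LAST3") - pool("FIRST3"),
               first3_patient_mean = pmean("FIRST3"),
               last3_patient_mean = pmean("LAST3"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Analyze one patient: segment, pick protocol windows, classify them.
analyze_patient <- function(record, config = classifier_config(),
                            min_positives = 2, spectral = TRUE) {
  segs <- protocol_segments(record, config)
  idx <- vapply(segs, function(s) s$segment_index, 0L)
  analyzable <- vapply(segs, function(s) s$analyzable, TRUE)
  an_idx <- idx[analyzable]
  first3 <- head(an_idx, 3L)
  if (record$group == "I") {
    sel <- select_case_segments(record, config, segments = segs)
  } else {
    sel <- suppressWarnings(
      select_control_segments(record, config, segments = segs))
  }
  sel_idx <- vapply(sel, function(s) s$segment_index, 0L)
  last3 <- tail(sel_idx, 3L)
  want <- sort(unique(c(first3, sel_idx)))
  res <- do.call(rbind, lapply(segs[match(want, idx)], function(s) {
    r <- classify_one_segment(s, config)
    data.frame(patient_id = record$patient_id,
               segment_index = s$segment_index,
               risk = r$risk, positive = r$positive,
               pac_per_hour = r$evidence$pac_per_hour %||% NA_real_,
               pattern = r$evidence$pattern %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  spec_first <- spec_last <- NULL
  if (spectral && length(first3) && length(last3)) {
    spec_first <- spectral_power(segs[[match(first3[1L], idx)]])
    spec_last <- spectral_power(segs[[match(last3[length(last3)], idx)]])
  }
  list(patient_id = record$patient_id, group = record$group,
       onset_s = record$onset_s, results = res, selected_idx = sel_idx,
       first3 = first3, last3 = last3,
       call_first = window_call(res$positive[match(first3, res$segment_index)],
                                min_positives),
       call_last = window_call(res$positive[match(last3, res$segment_index)],
                               min_positives),
       spectral_first = spec_first, spectral_last = spec_last)
}

#' Evaluate the full prediction protocol over a cohort
#'
#' Streams through the cohort patient by patient (simulating each
#' recording on demand when given a [cohort_config()], so the full
#' multi-day cohort never sits in memory), applies the segment selection
#' rules, classifies the selected hours, and assembles the segment- and
#' patient-level contingency tables, the window positivity rates, and
#' the first-hour vs last-pre-onset-hour spectral (HF, LF/HF) summary
#' for the POAF arm.
#'
#' @param cohort a `cohort` (from [simulate_cohort()]), a list of
#'   `patient_record`s, or a [cohort_config()] to simulate on the fly.
#' @param config a [classifier_config()].
#' @param min_positives positives required for a patient-level call.
#' @param spectral compute the autonomic (LF/HF) sub-analysis.
#' @param progress print one line per patient.
#' @return A `protocol_report` list: `segment_table`, `patient_table_first`,
#'   `patient_table_last` ([contingency_table()]s), `rates`
#'   ([window_positivity_rates()] output), `case_results`,
#'   `control_results`, `window_results`, `autonomic` (per group-I
#'   patient HF/LF-HF first vs last), `excluded` (assembly and
#'   window-level exclusions), `n_patients`.
#' @export
evaluate_cohort <- function(cohort, config = classifier_config(),
                            min_positives = 2, spectral = TRUE,
                            progress = FALSE) {
  excluded <- data.frame(patient_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (inherits(cohort, "cohort_config")) {
    cfg <- cohort
    set.seed(cfg$master_seed)
    profiles <- draw_cohort_profiles(cfg)
    get_record <- function(i) {
      pr <- profiles[[i]]
      if (pr$group == "I") {
        onset_s <- ((pr$onset_day - 1) * 24 + pr$onset_hour) * 3600
        if (onset_s < 6 * 3600) {
          return(list(skip = TRUE, patient_id = pr$patient_id,
                      reason = "AF onset within first 6 h of monitoring"))
        }
      }
      simulate_patient(pr, seed = patient_seed(cfg$master_seed, i),
                       recording_days = cfg$recording_days)
    }
    n <- length(profiles)
  } else if (inherits(cohort, "cohort")) {
    excluded <- rbind(excluded, cohort$excluded)
    get_record <- function(i) cohort$patients[[i]]
    n <- length(cohort$patients)
  } else {
    get_record <- function(i) cohort[[i]]
    n <- length(cohort)
  }

  case_rows <- list(); ctrl_rows <- list(); win_rows <- list()
  calls_first <- list(); calls_last <- list(); autonomic <- list()
  n_eval <- 0L
  for (i in seq_len(n)) {
    rec <- get_record(i)
    if (is.list(rec) && isTRUE(rec$skip)) {
      excluded <- rbind(excluded, data.frame(patient_id = rec$patient_id,
                                             reason = rec$reason,
                                             stringsAsFactors = FALSE))
      next
    }
    a <- analyze_patient(rec, config, min_positives, spectral)
    n_eval <- n_eval + 1L
    if (progress) {
      message(sprintf("%s (group %s): %d selected segments",
                      a$patient_id, a$group, length(a$selected_idx)))
    }
    sel <- a$results[a$results$segment_index %in% a$selected_idx, ,
                     drop = FALSE]
    if (a$group == "I") case_rows[[length(case_rows) + 1L]] <- sel
    else ctrl_rows[[length(ctrl_rows) + 1L]] <- sel
    for (w in c("FIRST3", "LAST3")) {
      hidx <- if (w == "FIRST3") a$first3 else a$last3
      if (length(hidx)) {
        win_rows[[length(win_rows) + 1L]] <- data.frame(
          patient_id = a$patient_id, group = a$group, window = w,
          positive = a$results$positive[match(hidx, a$results$segment_index)],
          stringsAsFactors = FALSE)
      }
    }
    calls_first[[length(calls_first) + 1L]] <- data.frame(
      patient_id = a$patient_id, group = a$group,
      call = if (a$call_first$defined) a$call_first$call else NA,
      stringsAsFactors = FALSE)
    calls_last[[length(calls_last) + 1L]] <- data.frame(
      patient_id = a$patient_id, group = a$group,
      call = if (a$call_last$defined) a$call_last$call else NA,
      stringsAsFactors = FALSE)
    if (!a$call_first$defined || !a$call_last$defined) {
      excluded <- rbind(excluded, data.frame(
        patient_id = a$patient_id,
        reason = "fewer than 3 analyzable hours in an evaluation window",
        stringsAsFactors = FALSE))
    }
    if (a$group == "I" && spectral && !is.null(a$spectral_first) &&
        !is_flagged_undefined(a$spectral_first) &&
        !is_flagged_undefined(a$spectral_last)) {
      autonomic[[length(autonomic) + 1L]] <- data.frame(
        patient_id = a$patient_id,
        hf_first = a$spectral_first$hf_power,
        hf_last = a$spectral_last$hf_power,
        lfhf_first = a$spectral_first$lf_hf,
        lfhf_last = a$spectral_last$lf_hf,
        stringsAsFactors = FALSE)
    }
  }
  case_results <- do.call(rbind, case_rows)
  control_results <- do.call(rbind, ctrl_rows)
  window_results <- do.call(rbind, win_rows)
  calls_first <- do.call(rbind, calls_first)
  calls_last <- do.call(rbind, calls_last)
  structure(
    list(segment_table = segment_contingency(case_results, control_results),
         patient_table_first = patient_contingency(calls_first),
         patient_table_last = patient_contingency(calls_last),
         rates = window_positivity_rates(window_results),
         case_results = case_results, control_results = control_results,
         window_results = window_results,
         calls_first = calls_first, calls_last = calls_last,
         autonomic = do.call(rbind, autonomic),
         excluded = excluded, n_patients = n_eval),
    class = "protocol_report"
  )
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("== Cohort protocol report ==\n")
  cat(sprintf("patients evaluated: %d (excluded rows: %d)\n",
              x$n_patients, nrow(x$excluded)))
  cat("\n-- segment level --\n")
  print(x$segment_table)
  print(diagnostic_stats(x$segment_table))
  cat("\n-- patient level, first 3 recorded hours --\n")
  print(x$patient_table_first)
  print(diagnostic_stats(x$patient_table_first))
  cat("\n-- patient level, 3 pre-onset / closing-day-2 hours --\n")
  print(x$patient_table_last)
  print(diagnostic_stats(x$patient_table_last))
  cat("\n-- window positivity rates --\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
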