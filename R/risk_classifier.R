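#' Classifier configuration
#'
#' All numeric thresholds of the three-class decision matrix in one
#' validated object. The published commercial matrix is proprietary;
#' these defaults are documented stand-ins, tuned once against the
#' default synthetic cohort and then frozen.
#'
#' @param pac_density_risk1 PACs per hour at or above which a segment is
#'   Risk 1.
#' @param dispersion_risk1 normalized-delta-RR dispersion at or above
#'   which a segment is Risk 1.
#' @param dispersion_af per-window dispersion above which a window is
#'   AF-like.
#' @param cv_af per-window coefficient of variation above which a window
#'   is AF-like.
#' @param autocorr_af per-window lag-1 autocorrelation below which a
#'   window is AF-like.
#' @param af_min_duration minimum duration (s) of a reportable AF
#'   stretch.
#' @param af_window,af_step sliding-window length and step (s) of the AF
#'   detector.
#' @param af_vote fraction of covering windows that must be AF-flagged
#'   for a beat to be counted inside a stretch.
#' @param af_irr_delta,af_dense_frac a window is only AF-like when more
#'   than `af_dense_frac` of its normalized successive deltas exceed
#'   `af_irr_delta` in magnitude -- sustained irregularity, as opposed
#'   to a chance cluster of ectopic beats.
#' @param min_beats minimum beats per analyzable hour.
#' @param prematurity,pause premature-beat labeling thresholds
#'   (see [label_premature_beats()]).
#' @param min_rr,max_rr,jump_fraction artifact-removal parameters
#'   (see [clean_artifacts()]).
#' @param k_outlier,cluster_eps,cluster_min,d1,d2,rho0 Poincare pattern
#'   constants (see [poincare_descriptors()]).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(pac_density_risk1 = 30,
                              dispersion_risk1 = 0.03,
                              dispersion_af = 0.08,
                              cv_af = 0.10,
                              autocorr_af = 0.2,
                              af_min_duration = 30,
                              af_window = 60,
                              af_step = 10,
                              af_vote = 0.5,
                              af_irr_delta = 0.04,
                              af_dense_frac = 0.5,
                              min_beats = 1800,
                              prematurity = 0.80,
                              pause = 1.15,
                              min_rr = 300,
                              max_rr = 2200,
                              jump_fraction = 0.5,
                              k_outlier = 3,
                              cluster_eps = 0.025,
                              cluster_min = 15,
                              d1 = 0.03,
                              d2 = 0.08,
                              rho0 = 0.2) {
  cfg <- as.list(environment())
  stopifnot(cfg$af_min_duration > 0, cfg$af_window > 0, cfg$af_step > 0,
            cfg$dispersion_risk1 <= cfg$dispersion_af)
  class(cfg) <- "classifier_config"
  cfg
}

#' Detect AF-like stretches of at least the minimum duration
#'
#' Sliding windows of `af_window` seconds (step `af_step`) are flagged
#' AF-like when, within the window, the coefficient of variation exceeds
#' `cv_af`, the lag-1 autocorrelation falls below `autocorr_af`, and the
#' normalized-delta-RR dispersion exceeds `dispersion_af` -- i.e. the
#' intervals are both irregular and serially uncorrelated. A beat is
#' then inside an AF stretch when at least `af_vote` of the windows
#' covering it are flagged (this per-beat vote localizes the stretch to
#' the irregular beats themselves rather than to the union of flagged
#' windows), and maximal runs of such beats shorter than
#' `af_min_duration` seconds are discarded.
#'
#' @param segment an `hour_segment` or [beat_series()].
#' @param config a [classifier_config()].
#' @return Data frame with one row per reportable stretch: `start_t`,
#'   `end_t` (s), `n_beats`.
#' @export
detect_af_stretches <- function(segment, config = classifier_config()) {
  b <- seg_beats(segment)
  b <- b[b$label != "X", , drop = FALSE]
  empty <- data.frame(start_t = numeric(), end_t = numeric(),
                      n_beats = integer())
  n <- nrow(b)
  if (n < 10L) return(empty)
  t0 <- b$t[1L] - b$rr[1L] / 1000
  t_end <- b$t[n]
  if (t_end - t0 < config$af_window) return(empty)
  starts <- seq(t0, t_end - config$af_window, by = config$af_step)
  flags <- af_window_flags(b$t, b$rr, starts, config$af_window,
                           config$cv_af, config$autocorr_af,
                           config$dispersion_af, config$af_irr_delta,
                           config$af_dense_frac, 10L)
  if (!any(flags)) return(empty)
  # per-beat vote: windows covering beat i are those with start in
  # (t_i - af_window, t_i]
  cumflag <- cumsum(flags)
  hi <- findInterval(b$t, starts)                      # last start <= t_i
  lo <- findInterval(b$t - config$af_window, starts)   # last start <= t_i - W
  covered <- hi - lo
  flagged <- ifelse(hi > 0, cumflag[pmax(hi, 1L)], 0) -
             ifelse(lo > 0, cumflag[pmax(lo, 1L)], 0)
  in_af <- covered > 0 & flagged / pmax(covered, 1L) >= config$af_vote
  runs <- rle(in_af)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  out <- empty
  for (j in which(runs$values)) {
    i1 <- begins[j]; i2 <- ends[j]
    start_t <- b$t[i1] - b$rr[i1] / 1000
    end_t <- b$t[i2]
    if (end_t - start_t >= config$af_min_duration) {
      out <- rbind(out, data.frame(start_t = start_t, end_t = end_t,
                                   n_beats = i2 - i1 + 1L))
    }
  }
  out
}

#' Classify one segment's features into a risk class
#'
#' Rule precedence (highest first):
#' \enumerate{
#' \item Risk 2 (AF present) if any reportable AF stretch exists.
#' \item Risk 1 (elevated paroxysmal-AF risk) if the Poincare pattern is
#'   `SCATTERED`, or the PAC density reaches `pac_density_risk1`, or the
#'   normalized-delta-RR dispersion reaches `dispersion_risk1`.
#' \item Risk 0 (sinus rhythm) otherwise.
#' }
#'
#' @param td a [time_domain()] result.
#' @param pc a [poincare_descriptors()] result.
#' @param em an [ectopy_metrics()] result.
#' @param af a data frame of AF stretches from [detect_af_stretches()].
#' @param config a [classifier_config()].
#' @param patient_id,segment_index identifiers carried into the result.
#' @return A `risk_result` list: `patient_id`, `segment_index`, `risk`
#'   (0/1/2), `positive` (`risk >= 1`), `analyzable`, and `evidence`, a
#'   named list recording every rule evaluated with the value it saw.
#' @export
classify_segment <- function(td, pc, em, af, config = classifier_config(),
                             patient_id = "unknown", segment_index = NA_integer_) {
  if (is_flagged_undefined(td) || is_flagged_undefined(pc)) {
    return(structure(list(patient_id = patient_id,
                          segment_index = segment_index,
                          risk = NA_integer_, positive = NA,
                          analyzable = FALSE, evidence = list()),
                     class = "risk_result"))
  }
  evidence <- list(
    af_stretches = nrow(af),
    af_seconds = if (nrow(af)) sum(af$end_t - af$start_t) else 0,
    pattern = pc$pattern,
    pac_per_hour = em$pac_per_hour,
    dispersion = pc$dispersion,
    autocorr = pc$autocorr,
    cv = td$cv
  )
  risk <- if (nrow(af) > 0L) {
    2L
  } else if (identical(pc$pattern, "SCATTERED") ||
             (!is.na(em$pac_per_hour) &&
              em$pac_per_hour >= config$pac_density_risk1) ||
             pc$dispersion >= config$dispersion_risk1) {
    1L
  } else {
    0L
  }
  structure(list(patient_id = patient_id, segment_index = segment_index,
                 risk = risk, positive = risk >= 1L, analyzable = TRUE,
                 evidence = evidence),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> patient %s hour %s: Risk %s\n",
              x$patient_id, x$segment_index,
              if (is.na(x$risk)) "unanalyzable" else x$risk))
  invisible(x)
}

classify_one_segment <- function(seg, config) {
  td <- time_domain(seg)
  pc <- poincare_descriptors(seg, k_outlier = config$k_outlier,
                             cluster_eps = config$cluster_eps,
                             cluster_min = config$cluster_min,
                             d1 = config$d1, d2 = config$d2,
                             rho0 = config$rho0)
  em <- ectopy_metrics(seg)
  af <- detect_af_stretches(seg, config)
  classify_segment(td, pc, em, af, config,
                   patient_id = seg$patient_id,
                   segment_index = seg$segment_index)
}

#' Classify every analyzable hour of a beat series
#'
#' Runs the per-hour pipeline: artifact removal, premature-beat labeling
#' (only when the series carries no `"A"` annotations), hourly
#' segmentation, feature extraction and risk classification.
#' Classification is deterministic: identical input and configuration
#' give identical output.
#'
#' @param series a [beat_series()].
#' @param config a [classifier_config()].
#' @param hours optional integer vector of 0-based hour indices to
#'   classify (others are skipped; used by the study protocol to avoid
#'   classifying hours outside its windows).
#' @param preprocess run [clean_artifacts()] / [label_premature_beats()]
#'   first (disable if the series is already prepared).
#' @return Data frame with one row per classified segment: `patient_id`,
#'   `segment_index`, `risk`, `positive`, `analyzable`, plus evidence
#'   columns `pattern`, `pac_per_hour`, `dispersion`, `af_stretches`.
#'   Unanalyzable hours are reported with `analyzable = FALSE` and `NA`
#'   risk.
#' @export
classify_series <- function(series, config = classifier_config(),
                            hours = NULL, preprocess = TRUE) {
  stopifnot(inherits(series, "beat_series"))
  if (preprocess) {
    series <- clean_artifacts(series, config$min_rr, config$max_rr,
                              config$jump_fraction)
    if (!any(series$label == "A")) {
      series <- label_premature_beats(series, config$prematurity,
                                      config$pause)
    }
  }
  segs <- segment_hours(series, min_beats = config$min_beats)
  if (!is.null(hours)) {
    segs <- Filter(function(s) s$segment_index %in% hours, segs)
  }
  rows <- lapply(segs, function(seg) {
    if (!seg$analyzable) {
      return(data.frame(patient_id = seg$patient_id,
                        segment_index = seg$segment_index,
                        risk = NA_integer_, positive = NA,
                        analyzable = FALSE, pattern = NA_character_,
                        pac_per_hour = NA_real_, dispersion = NA_real_,
                        af_stretches = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    r <- classify_one_segment(seg, config)
    data.frame(patient_id = r$patient_id, segment_index = r$segment_index,
               risk = r$risk, positive = r$positive,
               analyzable = r$analyzable,
               pattern = r$evidence$pattern %||% NA_character_,
               pac_per_hour = r$evidence$pac_per_hour %||% NA_real_,
               dispersion = r$evidence$dispersion %||% NA_real_,
               af_stretches = r$evidence$af_stretches %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(patient_id = character(), segment_index = integer(),
                      risk = integer(), positive = logical(),
                      analyzable = logical(), pattern = character(),
                      pac_per_hour = numeric(), dispersion = numeric(),
                      af_stretches = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
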