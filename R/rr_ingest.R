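#' Construct a beat series
#'
#' A beat series is the pipeline's raw material: an ordered table of
#' beats, each carrying its time since recording start (`t`, seconds),
#' the preceding inter-beat (RR) interval (`rr`, milliseconds) and a
#' one-character beat label: `"N"` normal sinus, `"A"` atrial premature,
#' `"V"` ventricular premature, `"X"` artifact, `"U"` unlabeled.
#'
#' @param t numeric, elapsed seconds since recording start, strictly
#'   increasing. If `NULL`, reconstructed cumulatively from `rr` with the
#'   first beat at 0.
#' @param rr numeric, RR intervals in milliseconds, all positive.
#' @param label character beat labels, recycled; default `"U"`.
#' @param patient_id opaque identifier.
#' @param start_day postoperative day index of the recording start (1-5).
#' @param start_hour hour-of-day of the recording start (0-24).
#' @param validate check basic invariants (positivity, ordering, labels).
#' @param check_gaps additionally require `diff(t)` to agree with `rr`
#'   within 1 ms; disabled internally after operations such as artifact
#'   removal that legitimately leave gaps.
#' @return A `beat_series`: a data frame with columns `t`, `rr`, `label`
#'   and attributes `patient_id`, `start_day`, `start_hour`.
#' @export
beat_series <- function(t = NULL, rr, label = "U", patient_id = "unknown",
                        start_day = 1L, start_hour = 0, validate = TRUE,
                        check_gaps = validate) {
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop("beat series must be non-empty")
  if (is.null(t)) {
    t <- c(0, cumsum(rr[-1L]) / 1000)
  }
  t <- as.numeric(t)
  if (length(t) != length(rr)) stop("t and rr lengths differ")
  label <- rep_len(as.character(label), length(rr))
  if (validate) {
    if (any(!is.finite(rr)) || any(rr <= 0)) stop("all RR intervals must be positive")
    if (any(diff(t) <= 0)) stop("beat times must be strictly increasing")
    if (!all(label %in% c("N", "A", "V", "X", "U"))) {
      stop("labels must be one of N, A, V, X, U")
    }
    if (!(start_day %in% 1:5)) stop("recording start day must be in 1..5")
    if (check_gaps) {
      # when both columns are supplied, successive time gaps must agree
      # with the stated RR to 1 ms
      gap_ms <- diff(t) * 1000
      if (length(gap_ms) && max(abs(gap_ms - rr[-1L])) > 1 + 1e-9) {
        stop("time column inconsistent with RR intervals (> 1 ms)")
      }
    }
  }
  out <- data.frame(t = t, rr = rr, label = label, stringsAsFactors = FALSE)
  class(out) <- c("beat_series", "data.frame")
  attr(out, "patient_id") <- patient_id
  attr(out, "start_day") <- as.integer(start_day)
  attr(out, "start_hour") <- as.numeric(start_hour)
  out
}

new_beat_series_like <- function(template, t, rr, label) {
  beat_series(t, rr, label,
    patient_id = attr(template, "patient_id") %||% "unknown",
    start_day = attr(template, "start_day") %||% 1L,
    start_hour = attr(template, "start_hour") %||% 0,
    validate = FALSE
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> patient %s, %d beats, %.2f h, start day %d %05.2fh\n",
    attr(x, "patient_id"), nrow(x), (x$t[nrow(x)] - x$t[1L]) / 3600,
    attr(x, "start_day"), attr(x, "start_hour")
  ))
  print(table(x$label))
  invisible(x)
}

#' Read a delimited RR-interval table
#'
#' Reads one beat per row. The native dialect is comma-separated with
#' header `t_s,rr_ms,label`; a bare single-column file of RR values (one
#' per line, no header) is also accepted. When the time column is absent
#' it is reconstructed cumulatively from the RR column (first beat at
#' t = 0). Rows with non-positive RR are rejected with a warning; if more
#' than 5% of rows are rejected the series is considered corrupt.
#'
#' @param path file to read.
#' @param units `"ms"` (default) or `"s"` for the RR column.
#' @param patient_id,start_day,start_hour metadata attached to the series.
#' @param sep field separator.
#' @return A [beat_series()].
#' @export
read_rr_table <- function(path, units = c("ms", "s"), patient_id = "unknown",
                          start_day = 1L, start_hour = 0, sep = ",") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("rr_ingest: file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z_]{2,}", first)
  df <- read.csv(path, header = has_header, sep = sep,
                 stringsAsFactors = FALSE)
  if (!has_header) {
    names(df) <- c("rr_ms", "t_s", "label")[seq_len(ncol(df))]
    if (ncol(df) >= 2L) names(df)[1:2] <- c("t_s", "rr_ms")
  }
  rr_col <- intersect(c("rr_ms", "rr", "RR"), names(df))[1L]
  if (is.na(rr_col)) stop("rr_ingest: no RR column found in ", path)
  rr <- suppressWarnings(as.numeric(df[[rr_col]]))
  if (units == "s") rr <- rr * 1000
  t_col <- intersect(c("t_s", "t", "time"), names(df))[1L]
  t <- if (!is.na(t_col)) suppressWarnings(as.numeric(df[[t_col]])) else NULL
  label <- if ("label" %in% names(df)) as.character(df$label) else "U"
  bad <- !is.finite(rr) | rr <= 0
  if (any(bad)) {
    if (mean(bad) > 0.05) {
      stop("rr_ingest: corrupt series: ", sum(bad), "/", length(bad),
           " rows rejected (> 5%)")
    }
    warning("rr_ingest: rejected ", sum(bad), " rows with non-positive RR")
    rr <- rr[!bad]
    if (!is.null(t)) t <- t[!bad]
    label <- rep_len(label, length(bad))[!bad]
  }
  beat_series(t, rr, label, patient_id = patient_id, start_day = start_day,
              start_hour = start_hour,
              check_gaps = FALSE) # cleaned external files may carry gaps
}

#' Write a beat series as a delimited table
#'
#' Writes the native dialect `t_s,rr_ms,label`, one beat per row, with
#' full (17 significant digit) numeric precision so that
#' write -> read -> write is byte-identical and read-back series compare
#' equal field by field.
#'
#' @param series a [beat_series()].
#' @param path output file.
#' @export
write_rr_table <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("t_s,rr_ms,label", con)
  writeLines(sprintf("%.17g,%.17g,%s", series$t, series$rr, series$label), con)
  invisible(NULL)
}

#' Remove artifact beats
#'
#' Drops beats labeled `"X"`, beats with RR outside `[min_rr, max_rr]`,
#' and beats whose RR deviates from the running median of the ten
#' surrounding plausible beats by more than `jump_fraction` of that
#' median. Hours in which more than 20% of beats are removed are flagged
#' unanalyzable (propagated to [segment_hours()] via the
#' `"unanalyzable_hours"` attribute) rather than silently passed on.
#'
#' @param series a [beat_series()].
#' @param min_rr,max_rr plausible RR range in ms.
#' @param jump_fraction maximum tolerated relative deviation from the
#'   local running median.
#' @return The cleaned series; attributes `n_removed` (count) and
#'   `unanalyzable_hours` (0-based hour indices with > 20% removal).
#' @export
clean_artifacts <- function(series, min_rr = 300, max_rr = 2200,
                            jump_fraction = 0.5) {
  stopifnot(inherits(series, "beat_series"), min_rr < max_rr)
  rr <- series$rr
  drop <- series$label == "X" | rr < min_rr | rr > max_rr
  # running median over the surrounding plausible (non-dropped) beats
  ok <- which(!drop)
  if (length(ok) >= 11L) {
    med_ok <- runmed(rr[ok], 11L, endrule = "median")
    # each beat takes the local median at its nearest plausible neighbour
    pos <- findInterval(seq_along(rr), ok, all.inside = TRUE)
    med <- med_ok[pos]
    drop <- drop | abs(rr - med) > jump_fraction * med
  }
  hour <- floor(series$t / 3600)
  rem_frac <- tapply(drop, hour, mean)
  bad_hours <- as.integer(names(rem_frac)[rem_frac > 0.20])
  out <- new_beat_series_like(series, series$t[!drop], rr[!drop],
                              series$label[!drop])
  attr(out, "n_removed") <- sum(drop)
  attr(out, "unanalyzable_hours") <-
    sort(unique(c(attr(series, "unanalyzable_hours"), bad_hours)))
  out
}

#' Split a beat series into hourly segments
#'
#' Beats are partitioned into half-open hourly bins
#' `[3600 k, 3600 (k + 1))` anchored at recording start, so every beat
#' falls in exactly one segment and a beat at exactly t = 3600 s belongs
#' to segment 1. Segments with fewer than `min_beats` beats, or flagged
#' by [clean_artifacts()], are marked unanalyzable.
#'
#' @param series a [beat_series()].
#' @param min_beats minimum beat count for an analyzable hour.
#' @return A list of `hour_segment` objects (possibly empty), each with
#'   fields `patient_id`, `segment_index` (0-based), `beats`, `n_beats`,
#'   `coverage_s`, `analyzable`.
#' @export
segment_hours <- function(series, min_beats = 1800) {
  stopifnot(inherits(series, "beat_series"))
  if (nrow(series) == 0L) return(list())
  hour <- floor(series$t / 3600)
  bad <- attr(series, "unanalyzable_hours") %||% integer()
  idx <- sort(unique(hour))
  lapply(idx, function(k) {
    sel <- hour == k
    beats <- series[sel, , drop = FALSE]
    new_hour_segment(
      patient_id = attr(series, "patient_id"),
      segment_index = as.integer(k),
      beats = beats,
      min_beats = min_beats,
      flagged_bad = k %in% bad
    )
  })
}

new_hour_segment <- function(patient_id, segment_index, beats, min_beats = 1800,
                             flagged_bad = FALSE) {
  coverage <- if (nrow(beats) >= 2L) {
    min(3600, beats$t[nrow(beats)] - beats$t[1L] + beats$rr[1L] / 1000)
  } else 0
  structure(
    list(
      patient_id = patient_id,
      segment_index = as.integer(segment_index),
      beats = beats,
      n_beats = nrow(beats),
      coverage_s = coverage,
      analyzable = nrow(beats) >= min_beats && !flagged_bad
    ),
    class = "hour_segment"
  )
}

#' @export
print.hour_segment <- function(x, ...) {
  cat(sprintf("<hour_segment> patient %s hour %d: %d beats (%s)\n",
              x$patient_id, x$segment_index, x$n_beats,
              if (x$analyzable) "analyzable" else "unanalyzable"))
  invisible(x)
}

# make an hour_segment directly from a series (tests, spectral windows)
as_hour_segment <- function(series, segment_index = 0L, min_beats = 1800) {
  new_hour_segment(attr(series, "patient_id") %||% "unknown",
                   segment_index, as.data.frame(series), min_beats)
}

#' Label premature atrial beats
#'
#' Rule-based relabeling for series without native annotations: a beat
#' whose RR is shorter than `prematurity` times the local running median
#' (11-beat window) and whose successor RR exceeds `pause` times that
#' median is relabeled `"A"` (premature beat followed by a compensatory
#' pause). Beats already labeled `A`, `V` or `X` are untouched.
#'
#' @param series a [beat_series()].
#' @param prematurity fraction of the local median RR below which a beat
#'   is premature.
#' @param pause fraction of the local median RR the following interval
#'   must exceed.
#' @return The relabeled series; attribute `n_relabel` gives the count.
#' @export
label_premature_beats <- function(series, prematurity = 0.80, pause = 1.15) {
  stopifnot(inherits(series, "beat_series"))
  rr <- series$rr
  lab <- series$label
  n <- length(rr)
  if (n < 12L) return(series)
  med <- runmed(rr, 11L, endrule = "median")
  cand <- seq_len(n - 1L)
  hit <- lab[cand] %in% c("N", "U") &
    rr[cand] < prematurity * med[cand] &
    rr[cand + 1L] > pause * med[cand]
  lab[cand][hit] <- "A"
  out <- new_beat_series_like(series, series$t, rr, lab)
  attr(out, "unanalyzable_hours") <- attr(series, "unanalyzable_hours")
  attr(out, "n_relabel") <- sum(hit)
  out
}
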