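seg_beats <- function(x) {
  if (inherits(x, "hour_segment")) x$beats
  else if (inherits(x, "beat_series")) as.data.frame(x)
  else if (is.numeric(x)) data.frame(t = c(0, cumsum(x[-length(x)]) / 1000),
                                     rr = x, label = "N")
  else stop("expected an hour_segment, beat_series or numeric RR vector")
}

undefined_result <- function(template) {
  out <- lapply(template, function(x) NA_real_)
  attr(out, "undefined") <- TRUE
  out
}

#' Time-domain HRV descriptors over normal-to-normal intervals
#'
#' Computes the classic linear indices over NN intervals, i.e. RR
#' intervals whose opening and closing beats are both sinus beats:
#' `mean_nn` and `sdnn` (population standard deviation, ms), `rmssd`
#' (root mean square of successive NN differences, ms), `pnn50`
#' (percentage of successive NN differences with |d| > 50 ms), and
#' `cv = sdnn/mean_nn`. Successive differences are only taken between
#' index-adjacent NN intervals so that excluded (ectopic/artifact) beats
#' never contribute a spurious jump.
#'
#' @param segment an `hour_segment`, [beat_series()] or numeric RR vector.
#' @param assume_unlabeled_normal treat `"U"` beats as sinus (default):
#'   unannotated recordings are presumed sinus unless flagged otherwise.
#' @return A `time_domain_hrv` list: `mean_nn`, `sdnn`, `rmssd`, `pnn50`,
#'   `cv`, `n_nn`. Fewer than 2 NN intervals gives an undefined-flagged
#'   result (all `NA`, attribute `undefined`), never silent zeros.
#' @export
time_domain <- function(segment, assume_unlabeled_normal = TRUE) {
  b <- seg_beats(segment)
  normal <- c("N", if (assume_unlabeled_normal) "U")
  n <- nrow(b)
  if (n < 3L) return(structure(undefined_result(
    list(mean_nn = 0, sdnn = 0, rmssd = 0, pnn50 = 0, cv = 0, n_nn = 0)),
    class = "time_domain_hrv"))
  # NN interval i: beats i-1 and i both normal; the first interval's
  # opening beat is unrecorded and presumed normal if beat 1 is
  is_nn <- c(b$label[1L] %in% normal,
             b$label[-n] %in% normal & b$label[-1L] %in% normal)
  nn <- b$rr[is_nn]
  if (length(nn) < 2L) {
    return(structure(undefined_result(
      list(mean_nn = 0, sdnn = 0, rmssd = 0, pnn50 = 0, cv = 0, n_nn = 0)),
      class = "time_domain_hrv"))
  }
  # successive differences between index-adjacent NN intervals only
  adj <- which(is_nn[-n] & is_nn[-1L])
  d <- b$rr[adj + 1L] - b$rr[adj]
  mean_nn <- mean(nn)
  sdnn <- psd(nn)
  rmssd <- if (length(d)) sqrt(mean(d^2)) else NA_real_
  pnn50 <- if (length(d)) 100 * mean(abs(d) > 50) else NA_real_
  structure(
    list(mean_nn = mean_nn, sdnn = sdnn, rmssd = rmssd, pnn50 = pnn50,
         cv = sdnn / mean_nn, n_nn = length(nn)),
    class = "time_domain_hrv"
  )
}

#' Normalized successive RR differences
#'
#' For each consecutive beat pair the dimensionless quantity
#' \deqn{n_i = (R_i - R_{i+1}) / (R_i + R_{i+1})}
#' which is strictly inside (-1, 1) for positive intervals and
#' antisymmetric under reversal of the pair. Pairs adjacent to an
#' artifact (`"X"`) beat are excluded.
#'
#' @param segment an `hour_segment`, [beat_series()] or numeric RR vector.
#' @return Numeric vector, one value per usable consecutive pair.
#' @export
normalized_delta_rr <- function(segment) {
  b <- seg_beats(segment)
  n <- nrow(b)
  if (n < 2L) stop("need at least 2 beats")
  keep <- b$label[-n] != "X" & b$label[-1L] != "X"
  a <- b$rr[-n][keep]
  z <- b$rr[-1L][keep]
  (a - z) / (a + z)
}

#' Poincare-plot descriptors and qualitative pattern
#'
#' Quantitative descriptors of the Poincare (Lorenz) plot of each RR
#' interval against its successor, computed over all usable pairs
#' (ectopic-adjacent pairs included -- rhythm irregularity is the signal
#' here, unlike the sinus-only time-domain indices):
#' \itemize{
#' \item `sd1 = sqrt(Var(dRR)/2)`, the dispersion across the identity
#'   line; `sd2 = sqrt(2 Var(RR) - Var(dRR)/2)` (floored at 0), the
#'   dispersion along it; population variances, so
#'   `sd1^2 + sd2^2 = 2 sdnn^2` exactly.
#' \item `dispersion`: the standard deviation of the normalized
#'   successive differences ([normalized_delta_rr()]), and
#'   `outlier_fraction`: the fraction of those values farther than
#'   `k_outlier` dispersions from their mean.
#' \item `cluster_count`: one-dimensional density grouping of the
#'   normalized differences (sorted values split at gaps wider than
#'   `cluster_eps`; groups of at least `cluster_min` points count) --
#'   ectopic couplings and compensatory pauses form satellite arms that
#'   appear as extra clusters.
#' \item `pattern`: a quantitative surrogate for the classic visual
#'   classes. Precedence: `DISPERSED` (full dispersion, AF-like) if
#'   `dispersion >= d2` and lag-1 autocorrelation `<= rho0`; else
#'   `SCATTERED` (main cluster with arms, ectopy on a correlated sinus
#'   baseline) if (`cluster_count >= 2` or `outlier_fraction >= 0.02`)
#'   and autocorrelation `> rho0`; else `COMET` (single tight cluster,
#'   sinus rhythm).
#' }
#'
#' @param segment an `hour_segment`, [beat_series()] or numeric RR vector.
#' @param k_outlier outlier distance in units of `dispersion`.
#' @param cluster_eps gap width (normalized-delta units) separating
#'   clusters.
#' @param cluster_min minimum points per counted cluster.
#' @param d1 dispersion below which a single-cluster plot is a comet.
#' @param d2 dispersion at or above which a decorrelated plot is
#'   dispersed.
#' @param rho0 lag-1 autocorrelation dividing correlated sinus dynamics
#'   from AF-like decorrelation.
#' @return A `poincare_descriptors` list with fields `sd1`, `sd2`,
#'   `sd_ratio`, `sdnn_all`, `dispersion`, `outlier_fraction`,
#'   `cluster_count`, `autocorr`, `pattern`, `n_pairs` and the vector
#'   `norm_delta_rr`. Fewer than 100 usable pairs gives an
#'   undefined-flagged result.
#' @export
poincare_descriptors <- function(segment, k_outlier = 3, cluster_eps = 0.025,
                                 cluster_min = 15, d1 = 0.03, d2 = 0.08,
                                 rho0 = 0.2) {
  b <- seg_beats(segment)
  n <- nrow(b)
  keep <- if (n >= 2L) b$label[-n] != "X" & b$label[-1L] != "X" else logical()
  if (sum(keep) < 100L) {
    out <- undefined_result(list(
      sd1 = 0, sd2 = 0, sd_ratio = 0, sdnn_all = 0, dispersion = 0,
      outlier_fraction = 0, cluster_count = 0, autocorr = 0, n_pairs = 0))
    out$pattern <- NA_character_
    out$norm_delta_rr <- numeric()
    class(out) <- "poincare_descriptors"
    return(out)
  }
  x <- b$rr[-n][keep]
  y <- b$rr[-1L][keep]
  d <- y - x
  rr_all <- b$rr[b$label != "X"]
  var_rr <- pvar(rr_all)
  var_d <- pvar(d)
  sd1 <- sqrt(var_d / 2)
  sd2 <- sqrt(max(0, 2 * var_rr - var_d / 2))
  nd <- (x - y) / (x + y)
  dispersion <- psd(nd)
  outlier_fraction <- if (dispersion > 0) {
    mean(abs(nd - mean(nd)) > k_outlier * dispersion)
  } else 0
  cluster_count <- count_gap_clusters(nd, cluster_eps, cluster_min)
  r1 <- lag1_autocorr(rr_all)
  pattern <- if (dispersion >= d2 && r1 <= rho0) {
    "DISPERSED"
  } else if ((cluster_count >= 2L || outlier_fraction >= 0.02) && r1 > rho0) {
    "SCATTERED"
  } else {
    "COMET"
  }
  structure(
    list(sd1 = sd1, sd2 = sd2,
         sd_ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
         sdnn_all = sqrt(var_rr),
         dispersion = dispersion, outlier_fraction = outlier_fraction,
         cluster_count = cluster_count, autocorr = r1, pattern = pattern,
         n_pairs = length(nd), norm_delta_rr = nd),
    class = "poincare_descriptors"
  )
}

# 1-D density grouping: sort, split at gaps > eps, count groups with
# >= min_pts members
count_gap_clusters <- function(x, eps, min_pts) {
  if (length(x) == 0L) return(0L)
  s <- sort(x)
  grp <- cumsum(c(1, diff(s) > eps))
  sum(tabulate(grp) >= min_pts)
}

#' Spectral HRV band powers (Lomb-Scargle)
#'
#' Band powers of the NN tachogram estimated with the Lomb-Scargle
#' least-squares periodogram evaluated directly on the irregular beat
#' times, so ectopic and artifact beats are simply excluded without
#' interpolation or resampling. Bands follow the conventional
#' short-term-HRV division: LF 0.04-0.15 Hz, HF 0.15-0.40 Hz. Powers are
#' returned in ms^2 (a pure modulation tone of amplitude `a` in one band
#' yields band power close to `a^2/2`, its variance).
#'
#' @param segment an `hour_segment`, [beat_series()] or numeric RR vector.
#' @param ofac frequency oversampling factor of the periodogram grid.
#' @param lf,hf band limits in Hz.
#' @param assume_unlabeled_normal treat `"U"` beats as sinus.
#' @return A `spectral_hrv` list: `lf_power`, `hf_power` (ms^2) and
#'   `lf_hf` (`NA` with an undefined flag when `hf_power` is 0). Fewer
#'   than 300 NN intervals or a span under 5 minutes gives an
#'   undefined-flagged result.
#' @export
spectral_power <- function(segment, ofac = 2, lf = c(0.04, 0.15),
                           hf = c(0.15, 0.40),
                           assume_unlabeled_normal = TRUE) {
  b <- seg_beats(segment)
  normal <- c("N", if (assume_unlabeled_normal) "U")
  keep <- b$label %in% normal
  t <- b$t[keep]
  y <- b$rr[keep]
  span <- if (length(t) >= 2L) t[length(t)] - t[1L] else 0
  if (length(y) < 300L || span < 300) {
    out <- undefined_result(list(lf_power = 0, hf_power = 0, lf_hf = 0))
    class(out) <- "spectral_hrv"
    return(out)
  }
  if (psd(y) < 1e-9) {
    return(structure(list(lf_power = 0, hf_power = 0, lf_hf = NA_real_),
                     class = "spectral_hrv"))
  }
  df <- 1 / (span * ofac)
  freq <- seq(lf[1L], hf[2L], by = df)
  p <- lomb_power(t, y, freq)
  scale <- 2 / (length(y) * ofac)
  lf_power <- sum(p[freq >= lf[1L] & freq < lf[2L]]) * scale
  hf_power <- sum(p[freq >= hf[1L] & freq <= hf[2L]]) * scale
  lf_hf <- if (hf_power > 1e-12) lf_power / hf_power else NA_real_
  out <- list(lf_power = lf_power, hf_power = hf_power, lf_hf = lf_hf)
  if (is.na(lf_hf)) attr(out, "undefined") <- TRUE
  structure(out, class = "spectral_hrv")
}

#' Atrial-ectopy metrics
#'
#' Counts of `"A"`-labeled beats in a segment: total count, density per
#' hour (scaled by the actually covered duration) and per 1000 beats,
#' and the longest consecutive run of atrial premature beats.
#'
#' @param segment an `hour_segment` or [beat_series()].
#' @return An `ectopy_metrics` list: `pac_count`, `pac_per_hour`,
#'   `pac_per_1000`, `max_pac_run`, `n_beats`.
#' @export
ectopy_metrics <- function(segment) {
  b <- seg_beats(segment)
  is_a <- b$label == "A"
  coverage <- if (inherits(segment, "hour_segment")) segment$coverage_s
              else if (nrow(b) >= 2L) b$t[nrow(b)] - b$t[1L] + b$rr[1L] / 1000
              else 0
  runs <- rle(is_a)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  structure(
    list(pac_count = sum(is_a),
         pac_per_hour = if (coverage > 0) sum(is_a) / coverage * 3600 else NA_real_,
         pac_per_1000 = if (nrow(b) > 0) sum(is_a) / nrow(b) * 1000 else NA_real_,
         max_pac_run = as.integer(max_run),
         n_beats = nrow(b)),
    class = "ectopy_metrics"
  )
}

#' Render a Poincare scatter plot
#'
#' Plots each preceding RR interval (abscissa) against the current one
#' (ordinate) for visual inspection of the comet / scattered / dispersed
#' shape.
#'
#' @param segment an `hour_segment` or [beat_series()].
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_poincare <- function(segment, main = NULL, ...) {
  b <- seg_beats(segment)
  n <- nrow(b)
  keep <- b$label[-n] != "X" & b$label[-1L] != "X"
  graphics::plot(b$rr[-n][keep], b$rr[-1L][keep],
                 xlab = "preceding RR (ms)", ylab = "current RR (ms)",
                 pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue4", 0.4),
                 main = main %||% "Poincaré plot", asp = 1, ...)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  invisible(NULL)
}
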