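# Naive-loop oracles, independent of the vectorized implementations.

# time-domain indices over NN intervals, written as explicit loops
td_oracle <- function(rr, label = rep("N", length(rr))) {
  n <- length(rr)
  ok <- function(i) {
    if (i == 1) label[1] %in% c("N", "U")
    else label[i - 1] %in% c("N", "U") && label[i] %in% c("N", "U")
  }
  nn <- c()
  for (i in 1:n) if (ok(i)) nn <- c(nn, rr[i])
  m <- 0
  for (v in nn) m <- m + v
  m <- m / length(nn)
  s2 <- 0
  for (v in nn) s2 <- s2 + (v - m)^2
  s2 <- s2 / length(nn)
  dd <- c()
  for (i in 1:(n - 1)) {
    if (ok(i) && ok(i + 1)) dd <- c(dd, rr[i + 1] - rr[i])
  }
  r2 <- 0
  n50 <- 0
  for (v in dd) {
    r2 <- r2 + v^2
    if (abs(v) > 50) n50 <- n50 + 1
  }
  list(mean_nn = m, sdnn = sqrt(s2), rmssd = sqrt(r2 / length(dd)),
       pnn50 = 100 * n50 / length(dd), n_nn = length(nn))
}

nd_oracle <- function(rr) {
  out <- numeric(length(rr) - 1)
  for (i in seq_len(length(rr) - 1)) {
    out[i] <- (rr[i] - rr[i + 1]) / (rr[i] + rr[i + 1])
  }
  out
}

# enumeration oracle for 2x2 diagnostics: reconstruct individual
# labelled records and count
diag_oracle <- function(tp, fp, fn, tn) {
  disease <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
  test <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  list(
    sens = sum(test & disease) / sum(disease),
    spec = sum(!test & !disease) / sum(!disease),
    ppv = sum(test & disease) / sum(test),
    npv = sum(!test & !disease) / sum(!test),
    accuracy = mean(test == disease)
  )
}

# constant-RR series helper (fast to build, every hour analyzable)
constant_series <- function(hours, rr = 800, patient_id = "const") {
  n <- ceiling(hours * 3600 * 1000 / rr) + 1L
  beat_series(rr = rep(rr, n), label = "N", patient_id = patient_id)
}

# an hour of sinus with an AF insert of the given duration at t_ins
sinus_with_af_insert <- function(dur_af, t_ins = 1800, seed = 3) {
  base <- simulate_sinus(sinus_params(), 3600, seed = seed)
  af <- simulate_af(af_params(min_duration = 10), dur_af, seed = seed + 1,
                    t0 = t_ins)
  b <- rbind(as.data.frame(base[base$t < t_ins, ]),
             as.data.frame(af),
             transform(as.data.frame(base[base$t >= t_ins, ]),
                       t = t + dur_af))
  beat_series(b$t, b$rr, b$label, validate = FALSE)
}
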