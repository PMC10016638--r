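test_that("time_domain handles the degenerate and alternating cases", {
  td <- time_domain(rep(800, 3600))
  expect_equal(td$mean_nn, 800)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)
  expect_equal(td$cv, 0)

  td2 <- time_domain(rep(c(800, 860), 300))
  expect_equal(td2$rmssd, 60)
  expect_equal(td2$pnn50, 100)
  expect_equal(td2$cv, td2$sdnn / td2$mean_nn)

  # too few NN pairs: undefined flag, not zeros
  short <- beat_series(rr = c(800, 810, 820), label = c("A", "V", "A"),
                       validate = FALSE)
  out <- time_domain(short)
  expect_true(isTRUE(attr(out, "undefined")))
  expect_true(is.na(out$sdnn))
})

test_that("time_domain equals the naive-loop oracle on random segments", {
  set.seed(501)
  for (k in 1:25) {
    n <- sample(300:900, 1)
    rr <- 600 + 300 * runif(n) + 40 * sin(seq_len(n) / 7)
    label <- sample(c("N", "A", "V"), n, replace = TRUE,
                    prob = c(0.92, 0.05, 0.03))
    or <- td_oracle(rr, label)
    td <- time_domain(beat_series(rr = rr, label = label, validate = FALSE))
    expect_equal(td$mean_nn, or$mean_nn, tolerance = 1e-9)
    expect_equal(td$sdnn, or$sdnn, tolerance = 1e-9)
    expect_equal(td$rmssd, or$rmssd, tolerance = 1e-9)
    expect_equal(td$pnn50, or$pnn50, tolerance = 1e-9)
    expect_equal(td$n_nn, or$n_nn)
  }
})

test_that("normalized_delta_rr matches its definition", {
  expect_equal(normalized_delta_rr(c(800, 800)), 0)
  expect_equal(normalized_delta_rr(c(1000, 500)), 1 / 3)
  # antisymmetry under pair reversal
  set.seed(77)
  for (k in 1:20) {
    pair <- runif(2, 400, 1200)
    expect_equal(normalized_delta_rr(pair), -normalized_delta_rr(rev(pair)))
  }
  # exact element-wise agreement with the loop oracle
  s <- simulate_sinus(sinus_params(), 600, seed = 13)
  expect_identical(normalized_delta_rr(s), nd_oracle(s$rr))
  # all values strictly inside (-1, 1)
  nd <- normalized_delta_rr(simulate_af(af_params(), 600, seed = 14))
  expect_true(all(abs(nd) < 1))
  # artifact-adjacent pairs are excluded
  lab <- rep("N", 10)
  lab[5] <- "X"
  sx <- beat_series(rr = rep(800, 10), label = lab)
  expect_length(normalized_delta_rr(sx), 7L) # 9 pairs - 2 X-adjacent
})

test_that("poincare closed forms: alternating and constant series", {
  rr <- rep(c(800, 860), 1201)[1:2401] # 2400 pairs, deltas exactly balanced
  pc <- poincare_descriptors(rr)
  expect_equal(pc$sd1, sqrt(1800), tolerance = 1e-9)
  expect_lt(pc$sd2, 1)

  pc0 <- poincare_descriptors(rep(800, 500))
  expect_equal(pc0$sd1, 0)
  expect_equal(pc0$sd2, 0)
  expect_equal(pc0$dispersion, 0)
  expect_identical(pc0$pattern, "COMET")
})

test_that("poincare identities hold across random segments", {
  set.seed(601)
  for (k in 1:100) {
    n <- sample(150:400, 1)
    rr <- 700 + cumsum(rnorm(n, 0, 12))
    rr <- pmax(rr, 350)
    pc <- poincare_descriptors(rr)
    expect_equal(pc$sd1^2 + pc$sd2^2, 2 * pc$sdnn_all^2,
                 tolerance = 1e-6)
  }
})

test_that("sd1 equals rmssd/sqrt(2) for zero-mean successive differences", {
  set.seed(602)
  for (k in 1:5) {
    d <- rnorm(250, 0, 15)
    d <- as.vector(rbind(d, -d)) # paired +/-: exactly zero-mean, bounded
    rr <- 800 + cumsum(c(0, d))
    stopifnot(all(rr > 300))
    td <- time_domain(rr)
    pc <- poincare_descriptors(rr)
    expect_equal(pc$sd1, td$rmssd / sqrt(2), tolerance = 1e-9)
  }
})

test_that("i.i.d. RR gives sd1 ~ sd2 ~ sdnn and a DISPERSED pattern", {
  set.seed(603)
  rr <- rgamma(6000, shape = 25, scale = 600 / 25) # cv 0.2
  pc <- poincare_descriptors(rr)
  expect_lt(abs(pc$sd1 / pc$sd2 - 1), 0.05)
  expect_lt(abs(pc$sd1 / pc$sdnn_all - 1), 0.05)
  expect_identical(pc$pattern, "DISPERSED")
  expect_lt(abs(pc$autocorr), 0.05)
})

test_that("spectral_power recovers tone structure", {
  flat <- spectral_power(rep(800, 600))
  expect_lt(flat$lf_power, 1e-6)
  expect_lt(flat$hf_power, 1e-6)

  hf_tone <- simulate_sinus(sinus_params(a_lf = 0, a_hf = 30, noise_sd = 2),
                            900, seed = 21)
  sp <- spectral_power(hf_tone)
  expect_gt(sp$hf_power / (sp$lf_power + sp$hf_power), 0.9)
  # a tone of amplitude a carries variance a^2/2 = 450 ms^2
  expect_equal(sp$hf_power, 450, tolerance = 0.15)

  lf_tone <- simulate_sinus(sinus_params(a_lf = 30, a_hf = 0, noise_sd = 2),
                            900, seed = 22)
  sp_lf <- spectral_power(lf_tone)
  expect_gt(sp_lf$lf_power / (sp_lf$lf_power + sp_lf$hf_power), 0.9)

  two <- simulate_sinus(sinus_params(a_lf = 30, a_hf = 30, noise_sd = 2),
                        1800, seed = 23)
  sp2 <- spectral_power(two)
  expect_gt(sp2$lf_hf, 0.7)
  expect_lt(sp2$lf_hf, 1.4)

  short <- spectral_power(rep(c(780, 820), 40))
  expect_true(isTRUE(attr(short, "undefined")))
})

test_that("ectopy_metrics counts PACs, density and runs", {
  z <- ectopy_metrics(beat_series(rr = rep(800, 100), label = "N"))
  expect_equal(z$pac_count, 0L)
  expect_equal(z$max_pac_run, 0L)

  lab <- rep("N", 4500)
  lab[seq(100, 4500, length.out = 12)] <- "A"
  s <- beat_series(rr = rep(800, 4500), label = lab)
  em <- ectopy_metrics(as_hour <- segment_hours(s)[[1]])
  expect_equal(em$pac_count, sum(segment_hours(s)[[1]]$beats$label == "A"))
  expect_equal(em$max_pac_run, 1L)

  lab2 <- rep("N", 200)
  lab2[50:51] <- "A" # one couplet
  em2 <- ectopy_metrics(beat_series(rr = rep(800, 200), label = lab2))
  expect_equal(em2$pac_count, 2L)
  expect_equal(em2$max_pac_run, 2L)
  expect_equal(em2$pac_per_1000, 10)
})
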