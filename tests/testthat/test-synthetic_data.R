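test_that("generators are pure functions of (params, seed)", {
  a <- simulate_sinus(sinus_params(), 300, seed = 1)
  b <- simulate_sinus(sinus_params(), 300, seed = 1)
  expect_identical(a, b)
  af1 <- simulate_af(af_params(), 120, seed = 2)
  af2 <- simulate_af(af_params(), 120, seed = 2)
  expect_identical(af1, af2)
  p <- patient_profile("R", group = "I", onset_day = 1, onset_hour = 8,
                       pac_base_rate = 12, af_duration = 1800)
  r1 <- simulate_patient(p, seed = 3, recording_days = 1)
  r2 <- simulate_patient(p, seed = 3, recording_days = 1)
  expect_identical(r1$series, r2$series)
})

test_that("deterministic sinus limit and floor guard", {
  s <- simulate_sinus(sinus_params(a_lf = 0, a_hf = 0, noise_sd = 0), 120)
  expect_equal(time_domain(s)$sdnn, 0)
  expect_equal(unique(s$rr), 800)
  expect_error(simulate_sinus(sinus_params(mean_rr = 320, a_lf = 15,
                                           a_hf = 10), 60),
               "floor")
})

test_that("inject_pacs respects rate, labels and ground truth", {
  s <- simulate_sinus(sinus_params(), 3600, seed = 11)
  expect_identical(inject_pacs(s, 0, seed = 1)$rr, s$rr)

  out <- inject_pacs(s, 60, seed = 12)
  truth <- attr(out, "pac_truth")
  # count within the central 99% Poisson interval for rate 60
  expect_gte(nrow(truth), qpois(0.005, 60))
  expect_lte(nrow(truth), qpois(0.995, 60))
  expect_true(all(out$label[truth$index] == "A"))
  expect_equal(sum(out$label == "A"), nrow(truth))
  # injected beats are genuinely premature with a following pause
  med <- stats::runmed(out$rr, 11)
  expect_true(all(out$rr[truth$index] < 0.75 * med[truth$index]))
  expect_error(inject_pacs(s, 1e5, seed = 13), "overlap|high")
})

test_that("simulate_af has the designed dispersion and no serial correlation", {
  af <- simulate_af(af_params(), 600, seed = 21)
  cv <- sd(af$rr) / mean(af$rr)
  expect_gte(cv, 0.17)
  expect_lte(cv, 0.23)
  r1 <- hrvaf:::lag1_autocorr(af$rr)
  expect_lt(abs(r1), 0.05)
  expect_true(all(af$label == "U"))
  pc <- poincare_descriptors(af)
  expect_identical(pc$pattern, "DISPERSED")
  expect_error(simulate_af(af_params(), 10), "minimum")
})

test_that("simulate_patient builds the stated pre-onset ramp", {
  p <- patient_profile("RMP", group = "I", onset_day = 2, onset_hour = 4,
                       pac_base_rate = 10, ramp_hours = 3, ramp_pac_mult = 4,
                       af_duration = 1800)
  rec <- simulate_patient(p, seed = 31, recording_days = 2)
  expect_true(all(rec$series$t[rec$series$label == "U"] >
                  rec$truth$af_start - 1))
  # PAC density in the last 3 pre-onset hours exceeds the first 3 hours
  pac_t <- rec$truth$pac_t
  on <- rec$truth$af_start
  first3 <- sum(pac_t < 3 * 3600) / 3
  last3 <- sum(pac_t >= on - 3 * 3600 & pac_t < on) / 3
  expect_gt(last3, first3)

  # control patients have no AF beats at all
  p2 <- patient_profile("CTL", group = "II", pac_base_rate = 10)
  rec2 <- simulate_patient(p2, seed = 32, recording_days = 1)
  expect_false(any(rec2$series$label == "U"))
  expect_true(is.na(rec2$onset_s))

  p3 <- patient_profile("BAD", group = "I", onset_day = 4, onset_hour = 2,
                        pac_base_rate = 10)
  expect_error(simulate_patient(p3, seed = 33, recording_days = 2),
               "outside")
})

test_that("cohort profiles match the stated prevalence and onset peak", {
  cfg <- cohort_config(n_patients = 114)
  set.seed(cfg$master_seed)
  profiles <- hrvaf:::draw_cohort_profiles(cfg)
  n_case <- sum(vapply(profiles, function(p) p$group == "I", TRUE))
  expect_gte(n_case, qbinom(0.005, 114, 0.28))
  expect_lte(n_case, qbinom(0.995, 114, 0.28))

  cfg500 <- cohort_config(n_patients = 500, prevalence = 0.99,
                          master_seed = 555)
  set.seed(cfg500$master_seed)
  pr500 <- hrvaf:::draw_cohort_profiles(cfg500)
  days <- vapply(pr500, function(p) p$onset_day, 0L)
  days <- days[!is.na(days)]
  expect_equal(unname(which.max(tabulate(days, 5))), 2L)
})

test_that("simulate_cohort is reproducible and honors degenerate prevalence", {
  cfg <- cohort_config(n_patients = 5, recording_days = 1,
                       master_seed = 777)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$patients[[1]]$series, c2$patients[[1]]$series)

  c0 <- simulate_cohort(cohort_config(n_patients = 4, prevalence = 0,
                                      recording_days = 1, master_seed = 778))
  expect_true(all(c0$truth$group == "II"))
  expect_true(all(is.na(c0$truth$onset_s)))
})
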