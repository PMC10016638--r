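# The default synthetic cohort evaluation is the backbone of several
# acceptance criteria and takes minutes; compute it once per test run.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_report <- function() {
  if (is.null(.cohort_cache$report)) {
    .cohort_cache$report <- evaluate_cohort(cohort_config(),
                                            classifier_config(),
                                            spectral = TRUE)
  }
  .cohort_cache$report
}
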