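# The full-size study cohort (126 cases / 121 controls, 120 s at 30 Hz)
# with its inference and classification results, computed once per test run
# and shared by the tests that exercise cohort-level claims.
study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(cohort = cohort_config(seed = 1))
      # the spine channel is identically zero in the spine-relative frame,
      # so PCA warns about dropping it; stepwise may warn on separation
      cache <<- suppressWarnings(run_analysis(cfg))
    }
    cache
  }
})
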