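# One mid-sized synthetic cohort with extracted features, built lazily and
# shared across test files to keep the suite inside its time budget.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_cohort_features(cohort_config(n_patients = 800,
                                                    seed = 77))
    cache
  }
})
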