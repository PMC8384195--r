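# Image-based cohort generation and extraction are the slow steps; cache one
# default cohort (fixed seed) for reuse across test files.
.cohort_cache <- new.env(parent = emptyenv())

get_image_cohort <- function() {
  if (is.null(.cohort_cache$cohort))
    .cohort_cache$cohort <- generate_cohort(cohort_spec(seed = 11))
  .cohort_cache$cohort
}

get_image_features <- function() {
  if (is.null(.cohort_cache$recs))
    .cohort_cache$recs <- extract_cohort_features(get_image_cohort())
  .cohort_cache$recs
}
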