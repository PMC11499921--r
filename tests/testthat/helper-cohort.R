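# The scaled default cohort (n = 10 patients, 64 x 64 sheets, 10-s
# post-pacing observation) is expensive; it is evaluated once per test run
# and shared by every test that needs cohort-level results.

.cohort_cache <- new.env(parent = emptyenv())

get_cohort_results <- function() {
  if (is.null(.cohort_cache$res)) {
    cfg <- load_config()
    .cohort_cache$out_dir <- file.path(tempdir(), "aftwin-cohort")
    .cohort_cache$res <- run_pipeline(cfg, out_dir = .cohort_cache$out_dir,
                                      biomarkers = TRUE, progress = FALSE)
  }
  .cohort_cache$res
}
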