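# one small synthetic study shared by the pipeline and acceptance tests;
# built once per test run
study_cache <- new.env(parent = emptyenv())

cached_study <- function(dwi = FALSE) {
  key <- if (dwi) "with_dwi" else "masks_only"
  if (is.null(study_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("bundlerepro_study_", key))
    unlink(dir, recursive = TRUE)
    study_cache[[key]] <- simulate_study(dir, n_subjects = 2, seed = 11,
                                         dwi = dwi)
  }
  study_cache[[key]]
}
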