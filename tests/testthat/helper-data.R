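# Shared fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Moderate synthetic dataset for pipeline-level tests.
small_dataset <- function() {
  cached("small", function() {
    generate_gla_dataset(gla_generator_spec(n_proteins = 30L, seed = 101L))
  })
}

small_fragments <- function() {
  cached("small_frags", function() {
    extract_fragments(small_dataset()$records, window_config(7))
  })
}

# Larger positive sample (~1000 sites) for composition-recovery checks.
large_dataset <- function() {
  cached("large", function() {
    generate_gla_dataset(gla_generator_spec(n_proteins = 250L, seed = 202L))
  })
}

# SVM settings tuned on this generator family (cost/gamma selection is part
# of the protocol; these values come from a coarse grid search).
tuned_cfg <- function() svm_config(cost = 32, gamma = 0.05)

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
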