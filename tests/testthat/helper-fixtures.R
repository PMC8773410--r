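# Shared fixtures, built once per test run. The small experiment keeps the
# per-file runtime down; the full-size study fixture is built only by the
# acceptance suite.

.fixture_env <- new.env(parent = emptyenv())

small_experiment <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_srna_experiment(
      n_hairpins = 10L, depth_a = 30000L, depth_b = 30000L,
      genome_length = 25000L, seed = 42L, n_sites_per_rule = 1L,
      outdir = file.path(tempdir(), "nitromir_small_fixture"))
  }
  .fixture_env$small
}

# a miRNA whose seed and tail both carry plenty of G/U, so every rule
# violation class is constructible for it
fixed_mirna <- function() "TGGAGCTGGTCAAGTACTTCG" # 21 nt

extdata <- function(name) {
  system.file("extdata", name, package = "nitromir", mustWork = TRUE)
}
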