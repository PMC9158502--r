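# The full-scale simulated benchmark is expensive (a few minutes), and two
# acceptance criteria read it (sensitivity, specificity); compute it once.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_bench <- function() {
  if (is.null(.acceptance_cache$bench)) {
    .acceptance_cache$bench <- simulate_benchmark(
      n_parents = 50, genome_length_bp = 1e6,
      psg_levels = c(70, 80, 90, 100),
      completeness_levels = seq(10, 100, 10),
      seed = 2026
    )
  }
  .acceptance_cache$bench
}
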