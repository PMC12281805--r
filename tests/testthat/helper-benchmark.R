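# A small planted meta-benchmark, computed once and shared across test
# files (generation is deterministic in the seed, so caching cannot change
# outcomes).
.bench_cache <- new.env(parent = emptyenv())

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

small_benchmark <- function() {
  if (is.null(.bench_cache$bm))
    .bench_cache$bm <- make_meta_benchmark(
      n_datasets = 4, n_representations = 4, seed = 42,
      sizes = 80, base_n = 80)
  .bench_cache$bm
}
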