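# Benchmark run under the study conditions (5 genomes x 1 Mb, 20
# caulimovirid + 10 decoy insertions each, sub_rate 0.10), computed at
# most once per test session.
get_benchmark_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bundle <- make_benchmark_bundle(seed = 1L)
      result <- run_pipeline(bundle)
      cache <<- list(bundle = bundle, result = result)
    }
    cache
  }
})
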