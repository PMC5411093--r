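# The default benchmark scene and its end-to-end evaluation are shared by
# several test files; compute them at most once per test run.
.bench_cache <- new.env(parent = emptyenv())

get_benchmark_scene <- function() {
  if (is.null(.bench_cache$scene))
    .bench_cache$scene <- default_benchmark_scene()
  .bench_cache$scene
}

get_benchmark_eval <- function() {
  if (is.null(.bench_cache$eval))
    .bench_cache$eval <- evaluate_scene(get_benchmark_scene())
  .bench_cache$eval
}
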