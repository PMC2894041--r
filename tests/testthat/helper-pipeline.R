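# The desk-scale study-condition run is expensive (~20 s), so it is computed
# once per session and shared by the acceptance tests.
.pipeline_cache <- new.env(parent = emptyenv())

desk_results <- function() {
  if (is.null(.pipeline_cache$res))
    .pipeline_cache$res <- run_pipeline(sim_config(1))
  .pipeline_cache$res
}
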