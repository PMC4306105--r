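# Shared cache of expensive solver runs so the acceptance tests and the
# unit tests reuse the same converged fields instead of re-solving.

.stentflow_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .stentflow_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .stentflow_test_cache)
  }
  get(key, envir = .stentflow_test_cache, inherits = FALSE)
}

## One production-geometry case (flow + drug + metrics row) at a given
## Reynolds number and resolution; keeps the flow/concentration fields as
## attributes for the bound/conservation checks.
cached_case <- function(Re, resolution = 20) {
  key <- sprintf("case_%g_res%g", Re, resolution)
  cached(key, {
    cfg <- run_config(resolution = resolution)
    run_case(cfg, Re)
  })
}

cached_mesh <- function(resolution = 20) {
  key <- sprintf("mesh_res%g", resolution)
  cached(key, make_fixture("reference_default", resolution = resolution)$mesh)
}
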