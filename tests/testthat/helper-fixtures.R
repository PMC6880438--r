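# Shared small-scale fixtures, generated in code and cached per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_config <- function(seed = 11L, ...) {
  sim_config(n_founders = 30L, n_panel_samples = 60L, n_sites = 600L,
             region_length_bp = 2e6, population_spec = list(
               labels = c("POPA", "POPB", "POPC"), drift = 0.05),
             seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_panel <- function() cached("small_panel", generate_panel(small_config()))

small_targets <- function() cached("small_targets", {
  generate_targets(small_panel()$panel, n = 8L, n_relatives = 2L, seed = 21L)
})
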