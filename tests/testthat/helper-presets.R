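# shared fixtures: simulate each figure preset once per test run
preset_cache <- new.env(parent = emptyenv())

preset_run <- function(name, ...) {
  if (is.null(preset_cache[[name]])) {
    pre <- clock_preset(name)
    preset_cache[[name]] <- c(simulate_clock(pre$spec, pre$params, ...),
                              list(preset = pre))
  }
  preset_cache[[name]]
}

# fast solver settings for scans in tests
scan_opts <- list(t_end = 300, n_out = 6000, rtol = 1e-6, atol = 1e-8)
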