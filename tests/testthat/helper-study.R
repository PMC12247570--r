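# the scaled-down study used by the acceptance checks, computed once per
# test run and shared between the criteria that consume it

acceptance_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_geometry(seed = derive_seed(1, "geometry"))
    }
    cache
  }
})

acceptance_single_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(seed = 1)
      cache <<- run_catalogue(cfg, geometry = acceptance_geometry())
    }
    cache
  }
})

# the EZ+PZ experiment keeps the full 50-seed inversion procedure (only the
# single-region catalogue is run with the reduced seed count)
acceptance_ezpz_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(seed = 1, n_single = 0, n_ezpz = 5,
                               conditions = "lc_none", n_seeds = 50)
      cache <<- run_catalogue(cfg, geometry = acceptance_geometry())
    }
    cache
  }
})
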