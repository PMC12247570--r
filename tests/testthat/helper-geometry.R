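# shared fixtures, built once per test run

# small full geometry bundle (coarse sphere, 8 regions, 2 subcortical,
# 3 electrodes) for pipeline-level tests
test_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_geometry(subdivisions = 2, n_regions = 8,
                               n_subcortical = 2, n_electrodes = 3,
                               contacts_per_electrode = 6, seed = 7)
    }
    cache
  }
})

# finer mesh for area-sensitive checks
test_mesh_ico3 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_icosphere(3, radius = 70)
    cache
  }
})

# minimal region-level geometry for neural-mass-only dynamics tests
toy_mass_geometry <- function(W) {
  structure(list(connectome = structure(list(weights = W),
                                        class = "connectome"),
                 n_regions_total = nrow(W)),
            class = "brain_geometry")
}

toy_mass_config <- function(u0, ez, pz = integer(0), gc = 1) {
  structure(list(ez = ez, pz = pz, u0_region = u0, gc = gc,
                 lc = "lc_none", lc_value = 0, half_size = FALSE),
            class = "spatial_config")
}

# wrap a signal matrix as a recording
as_recording <- function(signal, montage = "bipolar", dt = 0.1) {
  structure(list(signal = signal, montage = montage, dt = dt),
            class = "seeg_recording")
}
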