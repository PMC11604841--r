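# Shared small-scale fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small breathing phantom acquisition (32^3, 4000 spokes, 4 coils) shared
# by gating / recon / pipeline tests.
small_acq <- function() fixture("small_acq", function() {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_coils = 4, seed = 42,
                       defects = list(list(center = c(23, 16, 18),
                                           radius_vox = 4,
                                           ventilation_scale = 0)))
  truth <- build_phantom(spec)
  traj <- radial_trajectory(4000, 32)
  acq <- simulate_acquisition(truth, spec, traj, 4000, TR_s = 0.0095)
  list(spec = spec, truth = acq$truth, traj = traj, acq = acq)
})

# Static noiseless phantom acquisition for operator-quality tests.
static_acq <- function() fixture("static_acq", function() {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_coils = 2, seed = 7,
                       breathing = list(amplitude = 0),
                       drift = list(amplitude = 0), noise_sigma = 0)
  truth <- build_phantom(spec)
  traj <- radial_trajectory(4000, 32)
  acq <- simulate_acquisition(truth, spec, traj, 4000, TR_s = 0.0019)
  list(spec = spec, truth = acq$truth, traj = traj, acq = acq)
})

full_binning <- function(n_spokes) {
  structure(list(n_states = 1L,
                 membership = list(data.frame(spoke = seq_len(n_spokes),
                                              weight = 1)),
                 state_amplitude = 0.5, shared_fraction = 0,
                 decay_rate = 3), class = "phase_binning")
}
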