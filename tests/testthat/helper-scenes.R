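# Shared fixtures built in code. Scenes are kept small so the suite runs
# quickly; the scene geometry scales with the raster.

# Compact oracle scene: disjoint placement guaranteed, individually
# resolvable worms.
oracle_scene <- function(moving_fraction = 0.5, seed = 1, n_worms = 8,
                         n_eggs = 0, noise_sigma = 0.01) {
  scene_config(shape = c(320, 320), n_worms = n_worms,
               worm_length_px = c(25, 40), worm_width_px = c(4, 6),
               moving_fraction = moving_fraction, displacement_px = 50,
               n_eggs = n_eggs, noise_sigma = noise_sigma, seed = seed)
}

# Tiny scene for plate-level tests.
mini_scene <- function(seed = 1, moving_fraction = 0.5) {
  scene_config(shape = c(192, 192), n_worms = 5,
               worm_length_px = c(20, 35), worm_width_px = c(4, 6),
               moving_fraction = moving_fraction, displacement_px = 35,
               seed = seed)
}

# Simulate a small plate on disk and return its paths plus plate map.
make_mini_plate <- function(dir, n_wells = 4, n_timepoints = 2,
                            n_control = 2, seed = 1, bit_depth = 8) {
  wells <- well_ids_96()[seq_len(n_wells)]
  pm <- make_plate_map(
    wells,
    is_control = seq_len(n_wells) <= n_control,
    dose = ifelse(seq_len(n_wells) <= n_control, 0, 1))
  sim <- simulate_plate(dir, pm, n_timepoints = n_timepoints,
                        scene = mini_scene(), bit_depth = bit_depth,
                        seed = seed)
  list(root = dir, plate_map = pm, sim = sim)
}

# Synthetic paralysis-then-recovery trace over a standard 3 h assay.
recovery_trace <- function(min_fms = 0.2, window_level = 0.6) {
  times <- seq(0, 180, 5)
  fms <- c(rep(1, 3), seq(1, min_fms, length.out = 10),
           rep(window_level, length(times) - 13))
  list(times = times, fms = fms)
}
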