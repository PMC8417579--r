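# Shared fixtures: the standard acquisition schedule and small phantoms.

std_acq <- function(frame_times = seq(1, 35, by = 2), relaxivity = 3.3)
  acq_params(flip_angles = c(5, 15, 30, 50, 70), tr_ms = 10,
             dynamic_flip_angle = 15, frame_times = frame_times,
             relaxivity_r1 = relaxivity)

# Small two-follicle (DF + SF) phantom for fast end-to-end checks.
small_spec <- function(seed = 7, noise_sigma = 0, ...)
  phantom_spec(grid_shape = c(24, 24, 24), n_follicles = 2,
               follicle_kinds = c("DF", "SF"), radius_range = c(3, 4),
               seed = seed, noise_sigma = noise_sigma, ...)

# Run the relaxometry + kinetics chain on a simulated phantom; returns the
# pieces tests inspect. cb0 estimated from the phantom's blood pool unless
# given.
run_chain <- function(truth, acq = std_acq(), cb0 = NULL,
                      windows = kinetic_windows()) {
  conc_true <- simulate_concentration(truth)
  sim <- simulate_acquisition(truth, conc_true, acq)
  relax <- fit_r1_vfa(sim$vfa, acq)
  pre_ref <- sim$vfa[, , , which(acq$flip_angles == acq$dynamic_flip_angle)]
  conc <- concentration_series(sim$dynamic, pre_ref, relax, acq)
  if (is.null(cb0))
    cb0 <- estimate_blood_reference(conc, truth$label_volume == 3L, windows)
  vmaps <- fit_vascular_params(conc, cb0, windows)
  spike <- apply_spike_threshold(conc, windows$spike_threshold)
  late <- fit_late_enhancement(conc, windows,
                               exclude_mask = spike$excluded_mask)
  vmaps$late_rate <- late$late_rate
  list(conc_true = conc_true, sim = sim, relax = relax, conc = conc,
       cb0 = cb0, vmaps = vmaps, late = late, spike = spike)
}

# Single-voxel dce_series from a concentration vector.
voxel_series <- function(values, times)
  dce_series(array(values, c(1, 1, 1, length(values))), times, unit = "mM")
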