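# Shared fixtures, built in code.

# small, quiet acquisition for noise-free rendering tests
quiet_acq <- function(n_frames = 20, n_pixels = 40, ...) {
  acquisition_params(n_frames = n_frames, n_pixels = n_pixels,
                     background_photons = 0, read_noise_sd = 0, ...)
}

# a single ground-truth event with explicit kinematics
one_event <- function(x0_nt, v_nt_s, run_nt, t0_s = 0, molecule_id = 1L,
                      recording_s = Inf) {
  t_end <- if (v_nt_s > 0) t0_s + run_nt / v_nt_s else recording_s
  tibble::tibble(id = 1L, molecule_id = molecule_id, x0_nt = x0_nt,
                 t0_s = t0_s, v_nt_s = v_nt_s, run_nt = run_nt,
                 t_end_s = t_end, channel = 0L, coloc = FALSE)
}

# spot table for linking tests: one spot per (frame, position) pair
spot_table <- function(frames, positions, intensity = 100) {
  tibble::tibble(frame = as.integer(frames), position_px = positions,
                 position_nt = positions * 1000, intensity = intensity,
                 channel = "green")
}
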