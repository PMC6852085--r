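# small simulation helpers shared across test files

default_scenario <- function(emax = 1, hr = 136, rp = 0.45, n_beats = 15,
                             noise_sd = 0, seed = 3L, ...) {
  simulate_beats(elastance_params(emax = emax, hr = hr),
                 afterload_params(rp = rp),
                 sim_config(n_beats = n_beats, noise_sd = noise_sd,
                            seed = seed, ...))
}

# pure sine trace with known parameters, for exact-recovery fits
pure_sine_wave <- function(offset = 40, amp = 30, omega = 8, phase = 0.4,
                           fs = 250, dur = 1.2) {
  t <- seq(0, dur, by = 1 / fs)
  waveform(offset + amp * sin(omega * t + phase), fs, "sine", "mmHg")
}
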