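# Shared fixtures: everything is generated in code at test time.

# Reduced-scale configuration for experiment-level tests: shorter signals,
# lower rates, fewer impulses/sweeps. Physics defaults untouched.
make_test_cfg <- function(seed = 42) {
  cfg <- study_defaults(seed)
  cfg$source$duration <- 0.6
  cfg$source$sample_rate <- 20000
  cfg$sweep <- sweep_protocol(peak_flow = 5.5e-4, ramp_up_duration = 6,
                              hold_duration = 1, ramp_down_duration = 6,
                              onset_threshold_pressure = 12,
                              offset_threshold_pressure = 9)
  cfg$sweep_sample_rate <- 8000
  cfg$f_R1_values <- 500
  cfg$response$sample_rate <- 6000
  cfg$response$n_impulses <- 30
  cfg$larynx_presets <- cfg$larynx_presets[1:2, ]
  cfg$design <- list(n_sweeps = 2, n_repetitions = 1)
  cfg
}

# Anechoic reference tube with the spec-example medium constants
# (rho = 1.18, c = 350).
example_tube <- function() {
  tube_spec(termination = "anechoic", sound_speed = 350, air_density = 1.18)
}

# Steady anechoic simulation at shipped source defaults (f_o 106).
steady_anechoic <- function(duration = 1, sample_rate = 50000) {
  cfg <- study_defaults(1)
  params <- cfg$source
  params$duration <- duration
  params$sample_rate <- sample_rate
  flow <- generate_flow_pulse_train(params)
  p_sub <- subglottal_pressure(flow, cfg$tube_anechoic,
                               unname(cfg$R_g["anechoic"]))
  rad <- radiated_pressure(flow, cfg$radiation)
  list(cfg = cfg, params = params, flow = flow, p_sub = p_sub, rad = rad)
}

# Peak-to-trough of the demeaned middle half of a pressure waveform.
mid_excursion <- function(p) {
  n <- length(p$samples)
  mid <- p$samples[seq(round(n / 4), round(3 * n / 4))]
  diff(range(mid - mean(mid)))
}

# Plateau-tolerant count of interior local maxima (sampling a symmetric
# apex can land two exactly equal samples).
count_peaks <- function(seg) {
  ds <- sign(diff(seg))
  ds <- ds[ds != 0]
  if (length(ds) < 2) return(0L)
  sum(ds[-length(ds)] == 1 & ds[-1] == -1)
}

# Interior local maxima indices, plateau-tolerant (first sample of the
# plateau is reported).
peak_indices <- function(seg) {
  ds <- sign(diff(seg))
  idx <- which(ds != 0)
  ds_nz <- ds[idx]
  hits <- which(ds_nz[-length(ds_nz)] == 1 & ds_nz[-1] == -1)
  idx[hits] + 1L
}

# Harmonic peak levels of a spectrum at multiples of f_o.
harmonic_levels <- function(sp, f_o, f_max = 2400, halfwidth = 8) {
  hk <- seq(f_o, f_max, by = f_o)
  vapply(hk, function(h) {
    max(sp$level_db[abs(sp$frequency - h) <= halfwidth])
  }, numeric(1))
}
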