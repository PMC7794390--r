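test_that("impulse averaging reproduces a noiseless window and cuts noise
           by 1/N", {
  fs <- 2000
  wlen <- fs  # 1 s windows
  h <- numeric(wlen); h[10] <- 1; h[300] <- -0.4
  x <- pressure_waveform(rep(h, 8), fs)
  fr8 <- estimate_frequency_response(x, 1, 8)
  fr1 <- estimate_frequency_response(pressure_waveform(h, fs), 1, 1)
  expect_equal(fr8$magnitude_db, fr1$magnitude_db, tolerance = 1e-12)
  expect_equal(fr8$resolution, 1)
  expect_equal(fr8$n_impulses, 8)

  # white noise: averaging 100 windows drops the floor by ~20 dB
  set.seed(1)
  noise <- pressure_waveform(stats::rnorm(100 * wlen), fs)
  fr100 <- estimate_frequency_response(noise, 1, 100)
  fr_one <- estimate_frequency_response(
    pressure_waveform(noise$samples[seq_len(wlen)], fs), 1, 1)
  drop_db <- 10 * log10(mean(Mod(fr_one$complex_values)^2) /
                        mean(Mod(fr100$complex_values)^2))
  expect_equal(drop_db, 10 * log10(100), tolerance = 1.5)

  expect_warning(estimate_frequency_response(x, 1, 50), "available")
  expect_error(estimate_frequency_response(
    pressure_waveform(h[1:100], fs), 1, 1), "shorter")
})

test_that("simulated resonant-tube measurement recovers f_R1 = 500 Hz", {
  cfg <- make_test_cfg()
  tube <- resonant_tube(500, cfg)
  rec <- simulate_impulse_measurement(tube, cfg)
  fr <- estimate_frequency_response(rec, cfg$response$impulse_period,
                                    cfg$response$n_impulses)
  ls_fr <- estimate_frequency_response(
    simulate_impulse_measurement(NULL, cfg, seed = cfg$seed + 5),
    cfg$response$impulse_period, cfg$response$n_impulses)
  comp <- compensate_response(fr, ls_fr)
  peak <- find_first_peak(comp)
  expect_lt(abs(peak - 500) / 500, 0.02)
})

test_that("loudspeaker compensation is exact division on matching grids", {
  f <- seq(1, 2000, by = 1)
  tract <- 6 * sin(2 * pi * f / 700)           # arbitrary tract shape, dB
  tilt <- -10 + 8 * log10(f)                   # tilted loudspeaker
  fr_meas <- frequency_response(f, tract + tilt)
  fr_ls <- frequency_response(f, tilt)
  comp <- compensate_response(fr_meas, fr_ls)
  expect_true(comp$compensated)
  expect_lt(max(abs(comp$magnitude_db - tract)), 0.1)

  flat <- frequency_response(f, rep(0, length(f)))
  ident <- compensate_response(fr_meas, flat)
  expect_equal(ident$magnitude_db, fr_meas$magnitude_db)

  expect_error(compensate_response(fr_meas,
                                   frequency_response(f + 0.5, tilt)),
               "grids")
  deep <- frequency_response(f, ifelse(f == 100, -200, 0))
  expect_warning(compensate_response(fr_meas, deep), "clamped")
})

test_that("normalized spectra peak at 0 dB with harmonics on the f_o
           ladder", {
  # OQ 0.55 keeps all of the first 10 harmonics away from the source's
  # spectral nulls (at k * OQ integer)
  u <- generate_flow_pulse_train(source_params(f_o = 106, duration = 1,
                                               open_quotient = 0.55))
  sp <- compute_spectrum(flow_waveform(u$samples, u$sample_rate),
                         resolution = 4)
  expect_equal(max(sp$level_db), 0)
  expect_equal(sp$frequency[2] - sp$frequency[1], 4)
  for (k in 1:10) {
    # a local maximum lies within one bin of k * 106 Hz
    i <- which.min(abs(sp$frequency - k * 106))
    win <- sp$level_db[seq(i - 3, i + 3)]
    expect_lt(abs(sp$frequency[seq(i - 3, i + 3)][which.max(win)] - k * 106),
              4.1)
  }
  expect_error(compute_spectrum(
    pressure_waveform(rep(1, 100), 50000), 4), "shorter")
})

test_that("SPL track matches the closed form for sinusoids across six
           decades", {
  fs <- 10000
  t <- seq(0, 2, by = 1 / fs)
  for (A in c(1e-3, 1, 800, 1e3)) {
    w <- pressure_waveform(A * sin(2 * pi * 100 * t), fs)
    s <- compute_spl(w)
    steady <- s$spl[s$time > 1.5]
    expect_equal(mean(steady), 20 * log10(A / sqrt(2) / 20e-6),
                 tolerance = 0.1)
  }
  # 800 Pa sinusoid: the printed 149 dB operating point
  w <- pressure_waveform(800 * sin(2 * pi * 100 * t), fs)
  s <- compute_spl(w)
  expect_equal(mean(s$spl[s$time > 1.5]), 149.0, tolerance = 0.1)
  # rms exactly at the 20 uPa reference: 0 dB
  w0 <- pressure_waveform(20e-6 * sqrt(2) * sin(2 * pi * 100 * t), fs)
  s0 <- compute_spl(w0)
  expect_equal(mean(s0$spl[s0$time > 1.5]), 0, tolerance = 0.1)
  # pure DC dies in the 10 Hz high-pass
  dc <- compute_spl(pressure_waveform(rep(500, fs), fs))
  expect_lt(stats::median(dc$spl), -50)
  # uncalibrated input refused
  uncal <- pressure_waveform(sin(2 * pi * 100 * t), fs,
                             meta = list(calibrated = FALSE))
  expect_error(compute_spl(uncal), "uncalibrated")
})

test_that("pitch tracker: sines, radiated pulse trains, noise, silence", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)
  sine <- flow_waveform(sin(2 * pi * 126 * t), fs)
  fo <- estimate_fo(sine)
  expect_lt(abs(stats::median(fo$f_o[fo$voiced]) - 126), 0.5)

  sim <- steady_anechoic(duration = 1, sample_rate = 20000)
  fo2 <- estimate_fo(sim$rad)
  expect_lt(abs(stats::median(fo2$f_o[fo2$voiced]) - 106), 1)

  set.seed(2)
  noise <- flow_waveform(stats::rnorm(fs), fs)
  fo3 <- estimate_fo(noise)
  expect_gt(mean(!fo3$voiced), 0.8)

  silent <- flow_waveform(rep(0, fs), fs)
  fo4 <- estimate_fo(silent)
  expect_true(all(!fo4$voiced))
  expect_error(estimate_fo(flow_waveform(sin(t), 1000)), "sample rate")
})

test_that("threshold detector recovers gating pressures within 0.5 hPa", {
  cfg <- make_test_cfg()
  params <- cfg$source
  params$sample_rate <- cfg$sweep_sample_rate
  fl <- generate_flow_sweep(cfg$sweep, params, cfg$level2, "anechoic")
  p <- subglottal_pressure(fl, cfg$tube_anechoic, 6.25e6,
                           mean_flow = fl$meta$mean_flow_trace)
  ev <- detect_thresholds(p)
  expect_equal(ev$kind, c("onset", "offset"))
  expect_lt(abs(ev$mean_pressure[1] - 12), 0.5)
  expect_lt(abs(ev$mean_pressure[2] - 9), 0.5)

  # silence: no events
  quiet <- pressure_waveform(rep(1000, 8000 * 2), 8000)
  expect_equal(nrow(detect_thresholds(quiet)), 0)
})

test_that("threshold recovery holds over a 20-seed protocol sweep", {
  cfg <- make_test_cfg()
  params <- cfg$source
  params$sample_rate <- cfg$sweep_sample_rate
  set.seed(99)
  for (i in seq_len(20)) {
    onset <- stats::runif(1, 10, 14)
    offset <- stats::runif(1, 6.5, 8.5)
    prot <- cfg$sweep
    prot$onset_threshold_pressure <- onset
    prot$offset_threshold_pressure <- offset
    fl <- generate_flow_sweep(prot, params, cfg$level2, "anechoic")
    p <- subglottal_pressure(fl, cfg$tube_anechoic, 6.25e6,
                             mean_flow = fl$meta$mean_flow_trace)
    ev <- detect_thresholds(p)
    on_p <- ev$mean_pressure[ev$kind == "onset"][1]
    off_p <- ev$mean_pressure[ev$kind == "offset"]
    off_p <- off_p[length(off_p)]
    expect_lt(abs(on_p - onset), 0.5)
    expect_lt(abs(off_p - offset), 0.5)
    expect_gt(on_p, off_p)
  }
})

test_that("inverse filtering recovers the source flow shape", {
  sim <- steady_anechoic(duration = 1)
  inv <- inverse_filter(sim$rad)
  expect_equal(inv$sample_rate, 6000)
  # correlation with the mean-removed source flow after lag alignment
  src <- subglottalsim:::resample_wave(sim$flow$samples - 4e-4,
                                       sim$flow$sample_rate, 6000)
  r <- subglottalsim:::aligned_correlation(inv$samples, src$x, 6000)
  expect_gt(r, 0.95)

  # integrating an analytic derivative recovers the band-limited signal
  fs <- 6000
  t <- seq(0, 2, by = 1 / fs)
  freqs <- c(50, 120, 300)
  y <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * t) / f))
  dy <- rowSums(sapply(freqs, function(f) 2 * pi * cos(2 * pi * f * t)))
  expect_warning(inverse_filter(pressure_waveform(dy, fs),
                                target_rate = fs + 1), "skipped")
  out <- suppressWarnings(inverse_filter(pressure_waveform(dy, fs),
                                         target_rate = fs + 1))
  mid <- seq(round(length(t) / 4), round(3 * length(t) / 4))
  err <- out$samples[mid] - (y[mid] - mean(y[mid]))
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(y[mid]^2)), 0.02)

  z <- inverse_filter(pressure_waveform(rep(0, 12000), 12000))
  expect_true(all(abs(z$samples) < 1e-12))
})

test_that("cm H2O convert by the 0.981 factor", {
  expect_identical(cm_h2o_to_hpa(1), 0.981)
  expect_identical(cm_h2o_to_hpa(0), 0)
  expect_identical(cm_h2o_to_hpa(25), 24.525)
})

test_that("first-peak finder: tube model, flat response, ordering", {
  tube <- tube_spec(length = length_for_resonance(400, 372),
                    termination = "closed_piston", sound_speed = 372)
  f <- seq(50, 2500, by = 1)
  fr <- frequency_response(f, 20 * log10(Mod(input_impedance(tube, f))))
  expect_lt(abs(find_first_peak(fr) - 400), 2)

  flat <- frequency_response(f, rep(3, length(f)))
  expect_true(is.na(find_first_peak(flat)))

  two <- frequency_response(f, 10 * exp(-(f - 500)^2 / 800) +
                                 10 * exp(-(f - 1000)^2 / 800))
  expect_equal(find_first_peak(two), 500, tolerance = 3)
})
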