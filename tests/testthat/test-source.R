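test_that("pulse train hits the closed-form mean and peak", {
  p <- source_params(f_o = 106, mean_flow = 4e-4, open_quotient = 0.6,
                     leak_flow = 1e-4, duration = 0.5)
  u <- generate_flow_pulse_train(p)
  expect_equal(u$meta$peak_flow, 1.1e-3, tolerance = 1e-12)
  expect_lt(abs(mean(u$samples) - 4e-4) / 4e-4, 0.005)
  expect_equal(max(u$samples), 1.1e-3, tolerance = 1e-3)

  # degenerate cases: zero pulse amplitude and all-zero flow
  const <- generate_flow_pulse_train(
    source_params(mean_flow = 1e-4, leak_flow = 1e-4, duration = 0.1))
  expect_true(all(const$samples == 1e-4))
  zero <- generate_flow_pulse_train(
    source_params(mean_flow = 0, leak_flow = 0, duration = 0.1))
  expect_true(all(zero$samples == 0))
})

test_that("mean accuracy and exact leak-flow closed phases hold across OQ", {
  # integer cycle counts (f_o 100 Hz, 0.4 s): the waveform mean is the
  # closed-form cycle mean; a trailing fractional cycle would bias it
  for (oq in c(0.3, 0.45, 0.6, 0.8, 1.0)) {
    for (leak in c(0, 1e-4)) {
      p <- source_params(f_o = 100, mean_flow = 4e-4, open_quotient = oq,
                         leak_flow = leak, duration = 0.4)
      u <- generate_flow_pulse_train(p)
      expect_lt(abs(mean(u$samples) - 4e-4) / 4e-4, 0.005,
                label = sprintf("mean error at OQ=%g leak=%g", oq, leak))
      # every sample outside the open phases sits exactly at leak_flow
      fs <- p$sample_rate
      starts <- u$meta$cycle_starts * fs
      periods <- u$meta$cycle_periods * fs
      closed <- unlist(lapply(seq_along(starts), function(i) {
        i0 <- ceiling(starts[i] + oq * periods[i]) + 1
        i1 <- min(floor(starts[i] + periods[i]), length(u$samples))
        if (i1 >= i0) seq(i0, i1) else integer(0)
      }))
      expect_true(all(u$samples[closed] == leak),
                  label = sprintf("closed phase at OQ=%g leak=%g", oq, leak))
    }
  }
})

test_that("skewed pulses keep the closed-form mean", {
  for (sk in c(-0.5, 0.4, 0.8)) {
    u <- generate_flow_pulse_train(
      source_params(f_o = 100, duration = 0.4, skew = sk))
    expect_lt(abs(mean(u$samples) - 4e-4) / 4e-4, 0.005)
  }
})

test_that("invalid source parameters are rejected", {
  expect_error(source_params(leak_flow = 5e-4, mean_flow = 4e-4),
               "leak_flow")
  expect_error(source_params(open_quotient = 0))
  expect_error(source_params(open_quotient = 1.2))
  # unresolvable pulse: open phase shorter than 4 samples
  expect_error(
    generate_flow_pulse_train(
      source_params(f_o = 400, open_quotient = 0.3, sample_rate = 4000,
                    duration = 0.1)),
    "4 samples")
})

test_that("cycle jitter is seeded and deterministic", {
  p <- source_params(duration = 0.5, jitter_cv = 0.05, seed = 7)
  u1 <- generate_flow_pulse_train(p)
  u2 <- generate_flow_pulse_train(p)
  expect_identical(u1$samples, u2$samples)
  expect_gt(stats::sd(u1$meta$cycle_periods), 0)
  # mean stays close even under jitter
  expect_lt(abs(mean(u1$samples) - 4e-4) / 4e-4, 0.03)
})

test_that("EGG contact pulse spans the closed phase and is zero elsewhere", {
  p <- source_params(f_o = 106, open_quotient = 0.6, duration = 0.3)
  egg <- generate_egg(p, level2_config(egg_ripple_gain = 0))
  expect_true(all(egg$samples[!egg$contact] == 0))
  # single smooth maximum per contact phase
  runs <- split(which(egg$contact),
                cumsum(c(1, diff(which(egg$contact)) != 1)))
  # complete contact phases only (edge runs may be truncated)
  runs <- runs[lengths(runs) >= stats::median(lengths(runs)) - 1]
  n_max <- vapply(runs, function(idx) count_peaks(egg$samples[idx]),
                  integer(1))
  expect_true(all(n_max == 1))
  # contact duration ~ (1 - OQ) / f_o = 3.77 ms
  expect_equal(stats::median(lengths(runs)) / p$sample_rate,
               (1 - 0.6) / 106, tolerance = 0.02)
})

test_that("pressure-coupled EGG ripple creates secondary peaks at pressure
           maxima", {
  # phase-locked case: a 600 Hz ripple on a 100 Hz cycle puts exactly
  # three ripple periods into every 5 ms contact phase
  p <- source_params(f_o = 100, open_quotient = 0.5, duration = 0.2)
  fs <- p$sample_rate
  t <- (seq_len(round(0.2 * fs)) - 1) / fs
  p_sub <- pressure_waveform(2000 + 400 * sin(2 * pi * 600 * t), fs)
  cfg <- level2_config(egg_ripple_gain = 1.5e-3)
  egg <- generate_egg(p, cfg, p_sub)
  pk_p <- peak_indices(p_sub$samples)
  runs <- split(which(egg$contact),
                cumsum(c(1, diff(which(egg$contact)) != 1)))
  runs <- runs[lengths(runs) > 10]
  for (idx in runs) {
    lm_ <- peak_indices(egg$samples[idx])
    expect_gte(length(lm_), 2)
    for (i in lm_) {
      expect_lt(min(abs(idx[i] - pk_p)) / fs, 1e-3)
    }
  }

  # free-running 330 Hz ripple (~1.25 periods per contact): secondary
  # peaks appear in the contacts whose ripple phase allows them
  p2 <- source_params(f_o = 106, open_quotient = 0.6, duration = 0.2)
  p_sub2 <- pressure_waveform(2000 + 400 * sin(2 * pi * 330 * t), fs)
  egg2 <- generate_egg(p2, cfg, p_sub2)
  runs2 <- split(which(egg2$contact),
                 cumsum(c(1, diff(which(egg2$contact)) != 1)))
  runs2 <- runs2[lengths(runs2) > 10]
  n2 <- vapply(runs2, function(idx) count_peaks(egg2$samples[idx]),
               integer(1))
  expect_gt(sum(n2 >= 2), 0)

  # gain > 0 demands an aligned pressure input
  expect_error(generate_egg(p, cfg), "requires")
  bad_rate <- pressure_waveform(p_sub$samples, fs / 2)
  expect_error(generate_egg(p, cfg, bad_rate), "mismatch")
})

test_that("flow sweeps gate oscillation with onset/offset hysteresis", {
  prot <- sweep_protocol(ramp_up_duration = 4, hold_duration = 0.5,
                         ramp_down_duration = 4,
                         onset_threshold_pressure = 12,
                         offset_threshold_pressure = 9)
  params <- source_params(duration = 1, sample_rate = 8000)
  lvl <- level2_config()
  fl <- generate_flow_sweep(prot, params, lvl, "anechoic", R_g = 6.25e6)
  expect_length(fl$meta$onset_times, 1)
  expect_length(fl$meta$offset_times, 1)
  # pressure at gate-on exceeds pressure at gate-off (hysteresis)
  m <- fl$meta$mean_flow_trace
  fs <- fl$sample_rate
  p_on <- 6.25e6 * m[round(fl$meta$onset_times * fs) + 1] / 100
  p_off <- 6.25e6 * m[round(fl$meta$offset_times * fs) + 1] / 100
  expect_gt(p_on, p_off)
  expect_equal(p_on, 12, tolerance = 0.01)
  expect_equal(p_off, 9, tolerance = 0.01)

  # onset threshold above achievable pressure: no oscillation anywhere
  prot_hi <- sweep_protocol(onset_threshold_pressure = 60,
                            offset_threshold_pressure = 9)
  fl_hi <- generate_flow_sweep(prot_hi, params, lvl, "anechoic",
                               R_g = 6.25e6)
  expect_false(any(fl_hi$meta$gate))
  expect_equal(fl_hi$samples, fl_hi$meta$mean_flow_trace)

  # determinism: identical configuration, identical waveform
  fl2 <- generate_flow_sweep(prot, params, lvl, "anechoic", R_g = 6.25e6)
  expect_identical(fl$samples, fl2$samples)

  # hysteresis violations rejected
  expect_error(sweep_protocol(onset_threshold_pressure = 9,
                              offset_threshold_pressure = 12),
               "hysteresis")
  bad <- level2_config(offset_effect = 1.4)
  expect_error(generate_flow_sweep(prot, params, bad, "resonant"),
               "hysteresis")
})

test_that("resonant-condition sweeps apply the Level 2 effects", {
  prot <- sweep_protocol(ramp_up_duration = 4, hold_duration = 0.5,
                         ramp_down_duration = 4)
  params <- source_params(duration = 1, sample_rate = 8000)
  lvl <- level2_config(fo_anechoic = 126, fo_resonant = 106,
                       offset_effect = 0.89)
  fa <- generate_flow_sweep(prot, params, lvl, "anechoic")
  fr <- generate_flow_sweep(prot, params, lvl, "resonant")
  expect_equal(fa$meta$f_o, 126)
  expect_equal(fr$meta$f_o, 106)
  expect_equal(fr$meta$offset_threshold_hpa, 9 * 0.89)
  expect_equal(fa$meta$offset_threshold_hpa, 9)
  expect_equal(fr$meta$onset_threshold_hpa, 12)
})

test_that("threshold tables form a complete crossed design with the
           configured effects", {
  design <- list(n_larynx = 3, n_sweeps = 3, n_repetitions = 2)
  tab <- generate_threshold_dataset(design, c(12, 14, 10), c(9, 10, 7.5),
                                    level2_config(), noise_cv = 0.05,
                                    seed = 1)
  expect_equal(nrow(tab), 36)
  cells <- unique(tab[c("larynx_id", "condition", "sweep_index",
                        "repetition")])
  expect_equal(nrow(cells), 36)
  expect_true(all(tab$onset_pressure > tab$offset_pressure))

  # no effect, no noise: conditions identical
  tab0 <- generate_threshold_dataset(design, c(12, 14, 10), c(9, 10, 7.5),
                                     level2_config(offset_effect = 1),
                                     noise_cv = 0, seed = 1)
  an <- tab0[tab0$condition == "anechoic", ]
  re <- tab0[tab0$condition == "resonant", ]
  expect_equal(an$offset_pressure, re$offset_pressure)

  # exact multiplicative effect without noise
  tab89 <- generate_threshold_dataset(list(n_larynx = 1, n_sweeps = 1,
                                           n_repetitions = 1),
                                      12, 10,
                                      level2_config(offset_effect = 0.89),
                                      noise_cv = 0)
  expect_equal(tab89$offset_pressure[tab89$condition == "resonant"], 8.9)

  expect_error(generate_threshold_dataset(list(n_larynx = 0, n_sweeps = 3,
                                               n_repetitions = 2),
                                          12, 9, level2_config()),
               "empty design")
  expect_error(generate_threshold_dataset(design, c(12, 14, 10),
                                          c(13, 10, 7.5), level2_config()),
               "strictly below")
})

test_that("resonant/anechoic offset ratio converges to the configured
           effect as noise shrinks", {
  design <- list(n_larynx = 3, n_sweeps = 10, n_repetitions = 5)
  bounds <- c("0.1" = 0.03, "0.05" = 0.015, "0.01" = 0.003)
  for (cv in c(0.1, 0.05, 0.01)) {
    tab <- generate_threshold_dataset(design, c(12, 14, 10), c(9, 10, 7.5),
                                      level2_config(offset_effect = 0.89),
                                      noise_cv = cv, seed = 11)
    ratio <- mean(tab$offset_pressure[tab$condition == "resonant"]) /
      mean(tab$offset_pressure[tab$condition == "anechoic"])
    expect_lt(abs(ratio - 0.89), bounds[[as.character(cv)]])
  }
})
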