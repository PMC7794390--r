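#' Default experiment configuration
#'
#' One configuration object encoding every printed default of the
#' emulated excised-larynx study: steady source at f_o 106 Hz (resonant)
#' / 126 Hz (anechoic) and 400 mL/s mean flow; sweeps to 550 mL/s peak
#' flow; 24 mm tube; resonant settings f_R1 = 330, 400, 500, 600, 700,
#' 800 Hz (sweep experiment at 500 Hz); microphone at 10 cm; offset
#' threshold effect 0.89; per-condition DC glottal resistances calibrated
#' to the printed operating points (anechoic 6.25e6 Pa s/m^3 giving
#' 25 hPa at 400 mL/s, resonant 5.0e6 giving 20 hPa).
#'
#' The three sweep-experiment larynx presets (f_o 80/60/45 Hz, onset
#' thresholds 12/14/10 hPa, offsets 9/10/7.5 hPa) are free parameters
#' representing larynx-to-larynx variability; real per-larynx values
#' depend on tissue and are not reproducible.
#'
#' @param seed integer seed recorded in (and used by) all experiment
#'   runs.
#' @return A nested list of class `experiment_config`.
#' @export
study_defaults <- function(seed = 1) {
  cfg <- list(
    seed = seed,
    source = source_params(f_o = 106, mean_flow = 4e-4, open_quotient = 0.6,
                           leak_flow = 1e-4, duration = 2,
                           sample_rate = 50000),
    level2 = level2_config(fo_anechoic = 126, fo_resonant = 106,
                           offset_effect = 0.89, onset_effect = 1.0,
                           egg_ripple_gain = 5e-4),
    sound_speed = 372,
    f_R1_values = c(330, 400, 500, 600, 700, 800),
    sweep_f_R1 = 500,
    tube_anechoic = tube_spec(termination = "anechoic"),
    radiation = radiation_env(distance = 0.10, geometry = "free_field"),
    R_g = c(anechoic = 6.25e6, resonant = 5.0e6),
    sweep = sweep_protocol(peak_flow = 5.5e-4, ramp_up_duration = 10,
                           hold_duration = 5, ramp_down_duration = 10,
                           onset_threshold_pressure = 12,
                           offset_threshold_pressure = 9),
    sweep_sample_rate = 20000,
    larynx_presets = data.frame(
      larynx_id = c("L1", "L2", "L3"),
      f_o = c(80, 60, 45),
      onset_hpa = c(12, 14, 10),
      offset_hpa = c(9, 10, 7.5)),
    design = list(n_sweeps = 3, n_repetitions = 2),
    threshold_noise_cv = 0.05,
    response = list(sample_rate = 10000, impulse_period = 1,
                    n_impulses = 100, snr_db = 20,
                    loudspeaker_cutoff = 300),
    analysis = list(spectrum_resolution = 4, spl_hp_cutoff = 10,
                    invfilt_rate = 6000, invfilt_hp_cutoff = 20,
                    n_harmonics = 20)
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' Resonant tube for a requested f_R1
#'
#' Convenience wrapper: a closed-piston [tube_spec()] whose length is set
#' by [length_for_resonance()] at the configured effective sound speed.
#'
#' @param f_R1 requested first resonance, Hz.
#' @param cfg an [study_defaults()] configuration.
#' @return A [tube_spec()].
#' @export
resonant_tube <- function(f_R1, cfg = study_defaults()) {
  tube_spec(length = length_for_resonance(f_R1, cfg$sound_speed),
            termination = "closed_piston", sound_speed = cfg$sound_speed)
}

#' Serialize / restore an experiment configuration
#'
#' Configurations round-trip through YAML; S3 classes are re-applied on
#' read. [config_hash()] gives a short digest recorded in every output.
#'
#' @param cfg an `experiment_config`.
#' @param path YAML file path.
#' @return `read_config()` returns the restored `experiment_config`;
#'   `config_hash()` a 32-character md5 string.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(strip_classes(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_defaults(seed = raw$seed)
  cfg$source <- do.call(source_params, raw$source)
  cfg$level2 <- do.call(level2_config, raw$level2)
  cfg$sound_speed <- raw$sound_speed
  cfg$f_R1_values <- unlist(raw$f_R1_values)
  cfg$sweep_f_R1 <- raw$sweep_f_R1
  cfg$tube_anechoic <- do.call(tube_spec, raw$tube_anechoic)
  cfg$radiation <- do.call(radiation_env, raw$radiation)
  cfg$R_g <- unlist(raw$R_g)
  cfg$sweep <- do.call(sweep_protocol, raw$sweep)
  cfg$sweep_sample_rate <- raw$sweep_sample_rate
  cfg$larynx_presets <- as.data.frame(raw$larynx_presets)
  cfg$design <- raw$design
  cfg$threshold_noise_cv <- raw$threshold_noise_cv
  cfg$response <- raw$response
  cfg$analysis <- raw$analysis
  cfg
}

#' @rdname write_config
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(strip_classes(cfg), tmp)
  unname(tools::md5sum(tmp))
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.list(as.data.frame(x)))
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
    return(x)
  }
  # yaml drops names from named atomic vectors; write them as maps
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

# --- simulated measurement hardware -----------------------------------

# Magnitude response of the (small, bass-weak) measurement loudspeaker:
# 2nd-order Butterworth high-pass at `cutoff` Hz, zero phase.
loudspeaker_response <- function(freqs, cutoff = 300) {
  1 / sqrt(1 + (cutoff / freqs)^4)
}

#' Simulate one impulse-train response measurement
#'
#' Emulates the response-measurement hardware: the loudspeaker plays
#' `n_impulses` impulses at one per `impulse_period` seconds into the
#' tube; the microphone records the tube's impulse response coloured by
#' the loudspeaker magnitude response plus white noise at `snr_db`.
#' The tube transfer is its normalized input impedance `Z(f)/Z0`
#' (resonances appear as pressure maxima for a given excitation flow).
#' With `tube = NULL` the loudspeaker alone (free air) is measured.
#'
#' @param tube a [tube_spec()] or `NULL` for the loudspeaker-only
#'   calibration measurement.
#' @param cfg configuration (uses `cfg$response` and `cfg$seed`).
#' @param seed RNG seed for the noise (default `cfg$seed`).
#' @return A [pressure_waveform] containing the full impulse-train
#'   recording.
#' @export
simulate_impulse_measurement <- function(tube, cfg = study_defaults(),
                                         seed = cfg$seed) {
  rp <- cfg$response
  fs <- rp$sample_rate
  wlen <- round(rp$impulse_period * fs)
  half <- seq(2, floor(wlen / 2))         # skip DC, skip Nyquist
  freqs <- (half - 1) / rp$impulse_period
  H <- loudspeaker_response(freqs, rp$loudspeaker_cutoff) + 0i
  if (!is.null(tube)) {
    Z0 <- characteristic_impedance(tube)
    H <- H * input_impedance(tube, freqs) / Z0
  }
  spec <- complex(real = numeric(wlen))
  spec[half] <- H
  spec[wlen + 2 - half] <- Conj(H)
  h <- Re(stats::fft(spec, inverse = TRUE)) / wlen
  x <- rep(h, rp$n_impulses)
  set.seed(seed)
  noise_sd <- sqrt(mean(x^2)) * 10^(-rp$snr_db / 20)
  x <- x + stats::rnorm(length(x), sd = noise_sd)
  pressure_waveform(x, fs, location = "response_mic",
                    meta = list(seed = seed, snr_db = rp$snr_db,
                                tube = if (is.null(tube)) "loudspeaker"
                                       else tube$termination))
}

#' Run the response-measurement experiment
#'
#' For the anechoic tract and each configured resonant setting: simulate
#' the 100-impulse measurement, average and FFT
#' ([estimate_frequency_response()]), divide by the loudspeaker's
#' free-air response ([compensate_response()]), and locate the first
#' spectral peak ([find_first_peak()]). Optionally writes one CSV per
#' tube (frequency, magnitude dB) plus a summary CSV and a JSON run-info
#' record (seed, config hash).
#'
#' @param cfg configuration from [study_defaults()].
#' @param out_dir optional output directory.
#' @return A list with `responses` (named list of compensated
#'   [frequency_response()] objects) and `summary` (data frame of first
#'   peaks per tube).
#' @export
run_response_measurement <- function(cfg = study_defaults(), out_dir = NULL) {
  rp <- cfg$response
  ls_rec <- simulate_impulse_measurement(NULL, cfg, seed = cfg$seed)
  ls_fr <- estimate_frequency_response(ls_rec, rp$impulse_period,
                                       rp$n_impulses)
  tubes <- c(list(anechoic = cfg$tube_anechoic),
             stats::setNames(
               lapply(cfg$f_R1_values, resonant_tube, cfg = cfg),
               paste0("fR1_", cfg$f_R1_values)))
  responses <- list()
  rows <- list()
  for (nm in names(tubes)) {
    rec <- simulate_impulse_measurement(tubes[[nm]], cfg,
                                        seed = cfg$seed + match(nm, names(tubes)))
    fr <- estimate_frequency_response(rec, rp$impulse_period, rp$n_impulses)
    comp <- compensate_response(fr, ls_fr)
    responses[[nm]] <- comp
    rows[[nm]] <- data.frame(tube = nm,
                             first_peak_hz = find_first_peak(comp))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(responses)) {
      utils::write.csv(
        data.frame(frequency = responses[[nm]]$frequency,
                   magnitude_db = responses[[nm]]$magnitude_db),
        file.path(out_dir, paste0("response_", nm, ".csv")),
        row.names = FALSE)
    }
    utils::write.csv(summary, file.path(out_dir, "first_peaks.csv"),
                     row.names = FALSE)
    write_run_info(cfg, out_dir, "response_measurement")
  }
  list(responses = responses, summary = summary)
}

# Peak-to-trough excursion of the AC pressure over the middle half of the
# signal (edge tapers of the frequency-domain filtering excluded).
steady_excursion <- function(p) {
  n <- length(p$samples)
  mid <- p$samples[seq(round(n / 4), round(3 * n / 4))]
  diff(range(mid - mean(mid)))
}

# Mean of an SPL track over the second half of the signal (detector
# settled).
spl_steady <- function(track) {
  mean(track$spl[track$time > max(track$time) / 2])
}

# Maximum correlation between two equally sampled signals over lags up to
# max_lag seconds (scale/lag alignment for the inverse-filter check).
aligned_correlation <- function(x, y, rate, max_lag = 0.05) {
  L <- round(max_lag * rate)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]
  y <- y[seq_len(n)]
  best <- -1
  for (lag in seq(-L, L)) {
    if (lag >= 0) {
      r <- stats::cor(x[seq_len(n - lag)], y[seq(1 + lag, n)])
    } else {
      r <- stats::cor(x[seq(1 - lag, n)], y[seq_len(n + lag)])
    }
    if (!is.na(r) && r > best) best <- r
  }
  best
}

#' Run the steady-phonation experiment
#'
#' For the anechoic condition and each configured resonant f_R1:
#' synthesize the glottal flow (f_o per condition), subglottal pressure,
#' EGG and radiated sound; compute the 4-Hz normalized spectra, SPL
#' tracks, the f_o track on the radiated sound, and the
#' inverse-filter-versus-inverted-subglottal-pressure correlation.
#' Optionally writes WAV waveforms (with JSON sidecars), spectra CSVs and
#' a metrics CSV.
#'
#' @param cfg configuration from [study_defaults()].
#' @param out_dir optional output directory.
#' @param conditions subset of condition labels to run (default all:
#'   `"anechoic"` and `"fR1_<value>"` for each configured f_R1).
#' @return A list with `metrics` (one row per condition: mean subglottal
#'   pressure hPa, AC excursion Pa, subglottal and radiated SPL dB,
#'   median f_o Hz, inverse-filter correlation) and `runs` (per-condition
#'   list of waveforms, spectra and tracks).
#' @export
run_steady_experiment <- function(cfg = study_defaults(), out_dir = NULL,
                                  conditions = NULL) {
  all_conditions <- c("anechoic", paste0("fR1_", cfg$f_R1_values))
  if (is.null(conditions)) conditions <- all_conditions
  stopifnot(all(conditions %in% all_conditions))
  runs <- list()
  rows <- list()
  for (cond in conditions) {
    anechoic <- cond == "anechoic"
    tube <- if (anechoic) cfg$tube_anechoic else
      resonant_tube(as.numeric(sub("fR1_", "", cond)), cfg)
    R_g <- unname(cfg$R_g[if (anechoic) "anechoic" else "resonant"])
    params <- cfg$source
    params$f_o <- if (anechoic) cfg$level2$fo_anechoic else
      cfg$level2$fo_resonant
    flow <- generate_flow_pulse_train(params)
    p_sub <- subglottal_pressure(flow, tube, R_g)
    egg <- generate_egg(params, cfg$level2, p_sub)
    rad <- radiated_pressure(flow, cfg$radiation)
    spec_sub <- compute_spectrum(p_sub, cfg$analysis$spectrum_resolution)
    spec_rad <- compute_spectrum(rad, cfg$analysis$spectrum_resolution)
    spl_sub <- compute_spl(p_sub, cfg$analysis$spl_hp_cutoff)
    spl_rad <- compute_spl(rad, cfg$analysis$spl_hp_cutoff)
    fo <- estimate_fo(rad)
    inv <- inverse_filter(rad, cfg$analysis$invfilt_rate,
                          cfg$analysis$invfilt_hp_cutoff)
    target <- resample_wave(-(p_sub$samples - mean(p_sub$samples)),
                            p_sub$sample_rate, inv$sample_rate)
    inv_r <- aligned_correlation(inv$samples, target$x, inv$sample_rate)
    rows[[cond]] <- data.frame(
      condition = cond,
      f_o_source = params$f_o,
      mean_pressure_hpa = R_g * mean(flow$samples) / 100,
      ac_excursion_pa = steady_excursion(p_sub),
      spl_subglottal_db = spl_steady(spl_sub),
      spl_radiated_db = spl_steady(spl_rad),
      spl_gap_db = spl_steady(spl_sub) - spl_steady(spl_rad),
      fo_median_hz = stats::median(fo$f_o[fo$voiced]),
      invfilt_correlation = inv_r)
    runs[[cond]] <- list(flow = flow, p_sub = p_sub, egg = egg, rad = rad,
                         spectrum_sub = spec_sub, spectrum_rad = spec_rad,
                         spl_sub = spl_sub, spl_rad = spl_rad, fo = fo,
                         inverse_flow = inv)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "steady_metrics.csv"),
                     row.names = FALSE)
    for (cond in conditions) {
      write_waveform(runs[[cond]]$p_sub,
                     file.path(out_dir, paste0("p_sub_", cond, ".wav")))
      write_waveform(runs[[cond]]$rad,
                     file.path(out_dir, paste0("radiated_", cond, ".wav")))
      utils::write.csv(runs[[cond]]$spectrum_sub,
                       file.path(out_dir, paste0("spectrum_sub_", cond,
                                                 ".csv")),
                       row.names = FALSE)
      utils::write.csv(runs[[cond]]$spectrum_rad,
                       file.path(out_dir, paste0("spectrum_rad_", cond,
                                                 ".csv")),
                       row.names = FALSE)
    }
    write_run_info(cfg, out_dir, "steady_experiment")
  }
  list(metrics = metrics, runs = runs)
}

#' Run the flow-sweep experiment
#'
#' Simulates the full crossed sweep design (per-larynx presets x
#' anechoic/resonant condition x sweeps x repetitions): each sweep is
#' generated with per-sweep lognormal threshold variability, passed
#' through the condition's tube model, and analyzed with
#' [detect_thresholds()]. The detected onset/offset pressures form a
#' measured threshold table which is fed to [fit_threshold_model()] for
#' both responses. Frame-wise f_o and SPL versus mean-pressure tables are
#' built from the first sweep of each larynx/condition cell.
#'
#' @param cfg configuration from [study_defaults()].
#' @param out_dir optional output directory.
#' @param compute_tracks build the f_o/SPL-versus-pressure tables
#'   (slower); the threshold table and regressions are always computed.
#' @return A list with `thresholds` (measured `threshold_table`),
#'   `effects` (list of `effect_estimate` for onset and offset),
#'   `tracks` (data frame or `NULL`), and `spl_differences` (per-larynx
#'   mean radiated-SPL difference above 8 hPa, resonant minus anechoic).
#' @export
run_sweep_experiment <- function(cfg = study_defaults(), out_dir = NULL,
                                 compute_tracks = TRUE) {
  if (nrow(cfg$larynx_presets) < 1) stop("empty larynx preset list")
  if (is.null(cfg$sweep_f_R1)) stop("empty tube list for the sweep experiment")
  tube_res <- resonant_tube(cfg$sweep_f_R1, cfg)
  fo_ratio <- cfg$level2$fo_resonant / cfg$level2$fo_anechoic
  rows <- list()
  tracks <- list()
  run_id <- 0
  for (li in seq_len(nrow(cfg$larynx_presets))) {
    preset <- cfg$larynx_presets[li, ]
    for (cond in c("anechoic", "resonant")) {
      tube <- if (cond == "anechoic") cfg$tube_anechoic else tube_res
      R_g <- unname(cfg$R_g[cond])
      lvl2 <- cfg$level2
      lvl2$fo_anechoic <- preset$f_o
      lvl2$fo_resonant <- preset$f_o * fo_ratio
      for (sw in seq_len(cfg$design$n_sweeps)) {
        for (rep_i in seq_len(cfg$design$n_repetitions)) {
          run_id <- run_id + 1
          set.seed(cfg$seed * 1000 + run_id)
          cv <- cfg$threshold_noise_cv
          sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
          noise <- if (cv > 0)
            stats::rlnorm(2, -sdlog^2 / 2, sdlog) else c(1, 1)
          protocol <- cfg$sweep
          protocol$onset_threshold_pressure <- preset$onset_hpa * noise[1]
          protocol$offset_threshold_pressure <- preset$offset_hpa * noise[2]
          params <- cfg$source
          params$sample_rate <- cfg$sweep_sample_rate
          flow <- generate_flow_sweep(protocol, params, lvl2, cond, R_g)
          p_sub <- subglottal_pressure(flow, tube, R_g,
                                       mean_flow = flow$meta$mean_flow_trace)
          ev <- detect_thresholds(p_sub)
          onset <- ev$mean_pressure[ev$kind == "onset"][1]
          offs <- ev$mean_pressure[ev$kind == "offset"]
          offset <- if (length(offs)) offs[length(offs)] else NA_real_
          rows[[run_id]] <- data.frame(
            larynx_id = preset$larynx_id, condition = cond,
            sweep_index = sw, repetition = rep_i,
            onset_pressure = onset, offset_pressure = offset)
          if (compute_tracks && sw == 1 && rep_i == 1) {
            tracks[[length(tracks) + 1]] <-
              sweep_tracks(flow, p_sub, cfg, preset$larynx_id, cond)
          }
        }
      }
    }
  }
  thresholds <- do.call(rbind, rows)
  class(thresholds) <- c("threshold_table", "data.frame")
  effects <- list(onset = fit_threshold_model(thresholds, "onset"),
                  offset = fit_threshold_model(thresholds, "offset"))
  tracks_df <- if (length(tracks)) do.call(rbind, tracks) else NULL
  spl_differences <- NULL
  if (!is.null(tracks_df)) {
    spl_differences <- lapply(
      split(tracks_df, tracks_df$larynx_id), function(d) {
        a <- d[d$condition == "anechoic" & !is.na(d$spl_radiated), ]
        r <- d[d$condition == "resonant" & !is.na(d$spl_radiated), ]
        if (nrow(a) < 2 || nrow(r) < 2) return(NA_real_)
        tryCatch(spl_difference_by_pressure(
          data.frame(pressure = a$pressure, spl = a$spl_radiated),
          data.frame(pressure = r$pressure, spl = r$spl_radiated))$mean_db,
          error = function(e) NA_real_)
      })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(thresholds, file.path(out_dir, "threshold_table.csv"),
                     row.names = FALSE)
    if (!is.null(tracks_df))
      utils::write.csv(tracks_df, file.path(out_dir, "sweep_tracks.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(onset = unclass(effects$onset), offset = unclass(effects$offset),
           spl_differences = spl_differences),
      file.path(out_dir, "threshold_stats.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    write_run_info(cfg, out_dir, "sweep_experiment")
  }
  list(thresholds = thresholds, effects = effects, tracks = tracks_df,
       spl_differences = spl_differences)
}

# Frame-wise mean-pressure / SPL / f_o table for one sweep (increasing
# ramp only, oscillating frames).
sweep_tracks <- function(flow, p_sub, cfg, larynx_id, condition) {
  fs <- flow$sample_rate
  rad <- radiated_pressure(flow, cfg$radiation)
  spl_sub <- compute_spl(p_sub, cfg$analysis$spl_hp_cutoff)
  spl_rad <- compute_spl(rad, cfg$analysis$spl_hp_cutoff)
  fo <- estimate_fo(rad)
  dc <- fft_filter(p_sub$samples, fs, 5, "low", order = 4)
  gate <- flow$meta$gate
  t_frames <- fo$time
  idx <- pmin(pmax(round(t_frames * fs) + 1, 1), length(dc))
  keep <- gate[idx] & fo$voiced
  spl_at <- function(track) {
    stats::approx(track$time, track$spl, t_frames, rule = 2)$y
  }
  out <- data.frame(
    larynx_id = larynx_id, condition = condition,
    time = t_frames[keep],
    pressure = dc[idx][keep] / 100,
    f_o = fo$f_o[keep],
    spl_subglottal = spl_at(spl_sub)[keep],
    spl_radiated = spl_at(spl_rad)[keep])
  out
}

write_run_info <- function(cfg, out_dir, experiment) {
  jsonlite::write_json(
    list(experiment = experiment, seed = cfg$seed,
         config_hash = config_hash(cfg),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, paste0(experiment, "_run_info.json")),
    auto_unbox = TRUE)
  invisible(NULL)
}
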