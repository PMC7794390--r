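#' Glottal source parameters
#'
#' Parameter set for the synthetic voice source: a raised-cosine flow
#' pulse train riding on a constant leak flow. The pulse occupies the
#' open phase (`open_quotient` of each cycle); during the closed phase
#' the flow sits exactly at `leak_flow`. The pulse peak is chosen in
#' closed form so the waveform mean equals `mean_flow`:
#' `mean = leak + 0.5 * OQ * (peak - leak)`.
#'
#' Defaults are the steady-phonation operating point of the excised
#' larynx experiments this package emulates: fundamental frequency near
#' 106 Hz and mean flow about 400 mL/s. Open quotient and leak flow are
#' not reported for real larynges; the defaults (OQ 0.6, leak 100 mL/s)
#' are calibration choices that place the anechoic subglottal pressure
#' excursion near 800 Pa (see the methods vignette).
#'
#' @param f_o fundamental frequency, Hz.
#' @param mean_flow time-averaged flow, m^3/s.
#' @param open_quotient open-phase fraction of the cycle, in (0, 1].
#' @param leak_flow closed-phase (minimum) flow, m^3/s.
#' @param duration signal duration, s.
#' @param sample_rate sampling rate, Hz.
#' @param jitter_cv coefficient of variation of the lognormal cycle-length
#'   multiplier (0 = strictly periodic).
#' @param skew closing-phase skew in (-1, 1); 0 gives a symmetric
#'   raised cosine, positive values place the pulse peak later in the
#'   open phase. The pulse mean is skew-invariant.
#' @param seed RNG seed used when `jitter_cv > 0`.
#' @return A list of class `source_params`.
#' @export
source_params <- function(f_o = 106, mean_flow = 4e-4, open_quotient = 0.6,
                          leak_flow = 1e-4, duration = 1,
                          sample_rate = 50000, jitter_cv = 0, skew = 0,
                          seed = NULL) {
  stopifnot(f_o > 0, duration > 0, sample_rate > 0,
            open_quotient > 0, open_quotient <= 1,
            leak_flow >= 0, mean_flow >= 0,
            jitter_cv >= 0, abs(skew) < 1)
  if (leak_flow > mean_flow)
    stop("leak_flow must not exceed mean_flow")
  structure(list(f_o = f_o, mean_flow = mean_flow,
                 open_quotient = open_quotient, leak_flow = leak_flow,
                 duration = duration, sample_rate = sample_rate,
                 jitter_cv = jitter_cv, skew = skew, seed = seed),
            class = "source_params")
}

#' Level 2 interaction configuration
#'
#' Phenomenological parameters for the effects of subglottal acoustics on
#' the vocal fold oscillation itself (Level 2 interactions): the
#' condition-dependent fundamental frequency, the multiplicative effect of
#' the resonant condition on offset (and optionally onset) threshold
#' pressures, and the gain of pressure-coupled secondary peaks in the EGG
#' contact waveform. Defaults encode the experimentally observed
#' behaviour: f_o 126 Hz anechoic vs 106 Hz resonant, offset thresholds
#' about 11% lower in the resonant condition (factor 0.89), onsets
#' unaffected.
#'
#' @param fo_anechoic,fo_resonant fundamental frequency per condition, Hz.
#' @param offset_effect multiplicative factor applied to resonant-condition
#'   offset thresholds (0.89 = 11% reduction).
#' @param onset_effect same for onset thresholds (default 1 = no effect).
#' @param egg_ripple_gain EGG secondary-peak amplitude per Pa of AC
#'   subglottal pressure, au/Pa.
#' @return A list of class `level2_config`.
#' @export
level2_config <- function(fo_anechoic = 126, fo_resonant = 106,
                          offset_effect = 0.89, onset_effect = 1.0,
                          egg_ripple_gain = 5e-4) {
  stopifnot(fo_anechoic > 0, fo_resonant > 0, offset_effect > 0,
            onset_effect > 0, egg_ripple_gain >= 0)
  structure(list(fo_anechoic = fo_anechoic, fo_resonant = fo_resonant,
                 offset_effect = offset_effect, onset_effect = onset_effect,
                 egg_ripple_gain = egg_ripple_gain),
            class = "level2_config")
}

#' Flow sweep protocol
#'
#' Describes one flow sweep: the mean flow is ramped from zero to
#' `peak_flow`, held, and ramped back to zero, while oscillation switches
#' on when the mean subglottal pressure first exceeds the onset threshold
#' and off when it falls below the (lower) offset threshold — the
#' onset/offset hysteresis observed in phonation.
#'
#' @param peak_flow peak mean flow, m^3/s (default 550 mL/s).
#' @param ramp_up_duration,hold_duration,ramp_down_duration segment
#'   durations, s.
#' @param onset_threshold_pressure,offset_threshold_pressure gating
#'   thresholds on the mean subglottal pressure, hPa; the offset
#'   threshold must be strictly below the onset threshold.
#' @return A list of class `sweep_protocol`.
#' @export
sweep_protocol <- function(peak_flow = 5.5e-4, ramp_up_duration = 10,
                           hold_duration = 5, ramp_down_duration = 10,
                           onset_threshold_pressure = 12,
                           offset_threshold_pressure = 9) {
  stopifnot(peak_flow > 0, ramp_up_duration > 0, hold_duration >= 0,
            ramp_down_duration > 0)
  if (!(offset_threshold_pressure < onset_threshold_pressure))
    stop("hysteresis violated: offset threshold must be below onset threshold")
  structure(list(peak_flow = peak_flow,
                 ramp_up_duration = ramp_up_duration,
                 hold_duration = hold_duration,
                 ramp_down_duration = ramp_down_duration,
                 onset_threshold_pressure = onset_threshold_pressure,
                 offset_threshold_pressure = offset_threshold_pressure),
            class = "sweep_protocol")
}

# Continuous-time cycle boundaries (in samples) for a pulse train,
# honouring the lognormal jitter model. Returns start sample (0-based,
# fractional) and period (samples) per cycle.
source_cycles <- function(params) {
  n <- round(params$duration * params$sample_rate)
  T0 <- params$sample_rate / params$f_o
  if (params$jitter_cv > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    sdlog <- sqrt(log(1 + params$jitter_cv^2))
    n_cyc <- ceiling(n / T0 * (1 + 6 * params$jitter_cv)) + 2
    periods <- T0 * stats::rlnorm(n_cyc, -sdlog^2 / 2, sdlog)
  } else {
    n_cyc <- ceiling(n / T0) + 1
    periods <- rep(T0, n_cyc)
  }
  starts <- cumsum(c(0, periods))
  keep <- starts < n
  list(starts = starts[keep], periods = periods[seq_len(sum(keep))], n = n)
}

# Raised-cosine pulse value on [0, 1) with peak at fraction `a`.
rc_pulse <- function(phase, a) {
  ifelse(phase < a,
         0.5 * (1 - cos(pi * phase / a)),
         0.5 * (1 + cos(pi * (phase - a) / (1 - a))))
}

#' Generate a glottal flow pulse train
#'
#' Synthesizes the voice source: raised-cosine flow pulses of width
#' `open_quotient * T` on a `leak_flow` baseline, with the pulse peak set
#' so the waveform mean equals `mean_flow` exactly (closed form:
#' `mean = leak + 0.5 * OQ * (peak - leak)`). Cycle lengths are perturbed
#' by a seeded lognormal multiplier when `jitter_cv > 0`.
#'
#' @param params a [source_params()] object.
#' @return A [flow_waveform] whose `meta` carries the parameters, the
#'   realized cycle start times and periods (s), and the peak flow.
#' @examples
#' p <- source_params(f_o = 106, mean_flow = 4e-4, duration = 0.1)
#' u <- generate_flow_pulse_train(p)
#' mean(u$samples)            # 4e-4 to within 0.5%
#' u$meta$peak_flow           # 1.1e-3 m^3/s
#' @export
generate_flow_pulse_train <- function(params) {
  stopifnot(inherits(params, "source_params"))
  cyc <- source_cycles(params)
  open_len_min <- params$open_quotient * min(cyc$periods)
  if (params$mean_flow > params$leak_flow && open_len_min < 4)
    stop("open phase shorter than 4 samples: increase sample_rate or ",
         "reduce f_o (unresolvable pulse)")
  amp <- if (params$open_quotient > 0)
    2 * (params$mean_flow - params$leak_flow) / params$open_quotient else 0
  peak <- params$leak_flow + amp
  x <- rep(params$leak_flow, cyc$n)
  a <- 0.5 + params$skew / 2
  for (i in seq_along(cyc$starts)) {
    s <- cyc$starts[i]
    open_len <- params$open_quotient * cyc$periods[i]
    idx0 <- ceiling(s)
    idx1 <- min(ceiling(s + open_len) - 1, cyc$n - 1)
    if (idx1 < idx0) next
    idx <- idx0:idx1
    phase <- (idx - s) / open_len
    x[idx + 1] <- params$leak_flow + amp * rc_pulse(phase, a)
  }
  flow_waveform(x, params$sample_rate,
                meta = list(params = unclass(params),
                            peak_flow = peak,
                            cycle_starts = cyc$starts / params$sample_rate,
                            cycle_periods = cyc$periods / params$sample_rate))
}

#' Generate a synthetic EGG (vocal fold contact) waveform
#'
#' Builds a smooth contact pulse spanning each closed phase (duration
#' `(1 - OQ) * T`), zero during the open phase. When
#' `cfg$egg_ripple_gain > 0` an additive ripple term
#' `gain * (AC subglottal pressure)` is superimposed within the contact
#' phase only, emulating the pressure-coupled secondary EGG peaks seen
#' under low subglottal resonance frequencies (a Level 2 interaction).
#'
#' @param params a [source_params()] object (timing must match the flow
#'   the pressure was computed from).
#' @param cfg a [level2_config()] object.
#' @param p_sub optional subglottal [pressure_waveform]; required and must
#'   be sample-rate and duration aligned when `egg_ripple_gain > 0`.
#' @return An [egg_waveform] with a per-sample contact mask.
#' @export
generate_egg <- function(params, cfg = level2_config(), p_sub = NULL) {
  stopifnot(inherits(params, "source_params"), inherits(cfg, "level2_config"))
  cyc <- source_cycles(params)
  x <- numeric(cyc$n)
  contact <- logical(cyc$n)
  for (i in seq_along(cyc$starts)) {
    s <- cyc$starts[i]
    T_i <- cyc$periods[i]
    open_len <- params$open_quotient * T_i
    c0 <- s + open_len
    c1 <- min(s + T_i, cyc$n)
    idx0 <- ceiling(c0)
    idx1 <- min(ceiling(c1) - 1, cyc$n - 1)
    if (idx1 < idx0) next
    idx <- idx0:idx1
    phase <- (idx - c0) / (T_i - open_len)
    x[idx + 1] <- 0.5 * (1 - cos(2 * pi * phase))
    contact[idx + 1] <- TRUE
  }
  if (cfg$egg_ripple_gain > 0) {
    if (is.null(p_sub))
      stop("egg_ripple_gain > 0 requires a time-aligned subglottal pressure")
    if (!isTRUE(all.equal(p_sub$sample_rate, params$sample_rate)))
      stop("sample-rate mismatch between source params and p_sub")
    n_use <- min(cyc$n, length(p_sub$samples))
    ac <- p_sub$samples - mean(p_sub$samples)
    ripple <- numeric(cyc$n)
    ripple[seq_len(n_use)] <- cfg$egg_ripple_gain * ac[seq_len(n_use)]
    x <- x + ripple * contact
  }
  egg_waveform(x, params$sample_rate, contact,
               meta = list(egg_ripple_gain = cfg$egg_ripple_gain))
}

#' Generate a gated flow sweep
#'
#' Builds the mean-flow trajectory of one sweep (ramp up to
#' `protocol$peak_flow`, hold, ramp down) and superimposes oscillatory
#' flow pulses gated by the phonation thresholds: oscillation switches ON
#' when the instantaneous mean subglottal pressure (`R_g *` mean flow)
#' first exceeds the onset threshold and OFF when it falls below the
#' offset threshold. In the resonant condition the offset threshold is
#' multiplied by `cfg$offset_effect` (and the onset by
#' `cfg$onset_effect`), and the oscillation frequency is
#' `cfg$fo_resonant` instead of `cfg$fo_anechoic` — the Level 2 effects.
#'
#' @param protocol a [sweep_protocol()].
#' @param params a [source_params()]; its `f_o` is overridden by the
#'   condition-specific value from `cfg`, its pulse-shape parameters and
#'   sample rate are used as-is.
#' @param cfg a [level2_config()].
#' @param condition `"anechoic"` or `"resonant"`.
#' @param R_g DC glottal resistance, Pa s/m^3, mapping mean flow to mean
#'   subglottal pressure for the gating; defaults to the per-condition
#'   calibration of [study_defaults()] (6.25e6 anechoic, 5.0e6 resonant).
#' @return A [flow_waveform]; `meta` carries the gate mask, the mean-flow
#'   trace, condition, effective thresholds, and `R_g`.
#' @export
generate_flow_sweep <- function(protocol, params, cfg = level2_config(),
                                condition = c("anechoic", "resonant"),
                                R_g = NULL) {
  stopifnot(inherits(protocol, "sweep_protocol"),
            inherits(params, "source_params"),
            inherits(cfg, "level2_config"))
  condition <- match.arg(condition)
  if (is.null(R_g))
    R_g <- if (condition == "anechoic") 6.25e6 else 5.0e6
  f_o <- if (condition == "anechoic") cfg$fo_anechoic else cfg$fo_resonant
  onset_hpa <- protocol$onset_threshold_pressure *
    (if (condition == "resonant") cfg$onset_effect else 1)
  offset_hpa <- protocol$offset_threshold_pressure *
    (if (condition == "resonant") cfg$offset_effect else 1)
  if (!(offset_hpa < onset_hpa))
    stop("hysteresis violated after condition effects: offset >= onset")

  fs <- params$sample_rate
  total <- protocol$ramp_up_duration + protocol$hold_duration +
    protocol$ramp_down_duration
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  m <- numeric(n)
  up <- t < protocol$ramp_up_duration
  hold <- t >= protocol$ramp_up_duration &
    t < protocol$ramp_up_duration + protocol$hold_duration
  down <- !up & !hold
  m[up] <- protocol$peak_flow * t[up] / protocol$ramp_up_duration
  m[hold] <- protocol$peak_flow
  m[down] <- protocol$peak_flow *
    pmax(0, 1 - (t[down] - protocol$ramp_up_duration -
                   protocol$hold_duration) / protocol$ramp_down_duration)

  p_mean_hpa <- R_g * m / 100   # Pa -> hPa

  # Schmitt-trigger gating with hysteresis, vectorized by last-known-state
  # carry forward.
  state <- rep(NA, n)
  state[p_mean_hpa >= onset_hpa] <- 1
  state[p_mean_hpa < offset_hpa] <- 0
  known <- !is.na(state)
  last <- cummax(ifelse(known, seq_len(n), 0L))
  gate <- ifelse(last == 0L, FALSE, state[pmax(last, 1L)] == 1)

  # Normalized pulse shape (mean 1) at the condition's f_o.
  shape_params <- params
  shape_params$f_o <- f_o
  shape_params$duration <- total
  if (shape_params$mean_flow <= 0)
    stop("sweep source requires mean_flow > 0 to define the pulse shape")
  ref <- generate_flow_pulse_train(shape_params)
  shape <- ref$samples / mean(ref$samples)
  shape <- shape[seq_len(n)]

  u <- m * ifelse(gate, shape, 1)
  on_idx <- which(diff(c(FALSE, gate)) == 1)
  off_idx <- which(diff(c(gate, FALSE)) == -1)
  flow_waveform(u, fs, meta = list(
    condition = condition, f_o = f_o, R_g = R_g,
    onset_threshold_hpa = onset_hpa, offset_threshold_hpa = offset_hpa,
    gate = gate, mean_flow_trace = m,
    onset_times = (on_idx - 1) / fs, offset_times = (off_idx - 1) / fs,
    protocol = unclass(protocol)))
}

#' Generate a synthetic phonation threshold table
#'
#' Produces the full crossed design of onset/offset threshold pressures:
#' every (larynx, condition, sweep, repetition) cell exactly once.
#' Resonant-condition pressures are multiplied by the Level 2 effects
#' (`offset_effect` for offsets, `onset_effect` for onsets); anechoic rows
#' use factor 1. Every cell additionally receives an independent
#' mean-one lognormal multiplicative noise term with coefficient of
#' variation `noise_cv`.
#'
#' @param design list with `n_larynx`, `n_sweeps`, `n_repetitions`.
#' @param base_onsets,base_offsets per-larynx baseline pressures, hPa
#'   (recycled to `n_larynx`); each offset must be below its onset.
#' @param cfg a [level2_config()].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return A `threshold_table` data frame with columns `larynx_id`,
#'   `condition`, `sweep_index`, `repetition`, `onset_pressure`,
#'   `offset_pressure` (pressures in hPa).
#' @examples
#' tab <- generate_threshold_dataset(
#'   list(n_larynx = 3, n_sweeps = 3, n_repetitions = 2),
#'   base_onsets = c(12, 14, 10), base_offsets = c(9, 10, 7.5),
#'   cfg = level2_config(), noise_cv = 0.05, seed = 1)
#' nrow(tab)  # 36
#' @export
generate_threshold_dataset <- function(design, base_onsets, base_offsets,
                                       cfg = level2_config(),
                                       noise_cv = 0.05, seed = NULL) {
  stopifnot(inherits(cfg, "level2_config"), noise_cv >= 0)
  n_l <- design$n_larynx
  n_s <- design$n_sweeps
  n_r <- design$n_repetitions
  if (is.null(n_l) || is.null(n_s) || is.null(n_r) ||
      n_l < 1 || n_s < 1 || n_r < 1)
    stop("empty design: n_larynx, n_sweeps, n_repetitions must all be >= 1")
  base_onsets <- rep_len(base_onsets, n_l)
  base_offsets <- rep_len(base_offsets, n_l)
  if (any(base_offsets >= base_onsets))
    stop("base_offsets must be strictly below base_onsets for every larynx")
  if (!is.null(seed)) set.seed(seed)
  tab <- expand.grid(
    repetition = seq_len(n_r),
    sweep_index = seq_len(n_s),
    condition = c("anechoic", "resonant"),
    larynx_id = paste0("L", seq_len(n_l)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("larynx_id", "condition", "sweep_index", "repetition")]
  res <- tab$condition == "resonant"
  onset_factor <- ifelse(res, cfg$onset_effect, 1)
  offset_factor <- ifelse(res, cfg$offset_effect, 1)
  lnoise <- function(k) {
    if (noise_cv == 0) return(rep(1, k))
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  li <- match(tab$larynx_id, paste0("L", seq_len(n_l)))
  tab$onset_pressure <- base_onsets[li] * onset_factor * lnoise(nrow(tab))
  tab$offset_pressure <- base_offsets[li] * offset_factor * lnoise(nrow(tab))
  class(tab) <- c("threshold_table", "data.frame")
  tab
}
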