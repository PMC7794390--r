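#' Frequency response container
#'
#' Product of the impulse-averaging measurement pipeline: a strictly
#' increasing frequency grid with dB magnitudes (and optionally the
#' complex values), the grid resolution, and provenance (number of
#' impulses averaged, whether loudspeaker compensation was applied).
#'
#' @param frequency frequency grid, Hz (strictly increasing, uniform).
#' @param magnitude_db magnitude in dB.
#' @param complex_values optional complex response on the same grid.
#' @param n_impulses number of impulse windows averaged.
#' @param compensated logical: loudspeaker compensation applied?
#' @return A list of class `frequency_response`.
#' @export
frequency_response <- function(frequency, magnitude_db, complex_values = NULL,
                               n_impulses = NA_integer_, compensated = FALSE) {
  stopifnot(length(frequency) == length(magnitude_db),
            all(diff(frequency) > 0))
  structure(list(frequency = frequency, magnitude_db = magnitude_db,
                 complex_values = complex_values,
                 resolution = frequency[2] - frequency[1],
                 n_impulses = n_impulses, compensated = compensated),
            class = "frequency_response")
}

#' Estimate a frequency response by impulse averaging
#'
#' Implements the measurement protocol: the recording contains repeated
#' impulse excitations at a fixed period; the signal is segmented into
#' `impulse_period`-long windows which are averaged in the time domain to
#' suppress uncorrelated noise (variance reduction 1/N), and the FFT of
#' the averaged window gives the response. The frequency grid spacing is
#' `1 / impulse_period`.
#'
#' @param mic a [pressure_waveform] (or any waveform) containing the
#'   repeated impulse responses.
#' @param impulse_period period between impulses, s (default 1).
#' @param n_impulses number of windows requested (default 100); if fewer
#'   complete windows are present, the available count is used with a
#'   warning.
#' @return A [frequency_response()] (complex values retained).
#' @export
estimate_frequency_response <- function(mic, impulse_period = 1.0,
                                        n_impulses = 100) {
  stopifnot(inherits(mic, "waveform"), impulse_period > 0, n_impulses >= 1)
  fs <- mic$sample_rate
  wlen <- round(impulse_period * fs)
  n_avail <- floor(length(mic$samples) / wlen)
  if (n_avail < 1) stop("signal shorter than one impulse period")
  if (n_avail < n_impulses) {
    warning("only ", n_avail, " complete windows available (",
            n_impulses, " requested)")
    n_impulses <- n_avail
  }
  w <- matrix(mic$samples[seq_len(wlen * n_impulses)], nrow = wlen)
  avg <- rowMeans(w)
  X <- stats::fft(avg)
  half <- seq_len(floor(wlen / 2))
  freq <- (half - 1) / impulse_period
  cplx <- X[half]
  mag <- 20 * log10(pmax(Mod(cplx), .Machine$double.xmin))
  fr <- frequency_response(freq[-1], mag[-1], cplx[-1],
                           n_impulses = n_impulses, compensated = FALSE)
  fr
}

#' Compensate a measured response for the loudspeaker
#'
#' Divides the tract response by the loudspeaker's free-air response
#' measured with the same protocol (a dB subtraction), bin by bin on
#' identical grids. Loudspeaker bins below a -120 dB floor are clamped
#' with a warning to avoid blow-up.
#'
#' @param tract,loudspeaker [frequency_response()] objects on the same
#'   grid.
#' @param floor_db clamp level for the loudspeaker magnitude, dB.
#' @return A compensated [frequency_response()].
#' @export
compensate_response <- function(tract, loudspeaker, floor_db = -120) {
  stopifnot(inherits(tract, "frequency_response"),
            inherits(loudspeaker, "frequency_response"))
  if (length(tract$frequency) != length(loudspeaker$frequency) ||
      any(abs(tract$frequency - loudspeaker$frequency) > 1e-9))
    stop("frequency grids of tract and loudspeaker responses differ")
  ls_mag <- loudspeaker$magnitude_db
  if (any(ls_mag < floor_db)) {
    warning("loudspeaker magnitude below ", floor_db,
            " dB clamped at some bins")
    ls_mag <- pmax(ls_mag, floor_db)
  }
  cplx <- NULL
  if (!is.null(tract$complex_values) && !is.null(loudspeaker$complex_values)) {
    denom <- loudspeaker$complex_values
    denom[Mod(denom) < 10^(floor_db / 20)] <- 10^(floor_db / 20)
    cplx <- tract$complex_values / denom
  }
  frequency_response(tract$frequency, tract$magnitude_db - ls_mag, cplx,
                     n_impulses = tract$n_impulses, compensated = TRUE)
}

#' Normalized magnitude spectrum at fixed resolution
#'
#' Welch-style averaged magnitude spectrum: windows of length
#' `1/resolution` seconds (periodic Hann, 50% overlap), magnitudes
#' averaged across segments, then normalized so the maximum bin is
#' exactly 0 dB — the convention used for the published spectra (4 Hz
#' resolution).
#'
#' @param w a [waveform].
#' @param resolution frequency resolution (bin spacing), Hz.
#' @return A data frame of class `spectrum_db` with columns `frequency`
#'   and `level_db`; attribute `resolution`.
#' @export
compute_spectrum <- function(w, resolution = 4) {
  stopifnot(inherits(w, "waveform"), resolution > 0)
  fs <- w$sample_rate
  wlen <- round(fs / resolution)
  x <- w$samples - mean(w$samples)
  if (length(x) < wlen)
    stop("signal shorter than one analysis window (", 1 / resolution, " s)")
  hop <- floor(wlen / 2)
  starts <- seq(1, length(x) - wlen + 1, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / wlen))  # periodic Hann
  half <- seq_len(floor(wlen / 2))
  acc <- numeric(length(half))
  for (s in starts) {
    X <- stats::fft(x[s:(s + wlen - 1)] * win)
    acc <- acc + Mod(X[half])
  }
  acc <- acc / length(starts)
  level <- 20 * log10(pmax(acc, .Machine$double.xmin))
  level <- level - max(level)
  out <- data.frame(frequency = (half - 1) * resolution, level_db = level)
  class(out) <- c("spectrum_db", "data.frame")
  attr(out, "resolution") <- resolution
  out
}

#' Sound pressure level track ('fast' time weighting, non-weighted)
#'
#' Calibrated SPL re 20 uPa: the pressure is high-pass filtered at
#' `hp_cutoff` (removing the DC component), squared and smoothed by the
#' standard sound-level-meter 'fast' detector (125 ms exponential time
#' constant), then converted to dB. No frequency weighting is applied.
#'
#' @param w a calibrated [pressure_waveform] in Pa. Uncalibrated input
#'   (meta flag `calibrated = FALSE`) is an error.
#' @param hp_cutoff high-pass cutoff, Hz (default 10).
#' @param floor_db lower clamp for the returned SPL, dB.
#' @return A data frame of class `spl_track` with columns `time` (s) and
#'   `spl` (dB re 20 uPa).
#' @examples
#' fs <- 8000
#' w <- pressure_waveform(800 * sin(2 * pi * 100 * seq(0, 2, by = 1 / fs)), fs)
#' s <- compute_spl(w)
#' max(s$spl)   # about 149 dB
#' @export
compute_spl <- function(w, hp_cutoff = 10, floor_db = -100) {
  stopifnot(inherits(w, "pressure_waveform"))
  if (isFALSE(w$meta$calibrated))
    stop("uncalibrated pressure input: no Pa scale available")
  fs <- w$sample_rate
  x <- fft_filter(w$samples, fs, hp_cutoff, "high", order = 4)
  ms <- exp_mean_square(x, fs, tau = 0.125)
  p_ref2 <- (20e-6)^2
  spl <- pmax(10 * log10(pmax(ms, 0) / p_ref2 + 10^(floor_db / 10)),
              floor_db)
  out <- data.frame(time = waveform_time(w), spl = spl)
  class(out) <- c("spl_track", "data.frame")
  out
}

#' Fundamental frequency track (autocorrelation pitch tracker)
#'
#' Frame-wise normalized autocorrelation with parabolic peak
#' interpolation, substituting for an off-the-shelf pitch estimator.
#' Within each 100 ms frame (25 ms hop) the lag of the first strong
#' autocorrelation maximum in the 30-400 Hz search range gives f_o;
#' frames whose peak falls below the voicing threshold (or that are
#' essentially silent) are reported unvoiced (`NA`).
#'
#' @param w a [waveform].
#' @param frame,hop frame and hop sizes, s.
#' @param f_min,f_max search range, Hz.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return A data frame of class `fo_track` with columns `time`, `f_o`
#'   (Hz, `NA` where unvoiced) and `voiced`.
#' @export
estimate_fo <- function(w, frame = 0.100, hop = 0.025,
                        f_min = 30, f_max = 400,
                        voicing_threshold = 0.5) {
  stopifnot(inherits(w, "waveform"), f_min > 0, f_max > f_min)
  fs <- w$sample_rate
  if (fs < 4 * f_max)
    stop("sample rate must be at least 4x the maximum search frequency")
  flen <- round(frame * fs)
  hlen <- max(1L, round(hop * fs))
  x <- w$samples
  starts <- seq(1, length(x) - flen + 1, by = hlen)
  if (length(starts) < 1) stop("signal shorter than one analysis frame")
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- min(flen - 2L, ceiling(fs / f_min))
  silence_floor <- 10 * .Machine$double.eps * max(abs(x), 1e-300)
  res <- vapply(starts, function(s) {
    seg <- x[s:(s + flen - 1)]
    seg <- seg - mean(seg)
    if (sqrt(mean(seg^2)) <= silence_floor) return(c(NA_real_, 0))
    n2 <- next_pow2(2 * flen)
    X <- stats::fft(c(seg, rep(0, n2 - flen)))
    r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(lag_max + 2)] / n2
    if (!is.finite(r[1]) || r[1] <= 0) return(c(NA_real_, 0))
    r <- r / r[1]
    if (any(!is.finite(r))) return(c(NA_real_, 0))
    cand <- local_maxima(r[seq_len(lag_max + 1)])
    cand <- cand[cand - 1 >= lag_min]          # index i -> lag i-1
    if (length(cand) == 0) return(c(NA_real_, 0))
    best <- max(r[cand])
    # smallest lag among near-best maxima avoids octave-down errors
    pick <- cand[r[cand] >= best - 0.15 * abs(best)][1]
    lag <- pick - 1
    # parabolic interpolation around the peak
    y1 <- r[pick - 1]; y2 <- r[pick]; y3 <- r[pick + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    c(fs / (lag + delta), y2)
  }, numeric(2))
  f_o <- res[1, ]
  voiced <- !is.na(f_o) & res[2, ] >= voicing_threshold
  f_o[!voiced] <- NA_real_
  out <- data.frame(time = (starts - 1) / fs + frame / 2,
                    f_o = f_o, voiced = voiced)
  class(out) <- c("fo_track", "data.frame")
  out
}

#' Detect phonation onsets and offsets in a subglottal pressure sweep
#'
#' Automates the manual onset/offset picking: the pressure is band-passed
#' (30-1000 Hz) and its 25 ms RMS envelope compared against a relative
#' threshold (5% of the sweep's maximum envelope, with a 0.8 hysteresis
#' factor for the offset); an onset (offset) is declared when the
#' envelope stays above (below) threshold for at least `min_frames`
#' consecutive frames. The reported threshold pressure is the mean of the
#' low-passed (DC) pressure over a 50 ms window ending at the onset /
#' starting at the offset, in hPa.
#'
#' @param p_sub subglottal [pressure_waveform] of a sweep-like recording.
#' @param window averaging window for the mean pressure, s (default 0.050).
#' @param band band-pass edges for the oscillation envelope, Hz.
#' @param frame envelope frame length, s.
#' @param rel_threshold onset threshold as a fraction of the maximum
#'   envelope.
#' @param hysteresis offset threshold as a fraction of the onset
#'   threshold.
#' @param min_frames consecutive frames required to switch state.
#' @return A data frame of class `threshold_events` with columns `kind`
#'   (`"onset"`/`"offset"`), `time` (s) and `mean_pressure` (hPa); zero
#'   rows when no oscillation episode is found.
#' @export
detect_thresholds <- function(p_sub, window = 0.050, band = c(30, 1000),
                              frame = 0.025, rel_threshold = 0.05,
                              hysteresis = 0.8, min_frames = 3) {
  stopifnot(inherits(p_sub, "pressure_waveform"), window > 0)
  fs <- p_sub$sample_rate
  x <- p_sub$samples
  band[2] <- min(band[2], 0.45 * fs)
  dc <- fft_filter(x, fs, 5, "low", order = 4)
  ac <- fft_filter(x, fs, band, "band", order = 4)
  flen <- round(frame * fs)
  n_frames <- floor(length(x) / flen)
  if (n_frames < min_frames) return(empty_threshold_events())
  env <- sqrt(colMeans(matrix(ac[seq_len(flen * n_frames)]^2, nrow = flen)))
  thr_on <- rel_threshold * max(env)
  thr_off <- hysteresis * thr_on
  if (max(env) == 0) return(empty_threshold_events())

  events <- list()
  state <- FALSE
  i <- 1
  while (i + min_frames - 1 <= n_frames) {
    if (!state && all(env[i:(i + min_frames - 1)] > thr_on)) {
      state <- TRUE
      events[[length(events) + 1]] <- list(kind = "onset",
                                           frame = i)
    } else if (state && all(env[i:(i + min_frames - 1)] < thr_off)) {
      state <- FALSE
      events[[length(events) + 1]] <- list(kind = "offset",
                                           frame = i)
    }
    i <- i + 1
  }
  if (length(events) == 0) return(empty_threshold_events())
  kind <- vapply(events, `[[`, character(1), "kind")
  t_ev <- vapply(events, function(e) (e$frame - 1) * flen / fs, numeric(1))
  wlen <- round(window * fs)
  mean_pressure <- vapply(seq_along(events), function(j) {
    i_ev <- round(t_ev[j] * fs) + 1
    if (kind[j] == "onset") {
      i0 <- max(1, i_ev - wlen)
      i1 <- max(1, i_ev - 1)
      if (i_ev - wlen < 1)
        warning("onset window extends before signal start; shrunk")
    } else {
      i0 <- min(length(x), i_ev + 1)
      i1 <- min(length(x), i_ev + wlen)
      if (i_ev + wlen > length(x))
        warning("offset window extends past signal end; shrunk")
    }
    mean(dc[i0:i1]) / 100   # Pa -> hPa
  }, numeric(1))
  out <- data.frame(kind = kind, time = t_ev, mean_pressure = mean_pressure)
  class(out) <- c("threshold_events", "data.frame")
  out
}

empty_threshold_events <- function() {
  out <- data.frame(kind = character(0), time = numeric(0),
                    mean_pressure = numeric(0))
  class(out) <- c("threshold_events", "data.frame")
  out
}

#' Inverse filtering by numerical integration
#'
#' Recovers a flow-like source waveform from radiated pressure in the
#' no-vocal-tract case: anti-alias downsampling to `target_rate`
#' (default 6 kHz), cumulative trapezoidal integration (the radiated
#' pressure of a simple source is proportional to the flow derivative),
#' and a zero-phase high-pass at `hp_cutoff` (default 20 Hz) to suppress
#' integration drift. No resonance (pole/zero) correction is applied.
#' The output is flow-like with arbitrary scale.
#'
#' @param mic radiated-pressure [pressure_waveform].
#' @param target_rate output sample rate, Hz; if above the input rate,
#'   resampling is skipped with a warning.
#' @param hp_cutoff high-pass cutoff, Hz.
#' @return A [flow_waveform] (arbitrary units).
#' @export
inverse_filter <- function(mic, target_rate = 6000, hp_cutoff = 20) {
  stopifnot(inherits(mic, "pressure_waveform"))
  fs <- mic$sample_rate
  if (target_rate > fs) {
    warning("target_rate above input rate; resampling skipped")
    x <- mic$samples
    rate <- fs
  } else {
    rs <- resample_wave(mic$samples, fs, target_rate)
    x <- rs$x
    rate <- rs$rate
  }
  y <- cum_trapz(x - mean(x), 1 / rate)
  y <- fft_filter(y, rate, hp_cutoff, "high", order = 4)
  flow_waveform(y, rate, meta = list(arbitrary_scale = TRUE,
                                     hp_cutoff = hp_cutoff))
}

#' Convert centimetres of water to hectopascals
#'
#' Standard calibration factor for U-tube water manometers:
#' 1 cm H2O = 0.981 hPa.
#'
#' @param p pressure in cm H2O.
#' @return Pressure in hPa.
#' @examples
#' cm_h2o_to_hpa(25)  # 24.525
#' @export
cm_h2o_to_hpa <- function(p) {
  p * 0.981
}

#' First spectral peak of a frequency response
#'
#' Locates the first local magnitude maximum above `f_min` whose
#' prominence (height above the higher of the two flanking minima)
#' exceeds `prominence_db` — the quick f_R1 read-out used when
#' calibrating piston positions. A flat (peak-free) response returns
#' `NA_real_`, a none-result distinct from an error.
#'
#' @param fr a [frequency_response()].
#' @param f_min lowest admissible peak frequency, Hz.
#' @param prominence_db prominence floor, dB.
#' @param smooth_bins width (bins) of the running-mean smoother applied
#'   before peak picking; suppresses single-bin noise spikes while
#'   leaving the much broader physical resonance peaks intact. Use 1 to
#'   disable.
#' @return Peak frequency in Hz, or `NA_real_` when no qualifying peak
#'   exists.
#' @export
find_first_peak <- function(fr, f_min = 50, prominence_db = 6,
                            smooth_bins = 5) {
  stopifnot(inherits(fr, "frequency_response"))
  if (length(fr$frequency) == 0) stop("empty frequency response")
  x <- fr$magnitude_db
  if (smooth_bins > 1 && length(x) > smooth_bins) {
    k <- rep(1 / smooth_bins, smooth_bins)
    xs <- stats::filter(x, k, sides = 2)
    x <- ifelse(is.na(xs), x, as.numeric(xs))
  }
  f <- fr$frequency
  peaks <- local_maxima(x)
  peaks <- peaks[f[peaks] >= f_min]
  min_or_inf <- function(v) if (length(v) == 0) Inf else min(v)
  for (i in peaks) {
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, length(x))]
    # walk outwards until a sample higher than the peak bounds the basin
    lb <- which(left > x[i])
    lmin <- min_or_inf(left[seq.int(if (length(lb)) max(lb) + 1 else 1,
                                    i - 1)])
    rb <- which(right > x[i])
    rmin <- min_or_inf(right[seq_len(if (length(rb)) min(rb) - 1 else
                                     length(right))])
    if (x[i] - max(lmin, rmin) >= prominence_db) return(f[i])
  }
  NA_real_
}
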