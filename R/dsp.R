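# Internal DSP primitives shared by the simulation and analysis paths.
# No dedicated signal-processing package ships with this stack, so the
# few filters needed here are implemented directly: zero-phase filtering
# with a Butterworth *magnitude* response applied in the frequency domain
# (equivalent to a forward-backward IIR pass in magnitude, exactly linear
# phase), and a one-pole exponential mean-square detector for the 'fast'
# SPL weighting.

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Zero-phase frequency-domain filter with an order-`order` Butterworth
# magnitude response. type: "high", "low" or "band" (cutoff = c(lo, hi)).
fft_filter <- function(x, sample_rate, cutoff, type = c("high", "low", "band"),
                       order = 4) {
  type <- match.arg(type)
  n <- length(x)
  n2 <- next_pow2(n)
  # bridge the padding from the last back to the first sample: the FFT
  # sees a circular signal, and a zero pad would turn any DC offset into
  # large step transients at the signal edges
  pad <- if (n2 > n) {
    seq(x[n], x[1], length.out = n2 - n + 2)[-c(1, n2 - n + 2)]
  } else numeric(0)
  X <- stats::fft(c(x, pad))
  f <- c(seq(0, n2 / 2), seq(n2 / 2 - 1, 1)) * sample_rate / n2
  H <- switch(type,
    low  = 1 / sqrt(1 + (f / cutoff[1])^(2 * order)),
    high = {
      h <- numeric(length(f))
      pos <- f > 0
      h[pos] <- 1 / sqrt(1 + (cutoff[1] / f[pos])^(2 * order))
      h
    },
    band = {
      h <- numeric(length(f))
      pos <- f > 0
      h[pos] <- 1 / sqrt(1 + (cutoff[1] / f[pos])^(2 * order)) /
        sqrt(1 + (f[pos] / cutoff[2])^(2 * order))
      h
    })
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / n2
}

# Exponential mean square with time constant tau (s); the sound-level
# meter 'fast' detector uses tau = 0.125 s.
exp_mean_square <- function(x, sample_rate, tau = 0.125) {
  alpha <- exp(-1 / (sample_rate * tau))
  as.numeric(stats::filter((1 - alpha) * x^2, alpha, method = "recursive",
                           init = x[1]^2))
}

# Half-Hann taper applied to both ends of a signal over `dur` seconds.
taper_edges <- function(x, sample_rate, dur = 0.010) {
  n <- length(x)
  m <- min(round(dur * sample_rate), floor(n / 2))
  if (m < 2) return(x)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / (m - 1)))
  x[seq_len(m)] <- x[seq_len(m)] * ramp
  x[seq(n - m + 1, n)] <- x[seq(n - m + 1, n)] * rev(ramp)
  x
}

# Anti-aliased resampling: frequency-domain low pass at 0.45 * target
# rate, then linear interpolation onto the new uniform grid.
resample_wave <- function(x, sample_rate, target_rate) {
  if (target_rate >= sample_rate) return(list(x = x, rate = sample_rate))
  y <- fft_filter(x, sample_rate, 0.45 * target_rate, "low", order = 8)
  t_old <- (seq_along(x) - 1) / sample_rate
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate)
  list(x = stats::approx(t_old, y, t_new)$y, rate = target_rate)
}

# Cumulative trapezoidal integral with uniform spacing dt.
cum_trapz <- function(x, dt) {
  c(0, cumsum((x[-1] + x[-length(x)]) / 2)) * dt
}

# Amplitudes of the first n harmonics of f0 via DFT over an integer
# number of periods (harmonics then fall on exact bins).
harmonic_amplitudes <- function(x, sample_rate, f0, n_harmonics) {
  n_per <- floor(length(x) * f0 / sample_rate)
  if (n_per < 1) stop("signal shorter than one period of f0")
  n_use <- round(n_per * sample_rate / f0)
  n_use <- min(n_use, length(x))
  X <- stats::fft(x[seq_len(n_use)])
  k <- round((seq_len(n_harmonics)) * f0 * n_use / sample_rate) + 1
  2 * Mod(X[k]) / n_use
}

# Local maxima indices of a numeric vector (strictly greater than both
# neighbours).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}
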