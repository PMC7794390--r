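#' Subglottal tube specification
#'
#' Describes the one-dimensional subglottal waveguide: a straight
#' cylindrical tube of 24 mm diameter terminated either anechoically
#' (reflection-free, behaving as an infinite purely resistive waveguide)
#' or by a closed piston whose position sets the first resonance
#' frequency f_R1. Losses follow a viscothermal wall-loss scaling: the
#' propagation constant is `Gamma(f) = k_loss * sqrt(f) + 1i * 2*pi*f/c`.
#'
#' The default sound speed (372 m/s) is the effective value fitted from
#' the measured piston-position-to-f_R1 calibration of the hardware this
#' package emulates (see [fit_effective_sound_speed()]); it is higher
#' than free-air c because warm humidified air filled the tract.
#'
#' @param length tube length, m. Required for `closed_piston`; the
#'   hardware range is 0.25–0.55 m. Ignored (may be `NA`) for `anechoic`.
#' @param diameter inner diameter, m (default 0.024).
#' @param termination `"anechoic"` or `"closed_piston"`.
#' @param sound_speed effective sound speed c, m/s.
#' @param air_density air density rho, kg/m^3.
#' @param loss_coefficient k_loss, Np m^-1 Hz^-1/2.
#' @return A list of class `tube_spec`.
#' @export
tube_spec <- function(length = NA_real_, diameter = 0.024,
                      termination = c("anechoic", "closed_piston"),
                      sound_speed = 372, air_density = 1.14,
                      loss_coefficient = 0.03) {
  termination <- match.arg(termination)
  stopifnot(diameter > 0, sound_speed > 0, air_density > 0,
            loss_coefficient >= 0)
  if (termination == "closed_piston") {
    if (!is.finite(length) || length <= 0)
      stop("closed_piston termination requires a positive tube length")
    if (length < 0.25 || length > 0.55)
      warning("tube length ", length, " m is outside the hardware range ",
              "0.25-0.55 m")
  }
  structure(list(length = length, diameter = diameter,
                 termination = termination, sound_speed = sound_speed,
                 air_density = air_density,
                 loss_coefficient = loss_coefficient),
            class = "tube_spec")
}

#' Radiation environment
#'
#' Geometry and medium for the simple-source radiation model relating the
#' glottal flow to the pressure at a microphone above the glottis.
#'
#' @param distance microphone distance r from the glottis, m (default
#'   0.10, the experimental placement).
#' @param geometry `"free_field"` (radiation into the full sphere,
#'   `p = rho/(4*pi*r) * du/dt`) or `"baffled"` (half-space, doubled
#'   amplitude).
#' @param sound_speed,air_density medium constants for free air at the
#'   microphone (c = 350 m/s, rho = 1.18 kg/m^3 by default).
#' @return A list of class `radiation_env`.
#' @export
radiation_env <- function(distance = 0.10,
                          geometry = c("free_field", "baffled"),
                          sound_speed = 350, air_density = 1.18) {
  geometry <- match.arg(geometry)
  if (distance <= 0) stop("distance must be positive")
  stopifnot(sound_speed > 0, air_density > 0)
  structure(list(distance = distance, geometry = geometry,
                 sound_speed = sound_speed, air_density = air_density),
            class = "radiation_env")
}

tube_area <- function(tube) pi * (tube$diameter / 2)^2

#' Characteristic impedance of the tube
#'
#' `Z0 = rho * c / A` with `A` the cross-sectional area: the
#' pressure-to-flow ratio of a progressive wave, and the (flat, purely
#' resistive) input impedance of the anechoic tract.
#'
#' @param tube a [tube_spec()].
#' @return Characteristic impedance in Pa s/m^3.
#' @examples
#' characteristic_impedance(tube_spec(termination = "anechoic",
#'                                    sound_speed = 350, air_density = 1.18))
#' @export
characteristic_impedance <- function(tube) {
  stopifnot(inherits(tube, "tube_spec"))
  if (tube$diameter == 0) stop("diameter must be nonzero")
  tube$air_density * tube$sound_speed / tube_area(tube)
}

#' Input impedance of the subglottal tract
#'
#' For the anechoic termination the input impedance is the constant
#' characteristic impedance Z0. For the closed-piston termination it is
#' the lossy transmission-line result `Z(f) = Z0 * coth(Gamma(f) * L)`
#' with `Gamma(f) = k_loss * sqrt(f) + 1i * 2*pi*f / c`: magnitude maxima
#' (resonances) near `n*c/(2L)` and minima (antiresonances) near
#' `(2n-1)*c/(4L)`.
#'
#' With `k_loss = 0` the lossless impedance diverges at the poles; the
#' magnitude is capped at `1e6 * Z0` and the result carries attribute
#' `saturated = TRUE`.
#'
#' @param tube a [tube_spec()].
#' @param freqs frequency grid, Hz (all > 0).
#' @return Complex impedance vector (Pa s/m^3), same length as `freqs`.
#' @export
input_impedance <- function(tube, freqs) {
  stopifnot(inherits(tube, "tube_spec"), all(freqs > 0))
  Z0 <- characteristic_impedance(tube)
  if (tube$termination == "anechoic")
    return(complex(real = rep(Z0, length(freqs))))
  gamma <- complex(real = tube$loss_coefficient * sqrt(freqs),
                   imaginary = 2 * pi * freqs / tube$sound_speed)
  z <- Z0 / tanh(gamma * tube$length)
  cap <- 1e6 * Z0
  saturated <- !is.finite(Mod(z)) | Mod(z) > cap
  if (any(saturated)) {
    z[saturated] <- cap * exp(1i * Arg(z[saturated]))
    z[!is.finite(z)] <- complex(real = cap)
    attr(z, "saturated") <- TRUE
  }
  z
}

#' Resonance and antiresonance frequencies of the closed tube
#'
#' The closed-piston tube follows the harmonic patterns
#' `f_Rn = n * f_R1` and `f_ARn = (2n - 1) * f_AR1` with
#' `f_R1 = c / (2L)` and `f_AR1 = f_R1 / 2 = c / (4L)`.
#'
#' @param tube a [tube_spec()] with `closed_piston` termination.
#' @param n_max number of resonances (>= 0).
#' @return Numeric vector of frequencies, Hz (length `n_max`).
#' @export
resonance_frequencies <- function(tube, n_max) {
  stopifnot(inherits(tube, "tube_spec"), n_max >= 0)
  if (tube$termination == "anechoic")
    stop("anechoic termination has no resonances")
  if (n_max == 0) return(numeric(0))
  seq_len(n_max) * tube$sound_speed / (2 * tube$length)
}

#' @rdname resonance_frequencies
#' @export
antiresonance_frequencies <- function(tube, n_max) {
  stopifnot(inherits(tube, "tube_spec"), n_max >= 0)
  if (tube$termination == "anechoic")
    stop("anechoic termination has no antiresonances")
  if (n_max == 0) return(numeric(0))
  (2 * seq_len(n_max) - 1) * tube$sound_speed / (4 * tube$length)
}

#' Tube length for a requested first resonance
#'
#' Inverse of the half-wavelength resonance condition: `L = c / (2 f_R1)`.
#' With the fitted effective sound speed (372 m/s) this reproduces the
#' hardware's printed piston calibration, e.g. 37 cm for 500 Hz.
#'
#' @param f_R1 requested first resonance frequency, Hz.
#' @param sound_speed effective sound speed, m/s.
#' @return Length in m.
#' @export
length_for_resonance <- function(f_R1, sound_speed = 372) {
  stopifnot(f_R1 > 0, sound_speed > 0)
  sound_speed / (2 * f_R1)
}

#' Fit the effective sound speed from length/resonance pairs
#'
#' Each (L, f_R1) calibration pair implies `c = 2 * L * f`; the estimate
#' is their mean. Per-pair values are attached as attribute `per_pair`
#' so outlying pairs (end effects at the extreme piston positions) can be
#' inspected.
#'
#' @param lengths tube lengths, m.
#' @param f_R1 first resonance frequencies, Hz (same length).
#' @return Effective sound speed, m/s, with attribute `per_pair`.
#' @examples
#' # the mid-range piston calibration of the emulated hardware:
#' fit_effective_sound_speed(c(0.465, 0.37, 0.31, 0.27),
#'                           c(400, 500, 600, 700))  # ~373 m/s
#' @export
fit_effective_sound_speed <- function(lengths, f_R1) {
  if (length(lengths) == 0 || length(f_R1) == 0)
    stop("at least one (length, f_R1) pair required")
  stopifnot(length(lengths) == length(f_R1), all(lengths > 0), all(f_R1 > 0))
  per_pair <- 2 * lengths * f_R1
  est <- mean(per_pair)
  attr(est, "per_pair") <- per_pair
  est
}

#' Synthesize the subglottal pressure from a glottal flow
#'
#' The mean (DC) subglottal pressure is the glottal resistance times the
#' mean flow, `R_g * u_bar`. The AC part is the flow's AC component passed
#' through the tube input impedance, with a sign convention such that an
#' outgoing flow pulse produces a subglottal rarefaction — the measured
#' subglottal waveform is the *inverted* glottal flow:
#' `p(t) = R_g * u_bar - Zin{u(t) - u_bar}`.
#'
#' For the anechoic termination the impedance is the real constant Z0 and
#' the filter reduces exactly to `p = R_g * u_bar - Z0 * (u - u_bar)`,
#' constant during closed phases. For the closed-piston termination the
#' AC flow is filtered in the frequency domain by the complex input
#' impedance (signal padded to a power of two, 10 ms edge tapers, DC bin
#' excluded — DC is carried by the `R_g` term).
#'
#' @param flow a [flow_waveform].
#' @param tube a [tube_spec()].
#' @param R_g DC glottal resistance, Pa s/m^3 (>= 0).
#' @param mean_flow optional slow mean-flow trace (same length as the
#'   flow) for nonstationary signals such as sweeps; default is the
#'   scalar mean of the whole flow.
#' @return A subglottal [pressure_waveform] (Pa, DC included).
#' @export
subglottal_pressure <- function(flow, tube, R_g, mean_flow = NULL) {
  stopifnot(inherits(flow, "flow_waveform"), inherits(tube, "tube_spec"),
            R_g >= 0)
  u <- flow$samples
  fs <- flow$sample_rate
  if (is.null(mean_flow)) mean_flow <- mean(u)
  if (length(mean_flow) != 1 && length(mean_flow) != length(u))
    stop("mean_flow must be a scalar or match the flow length")
  u_ac <- u - mean_flow
  if (tube$termination == "closed_piston") {
    f_low <- antiresonance_frequencies(tube, 1)
    if (length(u) < fs / f_low)
      stop("flow shorter than one period at the lowest analysis frequency (",
           round(f_low, 1), " Hz)")
    p_ac <- zin_filter(u_ac, fs, tube)
  } else {
    p_ac <- characteristic_impedance(tube) * u_ac
  }
  pressure_waveform(R_g * mean_flow - p_ac, fs, location = "subglottal",
                    meta = list(R_g = R_g, termination = tube$termination,
                                flow_meta = flow$meta[c("condition", "f_o")]))
}

# Frequency-domain application of the tube input impedance to an AC flow
# signal. Edges are tapered over 10 ms and the signal padded to the next
# power of two. Bins below `dc_floor` (the DC bin and the sub-audio range)
# are forced to zero: the quasi-static pressure-flow path runs through the
# glottis/air supply (the R_g term), not into the sealed tube, whose
# compliance-like impedance diverges toward DC and would otherwise amplify
# slow gating transients unphysically.
zin_filter <- function(u_ac, sample_rate, tube, dc_floor = 10) {
  n <- length(u_ac)
  x <- taper_edges(u_ac, sample_rate, 0.010)
  n2 <- next_pow2(n)
  X <- stats::fft(c(x, rep(0, n2 - n)))
  half <- seq(2, n2 / 2 + 1)          # positive frequencies incl. Nyquist
  f_half <- (half - 1) * sample_rate / n2
  Zh <- input_impedance(tube, f_half)
  Zh[f_half < dc_floor] <- 0
  Z <- complex(real = numeric(n2))    # DC bin stays zero
  Z[half] <- Zh
  Z[n2 + 2 - seq(2, n2 / 2)] <- Conj(Zh[seq_len(n2 / 2 - 1)])
  Re(stats::fft(X * Z, inverse = TRUE))[seq_len(n)] / n2
}

#' Radiated pressure from the glottal flow (simple-source model)
#'
#' Treats the glottal exit as an acoustic monopole: the radiated pressure
#' at distance r is proportional to the time derivative of the flow at
#' retarded time, `p(t) = rho / (4*pi*r) * du/dt (t - r/c)` in the
#' free-field convention; a baffled source radiates into the half space
#' and doubles the amplitude (`2*pi*r` denominator). The derivative is
#' computed by central differences and the retarded time applied as an
#' integer-sample delay.
#'
#' @param flow a [flow_waveform].
#' @param env a [radiation_env()].
#' @return A [pressure_waveform] at location `"mic@<r>m"`.
#' @export
radiated_pressure <- function(flow, env = radiation_env()) {
  stopifnot(inherits(flow, "flow_waveform"), inherits(env, "radiation_env"))
  u <- flow$samples
  fs <- flow$sample_rate
  n <- length(u)
  dudt <- numeric(n)
  if (n >= 3)
    dudt[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) * fs / 2
  dudt[1] <- dudt[2]
  dudt[n] <- dudt[n - 1]
  denom <- if (env$geometry == "free_field") 4 * pi else 2 * pi
  p <- env$air_density / (denom * env$distance) * dudt
  delay <- round(env$distance / env$sound_speed * fs)
  if (delay > 0 && delay < n) p <- c(numeric(delay), p[seq_len(n - delay)])
  pressure_waveform(p, fs, location = sprintf("mic@%gm", env$distance),
                    meta = list(geometry = env$geometry,
                                distance = env$distance))
}

#' Theoretical subglottal-to-radiated transfer ratio A_L
#'
#' For a unit sinusoidal glottal flow at frequency f, the anechoic
#' subglottal pressure amplitude is `Z0 * U = rho_t * c_t / A * U` and the
#' radiated amplitude at distance r is `rho * f * U / (2 r)` (free
#' field), so the level difference is
#' `A_L(f) = 20 * log10(f * A / (2 r c))`, rising 6.02 dB per octave.
#' The tube medium constants cancel against the radiation medium in the
#' ratio up to `rho_rad * c_tube / (rho_tube * c_rad)`; both media are
#' taken at the radiation constants here, giving the plain `f A / (2 r c)`
#' form. A baffled source adds 6.02 dB.
#'
#' @param freqs frequencies, Hz (> 0).
#' @param tube a [tube_spec()] (supplies the cross-sectional area).
#' @param env a [radiation_env()] (supplies r, c and the geometry).
#' @return Transfer ratio in dB (radiated minus subglottal), one per
#'   frequency.
#' @examples
#' transfer_ratio_AL(100, tube_spec(termination = "anechoic"),
#'                   radiation_env())   # about -63.8 dB
#' @export
transfer_ratio_AL <- function(freqs, tube, env = radiation_env()) {
  stopifnot(all(freqs > 0), inherits(tube, "tube_spec"),
            inherits(env, "radiation_env"))
  A <- tube_area(tube)
  ratio <- freqs * A / (2 * env$distance * env$sound_speed)
  db <- 20 * log10(ratio)
  if (env$geometry == "baffled") db <- db + 20 * log10(2)
  db
}

#' Per-harmonic radiated-to-subglottal spectral peak ratios
#'
#' Measures the amplitudes of the first `n_harmonics` harmonics of f_o in
#' both the subglottal and the radiated pressure and returns their ratio
#' in dB (radiated minus subglottal) — the empirical counterpart of
#' [transfer_ratio_AL()].
#'
#' @param sub subglottal [pressure_waveform].
#' @param rad radiated [pressure_waveform]; same duration and rate.
#' @param f_o fundamental frequency, Hz.
#' @param n_harmonics number of harmonics (default 20); harmonics above
#'   Nyquist are truncated with a warning.
#' @return Data frame with `harmonic`, `frequency`, `ratio_db`.
#' @export
spectral_peak_ratios <- function(sub, rad, f_o, n_harmonics = 20) {
  stopifnot(inherits(sub, "pressure_waveform"),
            inherits(rad, "pressure_waveform"), f_o > 0)
  if (!isTRUE(all.equal(sub$sample_rate, rad$sample_rate)) ||
      length(sub$samples) != length(rad$samples))
    stop("sub and rad must share sample rate and duration")
  fs <- sub$sample_rate
  k_max <- floor((fs / 2) / f_o)
  if (n_harmonics > k_max) {
    warning("truncating harmonics above Nyquist: keeping ", k_max,
            " of ", n_harmonics)
    n_harmonics <- k_max
  }
  a_sub <- harmonic_amplitudes(sub$samples - mean(sub$samples), fs, f_o,
                               n_harmonics)
  a_rad <- harmonic_amplitudes(rad$samples - mean(rad$samples), fs, f_o,
                               n_harmonics)
  data.frame(harmonic = seq_len(n_harmonics),
             frequency = seq_len(n_harmonics) * f_o,
             ratio_db = 20 * log10(a_rad / a_sub))
}
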