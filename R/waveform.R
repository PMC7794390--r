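#' Sampled waveform containers
#'
#' Lightweight S3 containers for uniformly sampled signals. A
#' `flow_waveform` holds glottal volume flow in m^3/s, a
#' `pressure_waveform` holds acoustic pressure in Pa (DC included) at a
#' named location, and an `egg_waveform` holds an electroglottographic
#' contact signal in arbitrary units together with a per-sample
#' contact-phase mask.
#'
#' @param samples numeric vector of samples.
#' @param sample_rate sampling rate in Hz.
#' @param meta named list of free-form metadata (source parameters, seed,
#'   simulation provenance).
#' @return An object of class `flow_waveform`, `pressure_waveform` or
#'   `egg_waveform`, all inheriting from `waveform`.
#' @examples
#' w <- flow_waveform(rep(4e-4, 100), 1000)
#' waveform_duration(w)
#' @name waveform
NULL

new_waveform <- function(samples, sample_rate, class, meta = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 meta = meta),
            class = c(class, "waveform"))
}

#' @rdname waveform
#' @export
flow_waveform <- function(samples, sample_rate, meta = list()) {
  new_waveform(samples, sample_rate, "flow_waveform", meta)
}

#' @rdname waveform
#' @param location label for where the pressure was "measured"
#'   (e.g. `"subglottal"` or `"mic@0.1m"`).
#' @export
pressure_waveform <- function(samples, sample_rate, location = "subglottal",
                              meta = list()) {
  w <- new_waveform(samples, sample_rate, "pressure_waveform", meta)
  w$location <- location
  w
}

#' @rdname waveform
#' @param contact logical vector, TRUE where the vocal folds are in contact.
#' @export
egg_waveform <- function(samples, sample_rate, contact, meta = list()) {
  stopifnot(length(contact) == length(samples))
  w <- new_waveform(samples, sample_rate, "egg_waveform", meta)
  w$contact <- as.logical(contact)
  w
}

#' @rdname waveform
#' @param w a waveform object.
#' @export
waveform_duration <- function(w) {
  length(w$samples) / w$sample_rate
}

#' @rdname waveform
#' @export
waveform_time <- function(w) {
  (seq_along(w$samples) - 1) / w$sample_rate
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz (%.3f s)\n",
              class(x)[1], length(x$samples), x$sample_rate,
              waveform_duration(x)))
  if (!is.null(x$location)) cat("  location:", x$location, "\n")
  invisible(x)
}
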