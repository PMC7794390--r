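#' Waveform file I/O: RIFF WAV (32-bit float) plus JSON sidecar
#'
#' Waveforms are exchanged as mono 32-bit IEEE-float RIFF WAV files. The
#' physical scale does not fit in a WAV, so each file gets a JSON sidecar
#' (`<file>.json`) recording the physical unit, the scale factor
#' (physical units per WAV unit), the waveform class, location and
#' metadata. `write_waveform()` normalizes the signal to peak 1 before
#' writing; `read_waveform()` restores the physical scale.
#'
#' No WAV-capable R package is available in this stack, so the (trivial)
#' 44-byte canonical header is written and parsed directly.
#'
#' @param w a [waveform] object.
#' @param path output `.wav` path; the sidecar is written next to it.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns the reconstructed waveform object.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  peak <- max(abs(x), .Machine$double.eps)
  unit <- if (inherits(w, "flow_waveform")) "m^3/s"
          else if (inherits(w, "pressure_waveform")) "Pa" else "au"
  write_wav_f32(x / peak, w$sample_rate, path)
  sidecar <- list(
    unit = unit,
    scale = peak,
    sample_rate = w$sample_rate,
    class = class(w)[1],
    location = w$location,
    meta = w$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  wav <- read_wav_f32(path)
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    x <- wav$samples * sc$scale
    cls <- sc$class
    meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
    switch(cls,
      flow_waveform = flow_waveform(x, wav$sample_rate, meta),
      pressure_waveform = pressure_waveform(
        x, wav$sample_rate,
        location = if (is.null(sc$location)) "unknown" else sc$location,
        meta = meta),
      egg_waveform = egg_waveform(x, wav$sample_rate,
                                  contact = x > 0, meta = meta),
      new_waveform(x, wav$sample_rate, cls, meta))
  } else {
    # Bare recording with no calibration sidecar: keep WAV units,
    # caller must calibrate before SPL computation.
    pressure_waveform(wav$samples, wav$sample_rate, location = "uncalibrated",
                      meta = list(calibrated = FALSE))
  }
}

write_wav_f32 <- function(x, sample_rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(sample_rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(sample_rate) * 4L), con, size = 4,
           endian = "little")
  writeBin(4L, con, size = 2, endian = "little")   # block align
  writeBin(32L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

read_wav_f32 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NA_real_
  fmt <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (identical(id, "data")) {
      if (is.na(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt != 3L) stop("only 32-bit float WAV supported, got format ", fmt)
      x <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      return(list(samples = x, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
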