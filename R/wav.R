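#' Audio clip container
#'
#' Bundles a mono waveform with its sample rate and, when known, the
#' recording-site id and start time parsed from an SM4-style filename.
#'
#' @param samples numeric waveform with values in \[-1, 1\].
#' @param sr sample rate in Hz.
#' @param site site identifier or `NA` when unknown.
#' @param start `POSIXct` start time (UTC) or `NA` when unknown.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sr, site = NA_character_, start = as.POSIXct(NA)) {
  if (length(samples) == 0L) stop("audio clip must have positive duration", call. = FALSE)
  structure(list(samples = as.numeric(samples), sr = as.numeric(sr),
                 site = site, start = start),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.2f s @ %g Hz, site=%s, start=%s\n",
              length(x$samples) / x$sr, x$sr,
              ifelse(is.na(x$site), "?", x$site),
              ifelse(is.na(x$start), "?", format(x$start, "%Y-%m-%d %H:%M:%S"))))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an `audio_clip`.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sr

# Parse the SM4-style convention PREFIX_YYYYMMDD_HHMMSS.wav.
# Returns list(site=, start=) with NAs when the name does not match.
parse_sm4_filename <- function(path) {
  base <- basename(path)
  m <- regmatches(base, regexec("^(.+)_([0-9]{8})_([0-9]{6})\\.[Ww][Aa][Vv]$", base))[[1]]
  if (length(m) != 4L)
    return(list(site = NA_character_, start = as.POSIXct(NA)))
  start <- as.POSIXct(paste0(m[3], m[4]), format = "%Y%m%d%H%M%S", tz = "UTC")
  list(site = m[2], start = start)
}

#' Read a PCM WAV file
#'
#' Reads 8-, 16-, 24- or 32-bit integer PCM WAV files. Stereo (or any
#' multi-channel) audio is averaged to mono and integer samples are scaled
#' to \[-1, 1\]. Site and start time are parsed from the SM4-style filename
#' convention `PREFIX_YYYYMMDD_HHMMSS.wav`; a non-matching name yields a
#' warning and unset metadata, not an error.
#'
#' @param path path to a PCM WAV file.
#' @param warn_metadata warn when the filename does not follow the naming
#'   convention (default `TRUE`).
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, warn_metadata = TRUE) {
  if (!file.exists(path)) stopf("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF/WAV file: %s", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        sr           = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stopf("truncated or malformed WAV (missing fmt/data chunk): %s", path)
  if (fmt$audio_format != 1L)
    stopf("only integer PCM WAV supported (format code %d): %s", fmt$audio_format, path)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n_total, 1L, signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n_total, 2L, signed = TRUE,
                              endian = "little")) / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    "32" = as.numeric(readBin(data_raw, "integer", n_total, 4L, signed = TRUE,
                              endian = "little")) / 2147483648,
    stopf("unsupported bit depth %d: %s", fmt$bits, path))

  nch <- fmt$n_channels
  if (nch > 1L) {
    n_frames <- length(x) %/% nch
    x <- colMeans(matrix(x[seq_len(n_frames * nch)], nrow = nch))
  }
  meta <- parse_sm4_filename(path)
  if (warn_metadata && is.na(meta$site))
    warnf("filename does not match PREFIX_YYYYMMDD_HHMMSS.wav; site/start left unset: %s",
          basename(path))
  audio_clip(x, fmt$sr, site = meta$site, start = meta$start)
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples numeric waveform in \[-1, 1\]; values outside are clipped.
#' @param sr sample rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sr, path) {
  x <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")          # PCM
  writeBin(1L, con, 2L, endian = "little")          # mono
  writeBin(as.integer(sr), con, 4L, endian = "little")
  writeBin(as.integer(sr * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
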