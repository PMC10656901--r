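#' Log-mel frontend parameters
#'
#' Constants of the log-mel feature frontend. The defaults follow the
#' reference configuration of the VGGish audio embedding: audio resampled to
#' 16 kHz, magnitude STFT with a 25 ms periodic Hann window and 10 ms hop,
#' a 64-band mel filterbank spanning 125-7500 Hz, log compression with a
#' 0.01 offset, and non-overlapping groups of 96 frames (0.96 s) per patch.
#'
#' @param sr_target resample target in Hz.
#' @param stft_win_ms STFT window length in ms.
#' @param stft_hop_ms STFT hop in ms.
#' @param n_mels number of mel bands.
#' @param fmin,fmax mel filterbank edges in Hz.
#' @param log_offset additive offset before the log (prevents -Inf).
#' @param frames_per_patch frames grouped into one patch.
#' @param resampler `"fft"` (spectral truncation, exact for band-limited
#'   signals) or `"polyphase"` ([signal::resample()]); both are windowed-sinc
#'   style band-limited interpolators and differ at the 1e-3 level.
#' @return A list of class `frontend_params`.
#' @export
frontend_params <- function(sr_target = 16000, stft_win_ms = 25, stft_hop_ms = 10,
                            n_mels = 64, fmin = 125, fmax = 7500,
                            log_offset = 0.01, frames_per_patch = 96,
                            resampler = c("fft", "polyphase")) {
  resampler <- match.arg(resampler)
  stopifnot(fmin > 0, fmax > fmin, fmax <= sr_target / 2, n_mels >= 1)
  structure(list(sr_target = sr_target, stft_win_ms = stft_win_ms,
                 stft_hop_ms = stft_hop_ms, n_mels = n_mels, fmin = fmin,
                 fmax = fmax, log_offset = log_offset,
                 frames_per_patch = frames_per_patch, resampler = resampler),
            class = "frontend_params")
}

hz_to_mel <- function(f) 1127 * log(1 + f / 700)
mel_to_hz <- function(m) 700 * (exp(m / 1127) - 1)

#' Mel filterbank band edges and centres
#'
#' @param params a [frontend_params()] object.
#' @return Data frame with one row per band: `lower`, `center`, `upper` (Hz).
#' @export
mel_band_edges <- function(params = frontend_params()) {
  mel_pts <- seq(hz_to_mel(params$fmin), hz_to_mel(params$fmax),
                 length.out = params$n_mels + 2L)
  hz <- mel_to_hz(mel_pts)
  data.frame(band = seq_len(params$n_mels),
             lower = hz[seq_len(params$n_mels)],
             center = hz[seq_len(params$n_mels) + 1L],
             upper = hz[seq_len(params$n_mels) + 2L])
}

# Triangular mel filterbank matrix (n_bins x n_mels) on the positive-frequency
# STFT bins.
mel_filterbank <- function(params, n_fft, sr) {
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sr / n_fft
  edges <- mel_band_edges(params)
  fb <- matrix(0, n_bins, params$n_mels)
  for (b in seq_len(params$n_mels)) {
    lo <- edges$lower[b]; ce <- edges$center[b]; up <- edges$upper[b]
    rise <- (freqs - lo) / (ce - lo)
    fall <- (up - freqs) / (up - ce)
    fb[, b] <- pmax(0, pmin(rise, fall))
  }
  fb
}

# Band-limited resampling from sr_in to sr_out.
resample_audio <- function(x, sr_in, sr_out, method = "fft") {
  if (sr_in == sr_out) return(x)
  if (method == "polyphase") {
    g <- gcd_int(round(sr_out), round(sr_in))
    return(signal::resample(x, round(sr_out) / g, round(sr_in) / g))
  }
  n <- length(x)
  n2 <- round(n * sr_out / sr_in)
  # zero-pad to a 2-3-5-smooth length divisible by the rate denominator, so
  # both FFT lengths stay highly composite for any input length
  g <- gcd_int(round(sr_out), round(sr_in))
  p <- round(sr_out) / g; q <- round(sr_in) / g
  m <- stats::nextn(ceiling(n / q), c(2, 3, 5)) * q
  if (m > n) x <- c(x, numeric(m - n))
  m2 <- m * p / q
  X <- stats::fft(x)
  Y <- complex(real = numeric(m2), imaginary = numeric(m2))
  keep <- min(m2 %/% 2L, m %/% 2L)
  Y[seq_len(keep)] <- X[seq_len(keep)]
  Y[(m2 - keep + 2L):m2] <- X[(m - keep + 2L):m]
  Re(stats::fft(Y, inverse = TRUE))[seq_len(n2)] / m
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Compute log-mel patches from an audio clip
#'
#' Resamples the clip to `params$sr_target`, computes a magnitude STFT
#' (periodic Hann window, FFT length the next power of two above the window),
#' pools through a triangular mel filterbank, applies
#' `log(mel + log_offset)`, and groups consecutive non-overlapping runs of
#' `frames_per_patch` STFT frames into patches. A trailing partial patch is
#' dropped, so a 300 s clip yields exactly 312 patches of 96 x 64 values,
#' each covering 0.96 s.
#'
#' @param clip an [audio_clip()].
#' @param params a [frontend_params()] object.
#' @return Object of class `logmel_patches`: list with `values` (array
#'   `n_patches x frames_per_patch x n_mels`), `t0` (patch start offsets in
#'   seconds on the resampled time axis), `hop` (patch duration in s) and
#'   `params`. A clip shorter than one patch yields zero patches with a
#'   warning.
#' @export
logmel_patches <- function(clip, params = frontend_params()) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- resample_audio(clip$samples, clip$sr, params$sr_target, params$resampler)
  sr <- params$sr_target
  win <- round(params$stft_win_ms / 1000 * sr)
  hop <- round(params$stft_hop_ms / 1000 * sr)
  fpp <- params$frames_per_patch
  n <- length(x)
  n_frames <- if (n < win) 0L else 1L + (n - win) %/% hop
  n_patches <- n_frames %/% fpp
  if (n_patches == 0L) {
    warnf("clip shorter than one %.2f s patch; returning an empty patch sequence",
          fpp * params$stft_hop_ms / 1000)
    return(structure(list(values = array(0, c(0L, fpp, params$n_mels)),
                          t0 = numeric(0), hop = fpp * params$stft_hop_ms / 1000,
                          params = params, clip_site = clip$site,
                          clip_start = clip$start),
                     class = "logmel_patches"))
  }
  n_fft <- 2L^ceiling(log2(win))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1L) / win)  # periodic Hann
  fb <- mel_filterbank(params, n_fft, sr)
  n_used <- n_patches * fpp

  vals <- array(0, c(n_used, params$n_mels))
  chunk <- 4096L
  for (f0 in seq(0L, n_used - 1L, by = chunk)) {
    fi <- f0:min(f0 + chunk - 1L, n_used - 1L)
    idx <- outer(seq_len(win) - 1L, fi * hop, "+") + 1L
    Fm <- matrix(x[idx], win, length(fi)) * w
    Fm <- rbind(Fm, matrix(0, n_fft - win, length(fi)))
    S <- Mod(stats::mvfft(Fm)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])
    vals[fi + 1L, ] <- crossprod(S, fb)
  }
  vals <- log(vals + params$log_offset)
  patch_len <- fpp * params$stft_hop_ms / 1000
  structure(list(values = aperm(array(vals, c(fpp, n_patches, params$n_mels)),
                                c(2L, 1L, 3L)),
                 t0 = (seq_len(n_patches) - 1L) * patch_len,
                 hop = patch_len, params = params,
                 clip_site = clip$site, clip_start = clip$start),
            class = "logmel_patches")
}

#' @export
print.logmel_patches <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<logmel_patches> %d patches of %d frames x %d mel bands (%.2f s each)\n",
              d[1], d[2], d[3], x$hop))
  invisible(x)
}

#' Number of patches in a `logmel_patches` object
#' @param patches a `logmel_patches` object.
#' @export
n_patches <- function(patches) dim(patches$values)[1L]
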