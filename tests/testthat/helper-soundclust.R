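# Shared fixtures, all built in code.

# Short noise clip.
noise_clip <- function(dur_s = 2, sr = 16000, sd = 0.01, seed = 99) {
  withr_seed <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  audio_clip(rnorm(dur_s * sr, sd = sd), sr)
}

# Pure-tone clip.
tone_clip <- function(freq, dur_s = 2, sr = 16000, amp = 0.5) {
  audio_clip(amp * sin(2 * pi * freq * (0:(dur_s * sr - 1)) / sr), sr)
}

# Write an interleaved 16-bit stereo PCM WAV by hand (the package writer is
# mono-only, so stereo reading is exercised against an independent writer).
write_stereo_wav <- function(left, right, sr, path) {
  inter <- as.integer(round(rbind(left, right) * 32767))
  n_bytes <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(as.integer(sr), con, 4L, endian = "little")
  writeBin(as.integer(sr * 4L), con, 4L, endian = "little")
  writeBin(4L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(as.vector(inter), con, 2L, endian = "little")
  invisible(path)
}

# Labelled minute table built directly (no audio), for summary-module tests.
make_labelled_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$start <- as.POSIXct(df$start, tz = "UTC")
  df$date <- as.Date(df$start)
  df$hour <- as.integer(format(df$start, "%H", tz = "UTC"))
  df$month <- as.integer(format(df$start, "%m", tz = "UTC"))
  class(df) <- c("minute_features", "data.frame")
  df
}

# Tiny VGG-style synthetic weights (manifest + float32 binary); random but
# correctly shaped, enough to exercise the forward pass.
write_tiny_vggish_weights <- function(dir, seed = 5) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- list(
    list(name = "conv1", type = "conv", shape = c(3L, 3L, 1L, 2L)),
    list(name = "pool1", type = "pool"),
    list(name = "conv2", type = "conv", shape = c(3L, 3L, 2L, 4L)),
    list(name = "pool2", type = "pool"),
    list(name = "fc1", type = "dense", shape = c(24L * 16L * 4L, 32L)),
    list(name = "embedding", type = "dense", shape = c(32L, 128L)))
  w <- numeric(0)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "pool") next
    layers[[i]]$offset <- length(w)
    n_w <- prod(l$shape); n_b <- l$shape[length(l$shape)]
    w <- c(w, rnorm(n_w, sd = 0.05), rnorm(n_b, sd = 0.01))
  }
  bin <- file.path(dir, "weights.bin")
  con <- file(bin, "wb"); writeBin(w, con, size = 4L, endian = "little"); close(con)
  manifest <- file.path(dir, "weights.json")
  jsonlite::write_json(list(bin = "weights.bin", layers = layers), manifest,
                       auto_unbox = TRUE, digits = NA)
  manifest
}

# The per-component cluster counts of the published 95-cluster inventory.
component_map_95 <- function() {
  comps <- rep(c("mainly bird", "mainly insect", "mainly rain",
                 "no obvious biophony", "bird and insect", "bird and rain",
                 "biophony and anthropophony"),
               times = c(14, 30, 12, 22, 12, 2, 3))
  data.frame(cluster_id = 0:94, component = comps)
}
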