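# Synthetic soundscape generation: scheduled recordings with known source
# ground truth, rendered audio, and direct embedding-space mixtures.

#' Specify a synthetic sound source
#'
#' A source has a spectral band, an event model, relative diel and monthly
#' activity curves, a signal-to-noise ratio over the noise floor, a mean
#' daily event rate and an event duration range.
#'
#' @param name one of `"bird"`, `"insect"`, `"rain"`, `"anthro"`,
#'   `"silence"`.
#' @param band_hz length-2 numeric, lower/upper frequency bound in Hz.
#' @param event_model `"burst"`, `"continuous"` or `"broadband"`.
#' @param diel_curve 24 non-negative values of relative activity by hour.
#' @param month_curve 12 non-negative values of relative activity by month.
#' @param snr_db mean event level in dB over the noise floor.
#' @param events_per_day mean Poisson event count per day at the peak month.
#' @param dur_range_s length-2 numeric, event duration range in seconds.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(name, band_hz, event_model, diel_curve, month_curve,
                        snr_db, events_per_day, dur_range_s) {
  name <- match.arg(name, c("bird", "insect", "rain", "anthro", "silence"))
  event_model <- match.arg(event_model, c("burst", "continuous", "broadband"))
  if (length(diel_curve) != 24L || any(diel_curve < 0) || !any(diel_curve > 0))
    stopf("source '%s': diel_curve must be 24 non-negative values with at least one > 0", name)
  if (length(month_curve) != 12L || any(month_curve < 0) || !any(month_curve > 0))
    stopf("source '%s': month_curve must be 12 non-negative values with at least one > 0", name)
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stopf("source '%s': band_hz must be an increasing positive pair", name)
  structure(list(name = name, band_hz = as.numeric(band_hz),
                 event_model = event_model, diel_curve = as.numeric(diel_curve),
                 month_curve = as.numeric(month_curve), snr_db = snr_db,
                 events_per_day = events_per_day,
                 dur_range_s = as.numeric(dur_range_s)),
            class = "source_spec")
}

#' Default synthetic source inventory
#'
#' Four sources emulating the main soundscape constituents of a subtropical
#' forest recording campaign: bird-like upward FM chirps (2-8 kHz) with a
#' dawn peak around 06:00 and a secondary dusk bump, spring-biased months;
#' insect-like amplitude-modulated tones (3-6 kHz) peaking at night and in
#' late-season months (maximum in August); rain-like broadband band-limited
#' noise with no diel trend; and engine/voice-like low-frequency harmonic
#' stacks in daytime. SNRs default to +20 dB (bird), +15 dB (insect),
#' +10 dB (rain), +10 dB (anthro) over a -50 dBFS Gaussian noise floor.
#'
#' @return Named list of [source_spec()] objects.
#' @export
default_sources <- function() {
  list(
    bird = source_spec("bird", c(2000, 8000), "burst",
      diel_curve = c(0.05, 0.05, 0.05, 0.1, 0.5, 2, 3, 2.5, 1.5, 1, 0.8, 0.6,
                     0.5, 0.5, 0.5, 0.6, 0.8, 1.5, 1.8, 0.8, 0.2, 0.1, 0.05, 0.05),
      month_curve = c(0.2, 0.3, 0.6, 1, 1, 0.9, 0.6, 0.4, 0.3, 0.2, 0.2, 0.2),
      snr_db = 20, events_per_day = 200, dur_range_s = c(0.1, 1)),
    insect = source_spec("insect", c(3000, 6000), "continuous",
      diel_curve = c(2, 2, 1.8, 1.5, 1, 0.4, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1,
                     0.1, 0.1, 0.1, 0.2, 0.3, 0.6, 1.2, 2, 2.5, 2.5, 2.2, 2),
      month_curve = c(0.1, 0.1, 0.1, 0.2, 0.3, 0.4, 0.7, 1, 0.9, 0.8, 0.3, 0.1),
      snr_db = 15, events_per_day = 80, dur_range_s = c(60, 240)),
    rain = source_spec("rain", c(100, 11000), "broadband",
      diel_curve = rep(1, 24),
      month_curve = rep(1, 12),
      snr_db = 10, events_per_day = 12, dur_range_s = c(120, 300)),
    anthro = source_spec("anthro", c(60, 1500), "burst",
      diel_curve = c(rep(0.05, 7), 0.5, rep(1, 11), 0.5, rep(0.05, 4)),
      month_curve = rep(1, 12),
      snr_db = 10, events_per_day = 15, dur_range_s = c(5, 30))
  )
}

# -50 dBFS Gaussian noise floor.
NOISE_FLOOR_DB <- -50

#' Draw a synthetic recording schedule with Poisson source events
#'
#' Builds the recording grid — by default the first `slot_s = 300` seconds
#' of every half hour, i.e. 48 slots per site-day — and draws source events.
#' Event counts per (site, day, hour, source) are Poisson with rate
#' `events_per_day * diel_curve[hour]/sum(diel_curve) *
#' month_curve[month]/max(month_curve)`; each event is placed uniformly
#' inside one of the hour's recording slots, so every event overlaps a slot.
#' Identical seeds give identical schedules.
#'
#' @param sources named list of [source_spec()]s (default [default_sources()]).
#' @param sites number of recording sites (ids `SITE1`, `SITE2`, ...).
#' @param days number of consecutive days.
#' @param seed integer seed.
#' @param start_date first day (default `"2019-04-05"`, the campaign start
#'   the schedule emulates).
#' @param slot_s recording slot duration in seconds (default 300).
#' @return Object of class `event_schedule`: list with `entries` (site,
#'   start, source, duration_s), `grid` (site, start, duration_s), the
#'   sources, and the generation parameters.
#' @export
make_schedule <- function(sources = default_sources(), sites = 1L, days = 1L,
                          seed = 1L, start_date = "2019-04-05", slot_s = 300) {
  stopifnot(days >= 1L, sites >= 1L)
  if (!length(sources)) stop("at least one source is required", call. = FALSE)
  for (s in sources) if (!inherits(s, "source_spec"))
    stop("all sources must be source_spec objects", call. = FALSE)
  names(sources) <- vapply(sources, function(s) s$name, character(1))
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  site_ids <- sprintf("SITE%d", seq_len(sites))

  slot_offsets <- rep(0:23, each = 2L) * 3600 + rep(c(0, 1800), 24L)
  grid <- expand.grid(offset = slot_offsets, day = seq_len(days) - 1L,
                      site = site_ids, stringsAsFactors = FALSE)
  grid <- data.frame(site = grid$site,
                     start = t0 + grid$day * 86400 + grid$offset,
                     duration_s = slot_s)
  grid <- grid[order(grid$site, grid$start), , drop = FALSE]
  rownames(grid) <- NULL

  entries <- with_seed(seed, {
    parts <- list()
    for (site in site_ids) for (d in seq_len(days) - 1L) {
      day_start <- t0 + d * 86400
      m <- as.integer(format(day_start, "%m", tz = "UTC"))
      for (src in sources) {
        diel_n <- src$diel_curve / sum(src$diel_curve)
        mfac <- src$month_curve[m] / max(src$month_curve)
        for (h in 0:23) {
          lam <- src$events_per_day * diel_n[h + 1L] * mfac
          if (lam <= 0) next
          n_ev <- stats::rpois(1L, lam)
          if (n_ev == 0L) next
          half <- sample(c(0, 1800), n_ev, replace = TRUE)
          dur <- stats::runif(n_ev, src$dur_range_s[1], src$dur_range_s[2])
          off <- stats::runif(n_ev) * pmax(slot_s - dur, 0)
          parts[[length(parts) + 1L]] <- data.frame(
            site = site, start = day_start + h * 3600 + half + off,
            source = src$name, duration_s = dur)
        }
      }
    }
    if (length(parts)) do.call(rbind, parts)
    else data.frame(site = character(), start = as.POSIXct(character(), tz = "UTC"),
                    source = character(), duration_s = numeric())
  })
  entries <- entries[order(entries$site, entries$start), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, grid = grid, sources = sources,
                 seed = as.integer(seed), slot_s = slot_s, sites = sites,
                 days = days, start_date = start_date),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> %d sites x %d days: %d recording slots, %d events\n",
              x$sites, x$days, nrow(x$grid), nrow(x$entries)))
  if (nrow(x$entries)) print(table(x$entries$source))
  invisible(x)
}

#' Write the ground-truth schedule as CSV
#' @param schedule an `event_schedule`.
#' @param path output CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- schedule$entries
  df$start_iso <- format(df$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df[, c("site", "start_iso", "source", "duration_s")],
                   path, row.names = FALSE)
  invisible(path)
}

# Events of `schedule` overlapping [slot_start, slot_start + slot_s) at `site`.
events_in_slot <- function(schedule, site, slot_start) {
  e <- schedule$entries
  sel <- e$site == site &
    as.numeric(e$start) < as.numeric(slot_start) + schedule$slot_s &
    as.numeric(e$start) + e$duration_s > as.numeric(slot_start)
  e[sel, , drop = FALSE]
}

render_event <- function(src, dur, sr, amp) {
  n <- max(1L, round(dur * sr))
  t <- (seq_len(n) - 1L) / sr
  lo <- src$band_hz[1]; hi <- src$band_hz[2]; bw <- hi - lo
  if (src$name == "bird") {
    f0 <- stats::runif(1, lo, hi - 0.3 * bw)
    f1 <- min(f0 + stats::runif(1, 0.1, 0.3) * bw, hi)
    freq <- f0 + (f1 - f0) * t / max(t[n], 1e-9)       # upward FM sweep
    phase <- 2 * pi * cumsum(freq) / sr
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1L))
    amp * sqrt(2) * env * sin(phase)
  } else if (src$name == "insect") {
    cf <- stats::runif(1, lo + 0.1 * bw, hi - 0.1 * bw)
    fm <- stats::runif(1, 8, 40)
    amp * sqrt(2) * (0.6 + 0.4 * sin(2 * pi * fm * t)) * sin(2 * pi * cf * t +
                                                             stats::runif(1, 0, 2 * pi))
  } else if (src$name == "rain") {
    # pad to a 2-3-5-smooth FFT length: arbitrary n can have large prime
    # factors that make the mixed-radix FFT pathologically slow
    m <- stats::nextn(n, c(2, 3, 5))
    x <- stats::rnorm(m)
    X <- stats::fft(x)
    f <- (seq_len(m) - 1L) * sr / m
    f <- pmin(f, sr - f)                                # two-sided frequencies
    X[f < lo | f > hi] <- 0
    y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
    rms <- sqrt(mean(y^2))
    if (rms > 0) y <- y / rms
    amp * y
  } else if (src$name == "anthro") {
    f0 <- stats::runif(1, max(lo, 60), min(200, hi))
    ks <- which(seq_len(8L) * f0 <= hi)
    y <- numeric(n)
    for (k in ks)
      y <- y + sin(2 * pi * k * f0 * t + stats::runif(1, 0, 2 * pi)) / k
    rms <- sqrt(mean(y^2))
    if (rms > 0) y <- y / rms
    amp * y
  } else numeric(n)                                     # silence
}

#' Render one scheduled recording slot as audio
#'
#' Sums the slot's scheduled source events over a Gaussian noise floor at
#' -50 dBFS: bird events are upward frequency-modulated tonal bursts,
#' insects amplitude-modulated narrowband tones, rain band-limited noise,
#' anthropophony a low-frequency harmonic stack. Event levels follow each
#' source's `snr_db`. Output is a mono clip of the slot duration with peak
#' amplitude at most 1 and no synthesis above the source bands.
#'
#' @param schedule an `event_schedule`.
#' @param site site id present in the schedule grid.
#' @param slot `POSIXct` slot start; must be a grid slot of that site.
#' @param sr sample rate in Hz (default 24000); must be at least twice the
#'   highest scheduled source band edge.
#' @param seed integer seed; rendering is a pure function of
#'   (schedule, site, slot, sr, seed).
#' @return An [audio_clip()] with site and start set.
#' @export
synth_recording <- function(schedule, site, slot, sr = 24000, seed = 1L) {
  stopifnot(inherits(schedule, "event_schedule"))
  g <- schedule$grid
  slot_idx <- which(g$site == site & as.numeric(g$start) == as.numeric(slot))
  if (length(slot_idx) != 1L)
    stopf("slot %s at site %s is not in the recording grid",
          format(slot, "%Y-%m-%d %H:%M:%S", tz = "UTC"), site)
  max_band <- max(vapply(schedule$sources, function(s) s$band_hz[2], numeric(1)))
  if (sr < 2 * max_band)
    stopf("sample rate %g Hz below twice the maximum source band edge (%g Hz)",
          sr, max_band)
  n <- round(schedule$slot_s * sr)
  floor_sd <- 10^(NOISE_FLOOR_DB / 20)
  ev <- events_in_slot(schedule, site, slot)
  x <- with_seed(derive_seed(seed, slot_idx), {
    out <- stats::rnorm(n, sd = floor_sd)
    if (nrow(ev)) for (i in seq_len(nrow(ev))) {
      src <- schedule$sources[[ev$source[i]]]
      amp <- floor_sd * 10^(src$snr_db / 20)
      rel <- as.numeric(ev$start[i]) - as.numeric(slot)
      i0 <- max(0L, round(rel * sr))
      # render only the portion overlapping the slot (event textures are
      # stationary, so truncation does not change their character)
      eff_dur <- min(ev$duration_s[i], schedule$slot_s - max(rel, 0))
      seg <- render_event(src, eff_dur, sr, amp)
      keep <- min(length(seg), n - i0)
      if (keep > 0L)
        out[(i0 + 1L):(i0 + keep)] <- out[(i0 + 1L):(i0 + keep)] + seg[seq_len(keep)]
    }
    out
  })
  peak <- max(abs(x))
  if (peak > 1) x <- x * (0.99 / peak)
  audio_clip(x, sr, site = site, start = slot)
}

#' Render a whole schedule to WAV files
#'
#' Writes one 16-bit PCM WAV per recording slot, named
#' `SITE<k>_YYYYMMDD_HHMMSS.wav`, plus the ground-truth event schedule as
#' `schedule.csv`.
#'
#' @inheritParams synth_recording
#' @param dir output directory (created if needed).
#' @return Data frame manifest (site, start, path), invisibly.
#' @export
render_schedule <- function(schedule, dir, sr = 24000, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- schedule$grid
  paths <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    clip <- synth_recording(schedule, g$site[i], g$start[i], sr, seed)
    fn <- sprintf("%s_%s.wav", g$site[i],
                  format(g$start[i], "%Y%m%d_%H%M%S", tz = "UTC"))
    paths[i] <- file.path(dir, fn)
    write_wav(clip$samples, sr, paths[i])
  }
  write_schedule_csv(schedule, file.path(dir, "schedule.csv"))
  invisible(data.frame(site = g$site, start = g$start, path = paths))
}

#' Ground-truth dominant source per recorded minute
#'
#' For each recording slot and each complete 59.52 s minute block within it,
#' the source with the largest total overlap duration; blocks with no event
#' overlap are labelled `"silence"`. This is the ground truth against which
#' cluster-to-component recovery is scored on synthetic data.
#'
#' @param schedule an `event_schedule`.
#' @param block_s minute-block duration in seconds (default 59.52).
#' @return Data frame: site, start (slot), minute_index, label.
#' @export
truth_labels <- function(schedule, block_s = 59.52) {
  g <- schedule$grid
  n_min <- floor(schedule$slot_s / block_s)
  e <- schedule$entries
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    s0 <- as.numeric(g$start[i])
    ev <- e[e$site == g$site[i] &
              as.numeric(e$start) < s0 + schedule$slot_s &
              as.numeric(e$start) + e$duration_s > s0, , drop = FALSE]
    lab <- character(n_min)
    for (j in seq_len(n_min)) {
      w0 <- s0 + (j - 1L) * block_s; w1 <- w0 + block_s
      if (nrow(ev)) {
        ov <- pmin(as.numeric(ev$start) + ev$duration_s, w1) -
              pmax(as.numeric(ev$start), w0)
        ov <- pmax(ov, 0)
        tot <- tapply(ov, ev$source, sum)
        tot <- tot[tot > 0]
        lab[j] <- if (length(tot)) names(tot)[which.max(tot)] else "silence"
      } else lab[j] <- "silence"
    }
    out[[i]] <- data.frame(site = g$site[i], start = g$start[i],
                           minute_index = seq_len(n_min) - 1L, label = lab)
  }
  do.call(rbind, out)
}

#' Synthetic embedding-space mixture with known labels
#'
#' Draws `k_true` cluster means with coordinates i.i.d.
#' `N(0, separation^2 / 2)` — so the expected pairwise centre distance is
#' `separation * sqrt(dim)` and `separation` acts as a per-coordinate
#' displacement scale — and `n_per_cluster` points per cluster with unit
#' spherical covariance. Synthetic (site, timestamp) metadata is attached so
#' the table is a drop-in for the clustering stage; the true labels are
#' returned for scoring only.
#'
#' @param k_true number of clusters (>= 1).
#' @param n_per_cluster points per cluster.
#' @param dim feature dimension (default 128).
#' @param separation per-coordinate separation scale (>= 0; 0 makes all
#'   clusters coincide).
#' @param seed integer seed.
#' @return List with `table` (a `minute_features` data frame) and `labels`
#'   (integer true cluster per row, `0..k_true-1`).
#' @export
synth_embedding_dataset <- function(k_true, n_per_cluster, dim = 128L,
                                    separation = 10, seed = 1L) {
  stopifnot(k_true >= 1L, n_per_cluster >= 1L, separation >= 0)
  if (n_per_cluster < dim + 1L)
    warnf(paste("n_per_cluster (%d) < dim + 1 (%d): full-covariance fits",
                "downstream risk singular covariances"), n_per_cluster, dim + 1L)
  X <- with_seed(seed, {
    mu <- matrix(stats::rnorm(k_true * dim, sd = separation / sqrt(2)), k_true, dim)
    pts <- matrix(stats::rnorm(k_true * n_per_cluster * dim), ncol = dim)
    pts + mu[rep(seq_len(k_true), each = n_per_cluster), , drop = FALSE]
  })
  labels <- rep(seq_len(k_true) - 1L, each = n_per_cluster)
  n <- nrow(X)
  t0 <- as.POSIXct("2019-04-05 00:00:00", tz = "UTC")
  slot <- (seq_len(n) - 1L) %/% 5L
  mi <- (seq_len(n) - 1L) %% 5L
  ts <- t0 + slot * 1800 + mi * 59.52
  df <- data.frame(site = "SITE1", start = t0 + slot * 1800, minute_index = mi,
                   hour = as.integer(format(ts, "%H", tz = "UTC")),
                   date = as.Date(ts, tz = "UTC"),
                   month = as.integer(format(ts, "%m", tz = "UTC")))
  colnames(X) <- sprintf("f%03d", seq_len(dim) - 1L)
  out <- cbind(df, as.data.frame(X))
  class(out) <- c("minute_features", "data.frame")
  list(table = out, labels = labels)
}
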