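test_that("recording grid follows the half-hour study design", {
  sch <- make_schedule(sites = 1, days = 1, seed = 1)
  expect_equal(nrow(sch$grid), 48L)  # 24 h x 2 slots/h
  mins <- as.integer(format(sch$grid$start, "%M", tz = "UTC"))
  expect_true(all(mins %in% c(0L, 30L)))
  expect_true(all(sch$grid$duration_s == 300))
  sch3 <- make_schedule(sites = 2, days = 3, seed = 1)
  expect_equal(nrow(sch3$grid), 2L * 3L * 48L)
})

test_that("schedules are a pure function of (config, seed)", {
  a <- make_schedule(sites = 2, days = 2, seed = 7)
  b <- make_schedule(sites = 2, days = 2, seed = 7)
  expect_identical(a$entries, b$entries)
  c <- make_schedule(sites = 2, days = 2, seed = 8)
  expect_false(identical(a$entries, c$entries))
})

test_that("a degenerate diel curve confines events to its hour", {
  diel <- rep(0, 24); diel[7] <- 1  # hour 6
  bird <- source_spec("bird", c(2000, 8000), "burst", diel, rep(1, 12),
                      snr_db = 20, events_per_day = 50, dur_range_s = c(0.1, 1))
  sch <- make_schedule(list(bird), sites = 1, days = 5, seed = 2)
  hrs <- as.integer(format(sch$entries$start, "%H", tz = "UTC"))
  expect_true(nrow(sch$entries) > 0)
  expect_true(all(hrs == 6L))
})

test_that("all-zero activity curves are rejected", {
  expect_error(source_spec("bird", c(2000, 8000), "burst", rep(0, 24), rep(1, 12),
                           20, 10, c(0.1, 1)), "diel_curve")
  expect_error(source_spec("bird", c(2000, 8000), "burst", rep(1, 24), rep(0, 12),
                           20, 10, c(0.1, 1)), "month_curve")
})

test_that("every event overlaps a recording slot", {
  sch <- make_schedule(sites = 1, days = 2, seed = 11)
  e <- sch$entries; g <- sch$grid
  ok <- vapply(seq_len(nrow(e)), function(i) {
    s <- as.numeric(e$start[i]); d <- e$duration_s[i]
    any(g$site == e$site[i] &
          as.numeric(g$start) < s + d &
          as.numeric(g$start) + g$duration_s > s)
  }, logical(1))
  expect_true(all(ok))
})

test_that("per-hour event counts match the Poisson rates within 3 SE", {
  days <- 120
  bird <- default_sources()$bird
  sch <- make_schedule(list(bird), sites = 1, days = days, seed = 13,
                       start_date = "2019-05-01")
  hrs <- as.integer(format(sch$entries$start, "%H", tz = "UTC"))
  counts <- tabulate(hrs + 1L, nbins = 24L)
  # oracle rate: sum the per-day rates, month factor included
  day_months <- as.integer(format(as.Date("2019-05-01") + 0:(days - 1), "%m"))
  mfac_total <- sum(bird$month_curve[day_months] / max(bird$month_curve))
  expected <- bird$events_per_day * bird$diel_curve / sum(bird$diel_curve) * mfac_total
  se <- sqrt(pmax(expected, 1))
  z <- abs(counts - expected) / se
  # joint check over 24 hourly bins: essentially all within 3 SE, none wild
  expect_lte(sum(z > 3), 2)
  expect_true(all(z <= 4.5))
})

test_that("an event-free slot is noise floor only", {
  silent <- source_spec("bird", c(2000, 8000), "burst",
                        c(1, rep(0, 23)), rep(1, 12), 20, 2, c(0.1, 0.5))
  sch <- make_schedule(list(silent), sites = 1, days = 1, seed = 4, slot_s = 30)
  # pick a noon slot: no events scheduled outside hour 0
  slot <- sch$grid$start[sch$grid$start == as.POSIXct("2019-04-05 12:00:00", tz = "UTC")]
  clip <- synth_recording(sch, "SITE1", slot, sr = 24000, seed = 6)
  expect_equal(sd(clip$samples), 10^(-50 / 20), tolerance = 0.05)
  # spectral flatness of white noise is close to 1
  spec <- Mod(fft(clip$samples))^2
  spec <- spec[2:(length(spec) / 2)]
  flatness <- exp(mean(log(spec))) / mean(spec)
  expect_gt(flatness, 0.5)
})

test_that("an insect-only slot peaks inside the insect band", {
  ins <- source_spec("insect", c(3000, 6000), "continuous", rep(1, 24), rep(1, 12),
                     snr_db = 15, events_per_day = 2000, dur_range_s = c(30, 30))
  sch <- make_schedule(list(ins), sites = 1, days = 1, seed = 21, slot_s = 30)
  clip <- synth_recording(sch, "SITE1", sch$grid$start[25], sr = 24000, seed = 3)
  spec <- Mod(fft(clip$samples))^2
  freqs <- (seq_along(spec) - 1) * clip$sr / length(spec)
  half <- freqs <= clip$sr / 2
  peak_hz <- freqs[half][which.max(spec[half])]
  expect_gte(peak_hz, 3000)
  expect_lte(peak_hz, 6000)
})

test_that("rendering is deterministic, clip-safe and band-limited", {
  sch <- make_schedule(sites = 1, days = 1, seed = 31, slot_s = 60)
  slot <- sch$grid$start[13]
  a <- synth_recording(sch, "SITE1", slot, sr = 24000, seed = 9)
  b <- synth_recording(sch, "SITE1", slot, sr = 24000, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_lte(max(abs(a$samples)), 1)
  # slot must be a grid slot
  expect_error(synth_recording(sch, "SITE1", slot + 60, seed = 9), "not in the recording grid")
  # Nyquist must cover the source bands
  expect_error(synth_recording(sch, "SITE1", slot, sr = 8000, seed = 9),
               "twice the maximum source band")
})

test_that("truth labels follow scheduled dominance", {
  diel <- rep(0, 24); diel[7] <- 1
  bird <- source_spec("bird", c(2000, 8000), "burst", diel, rep(1, 12),
                      snr_db = 20, events_per_day = 400, dur_range_s = c(0.5, 1))
  sch <- make_schedule(list(bird), sites = 1, days = 1, seed = 2, slot_s = 60)
  tl <- truth_labels(sch)
  expect_equal(nrow(tl), 48L)  # one minute block per 60 s slot
  hrs <- as.integer(format(tl$start, "%H", tz = "UTC"))
  expect_true(all(tl$label[hrs == 6] == "bird"))
  expect_true(all(tl$label[hrs != 6] == "silence"))
})

test_that("embedding-space mixtures have the stated geometry", {
  ds <- synth_embedding_dataset(k_true = 3, n_per_cluster = 150, dim = 128,
                                separation = 10, seed = 5)
  X <- feature_matrix(ds$table)
  expect_equal(ncol(X), 128L)
  expect_equal(nrow(X), 450L)
  expect_equal(length(ds$labels), 450L)
  # same seed reproduces; separation 0 collapses the centres
  ds2 <- synth_embedding_dataset(3, 150, 128, 10, seed = 5)
  expect_identical(ds$table, ds2$table)
  d0 <- synth_embedding_dataset(3, 50, 16, 0, seed = 5)
  mus <- sapply(split(as.data.frame(feature_matrix(d0$table)), d0$labels), colMeans)
  expect_lt(max(dist(t(mus))), 1)  # centres coincide up to sampling noise
  expect_warning(synth_embedding_dataset(2, 10, 64, 5, seed = 1), "singular")
})
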