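test_that("the taxonomy is the closed seven-component set", {
  tax <- component_taxonomy()
  expect_length(tax, 7L)
  expect_true(all(c("mainly bird", "mainly insect", "mainly rain",
                    "no obvious biophony", "bird and insect", "bird and rain",
                    "biophony and anthropophony") %in% tax))
})

test_that("a 95-cluster mapping with the published counts validates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.csv")
  write.csv(component_map_95(), path, row.names = FALSE)
  map <- load_component_map(path, 0:94)
  counts <- table(factor(map$entries, levels = component_taxonomy()))
  expect_equal(unname(as.integer(counts)), c(14L, 30L, 12L, 22L, 12L, 2L, 3L))
  expect_equal(sum(counts), 95L)
  # the shipped example fixture is the same mapping
  shipped <- system.file("extdata", "component_map_synthetic95.csv",
                         package = "soundclust")
  expect_equal(load_component_map(shipped, 0:94)$entries, map$entries)
})

test_that("mapping violations are all reported", {
  dir <- withr::local_tempdir()
  df <- component_map_95()
  # missing cluster
  p1 <- file.path(dir, "m1.csv")
  write.csv(df[-1, ], p1, row.names = FALSE)
  expect_error(load_component_map(p1, 0:94), "missing cluster id\\(s\\): 0")
  # unknown component string, with row number
  df2 <- df; df2$component[5] <- "birds"
  p2 <- file.path(dir, "m2.csv")
  write.csv(df2, p2, row.names = FALSE)
  expect_error(load_component_map(p2, 0:94), "row 5: unknown component 'birds'")
  # duplicate cluster
  df3 <- rbind(df, df[1, ])
  p3 <- file.path(dir, "m3.csv")
  write.csv(df3, p3, row.names = FALSE)
  expect_error(load_component_map(p3, 0:94), "duplicate cluster")
})

test_that("apply_map is a total lookup whose counts push forward", {
  tab <- make_labelled_table(list(
    list(site = "SITE1", start = "2019-05-01 06:00:00", minute_index = 0:4)))
  tab$component <- NULL
  assignments <- c(0L, 0L, 1L, 2L, 1L)
  entries <- setNames(c("mainly rain", "mainly bird", "no obvious biophony"),
                      c("0", "1", "2"))
  map <- soundclust:::new_component_map(entries)
  out <- apply_map(tab, assignments, map)
  expect_equal(out$component,
               c("mainly rain", "mainly rain", "mainly bird",
                 "no obvious biophony", "mainly bird"))
  # pushforward: component counts equal cluster counts through the map
  comp_counts <- table(out$component)
  clus_counts <- table(assignments)
  expect_equal(unname(comp_counts[["mainly rain"]]), unname(clus_counts[["0"]]))
  # empty table maps to empty output
  empty <- out[0, ]
  expect_equal(nrow(apply_map(empty, integer(0), map)), 0L)
})

test_that("majority vote labels clusters by their dominant true source", {
  assignments <- c(0, 0, 0, 1, 1, 2, 2, 2, 2)
  labels <- c("bird", "bird", "insect", "rain", "rain",
              "silence", "silence", "silence", "anthro")
  map <- majority_component_map(assignments, labels)
  expect_equal(unname(map$entries[c("0", "1", "2")]),
               c("mainly bird", "mainly rain", "no obvious biophony"))
  expect_true(all(map$entries %in% component_taxonomy()))
})

test_that("the review pack manifests exemplars and flags missing audio", {
  dir <- withr::local_tempdir()
  audio <- file.path(dir, "audio"); out <- file.path(dir, "pack")
  dir.create(audio)
  t1 <- as.POSIXct("2019-05-01 06:00:00", tz = "UTC")
  t2 <- as.POSIXct("2019-05-01 06:30:00", tz = "UTC")
  write_wav(rnorm(8000 * 125, sd = 0.05), 8000,
            file.path(audio, "SITE1_20190501_060000.wav"))
  ex <- data.frame(cluster = c(0L, 0L, 1L), site = "SITE1",
                   start = c(t1, t1, t2), minute_index = c(0L, 1L, 0L),
                   distance = c(0.1, 0.2, 0.3))
  expect_warning(man <- export_review_pack(ex, audio, out, snippets = TRUE),
                 "missing")
  expect_equal(nrow(man), 3L)
  expect_equal(man$status, c("ok", "ok", "missing"))
  expect_true(all(man$duration_s == 59.52))
  # spectrogram parameters logged verbatim in the manifest header
  header <- readLines(file.path(out, "review_manifest.csv"), n = 3)
  expect_true(any(grepl("Hann window, FFT = 512, window overlap of 50%", header)))
  # snippet cut to one minute block
  snip <- list.files(out, pattern = "\\.wav$", full.names = TRUE)
  expect_length(snip, 2L)
  clip <- read_wav(snip[1], warn_metadata = FALSE)
  expect_equal(clip_duration(clip), 59.52, tolerance = 1e-3)
})
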