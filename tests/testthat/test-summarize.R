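`%||%` <- function(a, b) if (is.null(a)) b else a

# Builds a labelled minute table directly: `site_rows` is a list of
# (site, month, days, hours, component, minutes per slot) descriptions.
synthetic_label_table <- function(site_rows) {
  rows <- list()
  for (r in site_rows) {
    for (d in r$days) for (h in r$hours) {
      start <- as.POSIXct(sprintf("2019-%02d-%02d %02d:00:00", r$month, d, h),
                          tz = "UTC")
      rows[[length(rows) + 1L]] <-
        list(site = r$site, start = start,
             minute_index = seq_len(r$n_min %||% 5L) - 1L,
             component = r$component)
    }
  }
  make_labelled_table(rows)
}

test_that("diel proportions normalize per (site, hour) and recover schedules", {
  tab <- synthetic_label_table(list(
    list(site = "SITE1", month = 5, days = 1:3, hours = 5:8, component = "mainly bird"),
    list(site = "SITE1", month = 5, days = 1:3, hours = c(0:4, 9:23),
         component = "mainly insect")))
  prof <- diel_profile(tab)
  sums <- tapply(prof$proportion, paste(prof$site, prof$hour), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  bird <- prof[prof$component == "mainly bird", ]
  expect_true(all(bird$proportion[bird$hour %in% 5:8] == 1))  # birds own 5-8
  expect_true(all(bird$proportion[!bird$hour %in% 5:8] == 0)) # zero elsewhere
  # single-component data gives proportion 1 wherever observed
  solo <- tab[tab$component == "mainly insect", ]
  expect_true(all(diel_profile(solo)$proportion == 1))
})

test_that("per-component normalization is exposed as a flag", {
  tab <- synthetic_label_table(list(
    list(site = "SITE1", month = 5, days = 1:2, hours = 0:23, component = "mainly bird")))
  prof <- diel_profile(tab, normalize = "component")
  expect_equal(sum(prof$proportion), 1, tolerance = 1e-9)
})

test_that("monthly daily counts yield the boxplot statistics", {
  # exactly 2 bird-minutes per day for 30 days: median 2, IQR 0
  tab <- synthetic_label_table(list(
    list(site = "SITE1", month = 6, days = 1:30, hours = 6, component = "mainly bird",
         n_min = 2)))
  mc <- monthly_counts(tab)
  s <- mc$stats[mc$stats$component == "mainly bird", ]
  expect_equal(s$median, 2)
  expect_equal(s$q3 - s$q1, 0)
  expect_equal(s$n_days, 30L)
  expect_true(all(mc$daily$n >= 0 & mc$daily$n == round(mc$daily$n)))
})

test_that("a late-season insect peak shows up as the August maximum", {
  rows <- lapply(list(list(m = 5, n = 1), list(m = 6, n = 2), list(m = 8, n = 5),
                      list(m = 9, n = 3)), function(x)
    list(site = "SITE1", month = x$m, days = 1:10, hours = 21,
         component = "mainly insect", n_min = x$n))
  mc <- monthly_counts(synthetic_label_table(rows))
  s <- mc$stats
  expect_equal(s$month[which.max(s$median)], 8L)
})

test_that("site percentages sum to 100 and degenerate sites are pure", {
  tab <- synthetic_label_table(list(
    list(site = "SITE1", month = 5, days = 1:2, hours = 5:8, component = "mainly bird"),
    list(site = "SITE1", month = 5, days = 1:2, hours = 20:23, component = "mainly insect"),
    list(site = "SITE2", month = 5, days = 1:2, hours = 20:23, component = "mainly insect")))
  sp <- site_proportions(tab)
  tot <- tapply(sp$percentage, sp$site, sum)
  expect_true(all(abs(tot - 100) < 1e-6))
  s2 <- sp[sp$site == "SITE2", ]
  expect_equal(s2$percentage[s2$component == "mainly insect"], 100)
  expect_true(all(s2$percentage[s2$component != "mainly insect"] == 0))
})

test_that("the heatmap takes slot modes with taxonomy-order tie-breaks", {
  t0 <- as.POSIXct("2019-05-01 06:00:00", tz = "UTC")
  tab <- make_labelled_table(list(
    list(site = "SITE1", start = t0, minute_index = 0:4,
         component = c("mainly bird", "mainly bird", "mainly insect",
                       "mainly bird", "mainly rain")),
    # tie bird x2, insect x2: bird is earlier in the taxonomy
    list(site = "SITE1", start = t0 + 1800, minute_index = 0:4,
         component = c("mainly bird", "mainly bird", "mainly insect",
                       "mainly insect", "mainly rain"))))
  M <- heatmap_matrix(tab, "SITE1")
  expect_equal(M["2019-05-01", "06:00"], "mainly bird")
  expect_equal(M["2019-05-01", "06:30"], "mainly bird")
  # absent slots are NA blanks
  extra <- tab[1:5, ]
  extra$start <- extra$start + 86400
  extra$date <- extra$date + 1
  tab2 <- rbind(tab, extra)
  class(tab2) <- class(tab)
  M2 <- heatmap_matrix(tab2, "SITE1")
  expect_true(is.na(M2["2019-05-02", "06:30"]))
})

test_that("summaries are permutation invariant", {
  tab <- synthetic_label_table(list(
    list(site = "SITE1", month = 5, days = 1:3, hours = c(5, 12, 21),
         component = "mainly bird"),
    list(site = "SITE1", month = 5, days = 1:3, hours = c(6, 13, 22),
         component = "mainly insect")))
  set.seed(8)
  shuf <- tab[sample(nrow(tab)), ]
  class(shuf) <- class(tab)
  expect_equal(diel_profile(shuf), diel_profile(tab))
  expect_equal(site_proportions(shuf), site_proportions(tab))
  expect_equal(monthly_counts(shuf)$stats, monthly_counts(tab)$stats)
  expect_equal(heatmap_matrix(shuf, "SITE1"), heatmap_matrix(tab, "SITE1"))
})
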