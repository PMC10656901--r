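# Spatio-temporal summaries of component activity: diel profiles, monthly
# daily-count distributions, per-site proportions and recording-grid
# heatmaps. All are pure aggregations of the labelled minute table; the
# counting unit is the minute-row (5 per full recording slot). Missing
# recordings are simply absent — nothing is imputed.

require_component <- function(table) {
  if (!"component" %in% names(table))
    stop("table has no `component` column: run apply_map() first", call. = FALSE)
}

#' Diel activity profile per site and component
#'
#' For every (site, hour) stratum with data, the proportion of minute-rows
#' carrying each component. With `normalize = "hour"` (default) proportions
#' sum to 1 over components within each (site, hour); `"component"`
#' normalizes each component's counts over the 24 hours instead. Empty
#' strata are omitted, not zero-filled.
#'
#' @param table a labelled minute table (see [apply_map()]).
#' @param normalize `"hour"` or `"component"`.
#' @return Data frame: site, hour, component, n, proportion.
#' @export
diel_profile <- function(table, normalize = c("hour", "component")) {
  normalize <- match.arg(normalize)
  require_component(table)
  agg <- as.data.frame(table(site = table$site, hour = table$hour,
                             component = table$component),
                       stringsAsFactors = FALSE)
  names(agg)[4] <- "n"
  agg$hour <- as.integer(agg$hour)
  if (normalize == "hour") {
    tot <- stats::ave(agg$n, agg$site, agg$hour, FUN = sum)
  } else {
    tot <- stats::ave(agg$n, agg$site, agg$component, FUN = sum)
  }
  agg$proportion <- ifelse(tot > 0, agg$n / tot, NA_real_)
  agg <- agg[tot > 0, , drop = FALSE]
  agg <- agg[order(agg$site, agg$hour, agg$component), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Daily component counts per month with boxplot statistics
#'
#' Counts minute-rows per (site, month, component, date) and summarizes
#' each (site, month, component) over its observed days with median,
#' quartiles and whiskers ([grDevices::boxplot.stats()] conventions).
#' Months without data are absent; missing days shrink the sample and are
#' never imputed.
#'
#' @param table a labelled minute table.
#' @return List with `daily` (site, month, date, component, n) and `stats`
#'   (site, month, component, n_days, whisker_low, q1, median, q3,
#'   whisker_high).
#' @export
monthly_counts <- function(table) {
  require_component(table)
  key <- interaction(table$site, table$month, table$date, table$component, drop = TRUE)
  daily <- as.data.frame(table(site = table$site, month = table$month,
                               date = as.character(table$date),
                               component = table$component),
                         stringsAsFactors = FALSE)
  names(daily)[5] <- "n"
  # keep only (site, date) strata that actually have data that day
  observed <- unique(paste(table$site, as.character(table$date)))
  daily <- daily[paste(daily$site, daily$date) %in% observed, , drop = FALSE]
  daily$month <- as.integer(daily$month)
  # drop cross-tab artefacts pairing a date with a different calendar month
  daily <- daily[as.integer(format(as.Date(daily$date), "%m")) == daily$month, ,
                 drop = FALSE]
  daily$date <- as.Date(daily$date)
  daily <- daily[order(daily$site, daily$date, daily$component), , drop = FALSE]
  rownames(daily) <- NULL

  grp <- interaction(daily$site, daily$month, daily$component, drop = TRUE)
  stats_list <- lapply(split(daily, grp), function(d) {
    bs <- grDevices::boxplot.stats(d$n)
    data.frame(site = d$site[1], month = d$month[1], component = d$component[1],
               n_days = nrow(d), whisker_low = bs$stats[1], q1 = bs$stats[2],
               median = bs$stats[3], q3 = bs$stats[4], whisker_high = bs$stats[5])
  })
  stats_df <- do.call(rbind, stats_list)
  stats_df <- stats_df[order(stats_df$site, stats_df$month, stats_df$component), ,
                       drop = FALSE]
  rownames(stats_df) <- NULL
  list(daily = daily, stats = stats_df)
}

#' Component percentages per site
#'
#' `percentage(site, c) = 100 * rows(site, c) / rows(site)`; percentages
#' sum to 100 within each site.
#'
#' @param table a labelled minute table.
#' @return Data frame: site, component, n, percentage.
#' @export
site_proportions <- function(table) {
  require_component(table)
  agg <- as.data.frame(table(site = table$site, component = table$component),
                       stringsAsFactors = FALSE)
  names(agg)[3] <- "n"
  tot <- stats::ave(agg$n, agg$site, FUN = sum)
  agg$percentage <- 100 * agg$n / tot
  agg <- agg[order(agg$site, agg$component), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Date-by-slot heatmap grid of dominant components
#'
#' For one site, a matrix with one row per calendar date and one column per
#' recording slot time (HH:MM); each cell is the modal component over the
#' slot's minute-rows, ties broken by the fixed taxonomy order, and slots
#' with no data left `NA` (rendered as blanks).
#'
#' @param table a labelled minute table.
#' @param site site id.
#' @return Character matrix (dates x slot times) with `NA` blanks.
#' @export
heatmap_matrix <- function(table, site) {
  require_component(table)
  tb <- table[table$site == site, , drop = FALSE]
  if (!nrow(tb)) stopf("no rows for site %s", site)
  slot_time <- format(tb$start, "%H:%M", tz = "UTC")
  dates <- sort(unique(as.character(tb$date)))
  slots <- sort(unique(slot_time))
  M <- matrix(NA_character_, length(dates), length(slots),
              dimnames = list(dates, slots))
  tax <- component_taxonomy()
  grp <- split(tb$component, paste(as.character(tb$date), slot_time, sep = "|"))
  for (key in names(grp)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    counts <- table(factor(grp[[key]], levels = tax))
    M[parts[1], parts[2]] <- tax[which.max(counts)]  # first max = taxonomy order
  }
  M
}

#' Heatmap of dominant components over the recording grid
#'
#' Renders the [heatmap_matrix()] with [graphics::image()], dates on the
#' x axis and slot time of day on the y axis; blanks are missing data.
#'
#' @param table a labelled minute table.
#' @param site site id.
#' @param ... passed to [graphics::image()].
#' @export
plot_heatmap <- function(table, site, ...) {
  M <- heatmap_matrix(table, site)
  tax <- component_taxonomy()
  Z <- matrix(match(M, tax), nrow(M), ncol(M))
  cols <- grDevices::hcl.colors(length(tax), "Dark 3")
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), Z, zlim = c(1, length(tax)),
                  col = cols, xlab = "day", ylab = "slot", axes = FALSE,
                  main = site, ...)
  graphics::axis(1, at = pretty(seq_len(nrow(M))))
  graphics::axis(2, at = seq(1, ncol(M), length.out = min(8, ncol(M))),
                 labels = colnames(M)[seq(1, ncol(M), length.out = min(8, ncol(M)))])
  invisible(M)
}
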