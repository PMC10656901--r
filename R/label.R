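# Cluster -> soundscape-component mapping. The mapping itself is a human
# listening product and enters the pipeline as data; this module validates
# it, applies it, and exports the exemplar review pack listeners work from.

#' The seven-component soundscape taxonomy
#'
#' The closed component taxonomy, in its fixed order (also the tie-break
#' order used by [heatmap_matrix()]): mainly bird, mainly insect, mainly
#' rain, no obvious biophony, bird and insect, bird and rain, biophony and
#' anthropophony.
#'
#' @return Character vector of length 7.
#' @export
component_taxonomy <- function() {
  c("mainly bird", "mainly insect", "mainly rain", "no obvious biophony",
    "bird and insect", "bird and rain", "biophony and anthropophony")
}

new_component_map <- function(entries) {
  structure(list(entries = entries, components = component_taxonomy()),
            class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  cat(sprintf("<component_map> %d clusters -> %d components\n",
              length(x$entries), length(unique(x$entries))))
  print(table(factor(x$entries, levels = x$components)))
  invisible(x)
}

#' Load and validate a cluster-to-component mapping file
#'
#' Reads a CSV with columns `cluster_id`, `component` and validates it
#' against the fitted model: every model cluster id must appear exactly
#' once and every component must belong to the closed seven-way taxonomy.
#' All violations are collected and reported together, with row numbers for
#' unknown component strings.
#'
#' @param path CSV path.
#' @param model a `soundscape_gmm`, or an integer vector of expected
#'   cluster ids.
#' @return A `component_map` (named character vector of components indexed
#'   by cluster id, wrapped with the taxonomy).
#' @export
load_component_map <- function(path, model) {
  if (!file.exists(path)) stopf("mapping file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "component") %in% names(df)))
    stopf("mapping file %s must have columns cluster_id, component", path)
  expected <- if (inherits(model, "soundscape_gmm")) seq_len(model$K) - 1L
              else as.integer(model)
  tax <- component_taxonomy()
  problems <- character()
  bad <- which(!df$component %in% tax)
  for (i in bad)
    problems <- c(problems, sprintf("row %d: unknown component '%s'", i, df$component[i]))
  dup <- unique(df$cluster_id[duplicated(df$cluster_id)])
  if (length(dup))
    problems <- c(problems, sprintf("duplicate cluster id(s): %s",
                                    paste(dup, collapse = ", ")))
  missing <- setdiff(expected, df$cluster_id)
  if (length(missing))
    problems <- c(problems, sprintf("missing cluster id(s): %s",
                                    paste(missing, collapse = ", ")))
  extra <- setdiff(df$cluster_id, expected)
  if (length(extra))
    problems <- c(problems, sprintf("cluster id(s) not in the model: %s",
                                    paste(extra, collapse = ", ")))
  if (length(problems))
    stopf("invalid component map %s:\n  %s", path, paste(problems, collapse = "\n  "))
  entries <- stats::setNames(df$component, as.character(df$cluster_id))
  new_component_map(entries)
}

#' Build a ground-truth component map from synthetic source labels
#'
#' Test convenience for synthetic data only: assigns to each cluster the
#' component implied by the majority true source label among its rows
#' (bird -> "mainly bird", insect -> "mainly insect", rain -> "mainly
#' rain", anthro -> "biophony and anthropophony", silence -> "no obvious
#' biophony"). Real data is mapped by human listening, never by this
#' function.
#'
#' @param assignments 0-based cluster ids per row.
#' @param labels true source name per row.
#' @return A `component_map`.
#' @export
majority_component_map <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  to_comp <- c(bird = "mainly bird", insect = "mainly insect",
               rain = "mainly rain", anthro = "biophony and anthropophony",
               silence = "no obvious biophony")
  ids <- sort(unique(assignments))
  entries <- vapply(ids, function(k) {
    tab <- sort(table(labels[assignments == k]), decreasing = TRUE)
    unname(to_comp[names(tab)[1L]])
  }, character(1))
  new_component_map(stats::setNames(entries, as.character(ids)))
}

#' Attach component labels to a minute table
#'
#' Pure lookup of each row's cluster through a validated map; adds
#' `cluster` and `component` columns.
#'
#' @param table a `minute_features` data frame.
#' @param assignments 0-based cluster id per row (e.g.
#'   `model$assignments`).
#' @param map a validated `component_map`.
#' @return The table with `cluster` and `component` columns added.
#' @export
apply_map <- function(table, assignments, map) {
  stopifnot(inherits(map, "component_map"))
  if (nrow(table) != length(assignments))
    stop("assignments length does not match the table", call. = FALSE)
  table$cluster <- assignments
  table$component <- unname(map$entries[as.character(assignments)])
  table
}

#' Export the exemplar review pack for human component identification
#'
#' Writes a manifest CSV with one row per exemplar (cluster, source WAV,
#' minute offset, duration 59.52 s) for listeners, optionally cutting the
#' minute snippets to WAV and rendering spectrogram PNGs (Hann window,
#' FFT 512, 50% overlap — the parameters logged verbatim in the manifest
#' header). Exemplars whose source recording is missing are kept in the
#' manifest with status `"missing"` and a warning.
#'
#' @param ex exemplar data frame from [exemplars()].
#' @param audio_dir directory holding `SITE_YYYYMMDD_HHMMSS.wav` recordings.
#' @param out_dir output directory for the manifest (and snippets).
#' @param snippets also cut WAV snippets (default `FALSE`).
#' @param spectrograms also render spectrogram PNGs (default `FALSE`).
#' @param block_s snippet duration in seconds (default 59.52).
#' @return The manifest data frame, invisibly.
#' @export
export_review_pack <- function(ex, audio_dir, out_dir, snippets = FALSE,
                               spectrograms = FALSE, block_s = 59.52) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  src <- file.path(audio_dir, sprintf("%s_%s.wav", ex$site,
                                      format(ex$start, "%Y%m%d_%H%M%S", tz = "UTC")))
  man <- data.frame(cluster = ex$cluster, source_file = basename(src),
                    minute_index = ex$minute_index,
                    offset_s = ex$minute_index * block_s,
                    duration_s = block_s, distance = ex$distance,
                    status = ifelse(file.exists(src), "ok", "missing"))
  n_miss <- sum(man$status == "missing")
  if (n_miss) warnf("%d exemplar source file(s) missing; skipped", n_miss)
  if (snippets || spectrograms) {
    for (i in which(man$status == "ok")) {
      clip <- read_wav(src[i], warn_metadata = FALSE)
      i0 <- round(man$offset_s[i] * clip$sr)
      seg <- clip$samples[(i0 + 1L):min(i0 + round(block_s * clip$sr),
                                        length(clip$samples))]
      stem <- sprintf("cluster%02d_%s_min%d", man$cluster[i],
                      sub("\\.wav$", "", man$source_file[i]), man$minute_index[i])
      if (snippets) write_wav(seg, clip$sr, file.path(out_dir, paste0(stem, ".wav")))
      if (spectrograms) {
        grDevices::png(file.path(out_dir, paste0(stem, ".png")), 800, 400)
        sp <- signal::specgram(seg, n = 512, Fs = clip$sr, overlap = 256)
        graphics::image(sp$t, sp$f, t(20 * log10(abs(sp$S) + 1e-10)),
                        xlab = "time (s)", ylab = "frequency (Hz)",
                        col = grDevices::hcl.colors(64, "Inferno"))
        grDevices::dev.off()
      }
    }
  }
  path <- file.path(out_dir, "review_manifest.csv")
  header <- c("# exemplar review pack",
              "# spectrogram parameters: Hann window, FFT = 512, window overlap of 50%",
              sprintf("# snippet duration: %.2f s", block_s))
  writeLines(header, path)
  suppressWarnings(utils::write.table(man, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(man)
}
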