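#' Average embeddings over consecutive 1-min blocks
#'
#' Averages consecutive non-overlapping blocks of `block` embedding vectors
#' elementwise. With the default block of 62 patches of 0.96 s each block
#' spans 59.52 s, and a 5-min recording's 312 vectors yield 5 minute-vectors
#' with the trailing 2 discarded. A trailing remainder shorter than `block`
#' is always dropped.
#'
#' @param emb an `embedding_set` or a numeric matrix (vectors in rows).
#' @param block vectors per block (default 62).
#' @return Matrix `n_blocks x dim` of block means (zero rows, with a
#'   warning, when fewer than `block` vectors are supplied).
#' @export
minute_average <- function(emb, block = 62L) {
  stopifnot(block >= 1L)
  X <- if (inherits(emb, "embedding_set")) emb$values else as.matrix(emb)
  n_blocks <- nrow(X) %/% block
  if (n_blocks == 0L) {
    warnf("fewer than %d vectors (%d); no complete minute block", block, nrow(X))
    out <- matrix(numeric(0), 0L, ncol(X))
    colnames(out) <- colnames(X)
    return(out)
  }
  grp <- rep(seq_len(n_blocks), each = block)
  used <- X[seq_len(n_blocks * block), , drop = FALSE]
  out <- rowsum(used, grp, reorder = TRUE) / block
  dimnames(out) <- if (is.null(colnames(X))) NULL else list(NULL, colnames(X))
  out
}

#' Assemble the site/time-indexed minute-feature table
#'
#' Combines per-recording minute vectors into the single table the
#' clustering consumes. Calendar columns (`hour`, `date`, `month`) are
#' derived from each recording's start time plus `minute_index` x 59.52 s;
#' rows are sorted by (site, start, minute_index). Recordings lost in the
#' field are simply absent rows; nothing is imputed.
#'
#' @param recordings list of `embedding_set`-like elements, each a list with
#'   `site`, `start` (POSIXct) and `minutes` (matrix of minute vectors), or
#'   a list of `embedding_set` objects (then `block` is applied first).
#' @param block vectors per minute block when averaging `embedding_set`s.
#' @param patch_s patch duration in seconds (default 0.96).
#' @return A `minute_features` data frame: site, start, minute_index, hour,
#'   date, month, f000...f127.
#' @export
assemble_table <- function(recordings, block = 62L, patch_s = 0.96) {
  keys <- vapply(recordings, function(r)
    paste(r$site, format(r$start, "%Y%m%d%H%M%S", tz = "UTC")), character(1))
  if (anyDuplicated(keys))
    stopf("duplicate (site, start) recording keys: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  parts <- lapply(recordings, function(r) {
    M <- if (!is.null(r$minutes)) r$minutes else minute_average(r, block)
    if (nrow(M) == 0L) return(NULL)
    if (is.na(r$start[1L])) stopf("recording for site %s has no parseable start time", r$site)
    mi <- seq_len(nrow(M)) - 1L
    ts <- r$start + mi * (block * patch_s)
    df <- data.frame(site = r$site, start = r$start, minute_index = mi,
                     hour = as.integer(format(ts, "%H", tz = "UTC")),
                     date = as.Date(ts, tz = "UTC"),
                     month = as.integer(format(ts, "%m", tz = "UTC")))
    colnames(M) <- sprintf("f%03d", seq_len(ncol(M)) - 1L)
    cbind(df, as.data.frame(M))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) stop("no complete minute blocks in any recording", call. = FALSE)
  out <- out[order(out$site, out$start, out$minute_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("minute_features", "data.frame")
  out
}

#' Extract the feature matrix from a minute-feature table
#'
#' @param table a `minute_features` data frame.
#' @return Numeric matrix of the f-columns.
#' @export
feature_matrix <- function(table) {
  fcols <- grep("^f[0-9]{3}$", names(table), value = TRUE)
  as.matrix(table[, fcols, drop = FALSE])
}
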