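#' Deterministic surrogate embedding backend
#'
#' A self-contained stand-in for a pre-trained deep audio embedding. Each
#' 96 x 64 log-mel patch is flattened, standardized (its mean subtracted and
#' divided by its standard deviation; a constant patch maps to the zero
#' vector), and multiplied by a fixed seeded random 6144 -> 128 projection
#' with orthonormalized columns. By the Johnson-Lindenstrauss property the
#' projection approximately preserves pairwise patch geometry (up to the
#' known sqrt(128/6144) scale), so clustering structure in the log-mel
#' domain survives into the embedding space. The projection is a pure
#' function of the seed.
#'
#' @param seed integer seed fixing the projection.
#' @param in_dim flattened patch dimension (default 96 * 64).
#' @param out_dim embedding dimension (default 128).
#' @return An object of class `embedding_backend`.
#' @export
surrogate_backend <- function(seed = 1L, in_dim = 96L * 64L, out_dim = 128L) {
  P <- with_seed(seed, {
    M <- matrix(stats::rnorm(in_dim * out_dim), in_dim, out_dim)
    qr_d <- qr(M)
    Q <- qr.Q(qr_d)
    # fix signs (diag of R positive) so the projection is BLAS-independent
    s <- sign(diag(qr.R(qr_d)))
    s[s == 0] <- 1
    sweep(Q, 2L, s, "*")
  })
  structure(list(type = "surrogate", seed = as.integer(seed),
                 projection = P, out_dim = as.integer(out_dim)),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend> type=%s, out_dim=%d\n", x$type, x$out_dim))
  invisible(x)
}

#' Pre-trained VGG-style convolutional embedding backend
#'
#' Loads convolutional-network weights from a JSON manifest plus a raw
#' little-endian float32 binary and runs the VGG-style stack (3x3 `same`
#' convolutions with ReLU, 2x2 max pooling, dense layers, a final 128-unit
#' embedding layer) on each patch. The manifest lists layers in order, each
#' with `type` (`"conv"`, `"pool"` or `"dense"`), `shape`, and `offset`
#' (float32 elements into the binary); converting a published checkpoint to
#' this layout is a one-off preprocessing step outside this package. No part
#' of the pipeline requires this backend; the surrogate backend is the
#' self-contained default and is never silently substituted for it.
#'
#' @param weights_path path to the JSON manifest; the manifest's `bin` entry
#'   names the weight binary relative to the manifest.
#' @return An object of class `embedding_backend`.
#' @export
vggish_backend <- function(weights_path) {
  if (!file.exists(weights_path))
    stopf(paste("embedding weights file not found: %s",
                "(provide the converted checkpoint manifest, or use surrogate_backend())"),
          weights_path)
  man <- tryCatch(jsonlite::read_json(weights_path, simplifyVector = TRUE),
                  error = function(e) stopf("corrupt weights manifest %s: %s",
                                            weights_path, conditionMessage(e)))
  if (is.null(man$layers) || is.null(man$bin))
    stopf("weights manifest %s lacks required fields `layers`/`bin`", weights_path)
  bin_path <- file.path(dirname(weights_path), man$bin)
  if (!file.exists(bin_path))
    stopf("weight binary not found: %s (referenced by %s)", bin_path, weights_path)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  n_float <- file.size(bin_path) %/% 4L
  w <- readBin(con, "numeric", n = n_float, size = 4L, endian = "little")
  layers <- man$layers
  if (is.data.frame(layers)) layers <- split(layers, seq_len(nrow(layers)))
  layers <- lapply(layers, function(l) {
    l <- as.list(l)
    if (is.list(l$shape)) l$shape <- unlist(l$shape)
    if (!is.null(l$shape[[1]]) && is.list(l$shape)) l$shape <- unlist(l$shape)
    l
  })
  parsed <- lapply(layers, function(l) {
    if (l$type == "pool") return(list(type = "pool"))
    shape <- as.integer(unlist(l$shape))
    n_w <- prod(shape)
    n_b <- shape[length(shape)]
    if (l$offset + n_w + n_b > n_float + 1e-9)
      stopf("weights binary %s too short for layer %s", bin_path, l$name %||% l$type)
    W <- w[l$offset + seq_len(n_w)]
    b <- w[l$offset + n_w + seq_len(n_b)]
    list(type = l$type, shape = shape, W = W, b = b)
  })
  checksum <- unname(tools::md5sum(bin_path))
  structure(list(type = "vggish", layers = parsed, checksum = checksum,
                 out_dim = utils::tail(parsed, 1L)[[1L]]$shape[2L] %||% 128L,
                 weights_path = weights_path),
            class = "embedding_backend")
}

# 3x3 same conv + ReLU over a H x W x C_in array; W shaped (3,3,C_in,C_out).
conv3x3_relu <- function(x, Wv, shape, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- shape[4]
  Wk <- array(Wv, shape)
  out <- array(0, c(H, Wd, Cout))
  xp <- array(0, c(H + 2L, Wd + 2L, Cin))
  xp[2:(H + 1L), 2:(Wd + 1L), ] <- x
  # im2col: rows = H*W positions, cols = 9*Cin
  cols <- matrix(0, H * Wd, 9L * Cin)
  k <- 1L
  for (ci in seq_len(Cin)) for (dj in 0:2) for (di in 0:2) {
    cols[, k] <- as.vector(xp[(1:H) + di, (1:Wd) + dj, ci])
    k <- k + 1L
  }
  # kernel matrix (9*Cin) x Cout in matching order
  Km <- matrix(0, 9L * Cin, Cout)
  k <- 1L
  for (ci in seq_len(Cin)) for (dj in 1:3) for (di in 1:3) {
    Km[k, ] <- Wk[di, dj, ci, ]
    k <- k + 1L
  }
  res <- cols %*% Km
  res <- sweep(res, 2L, b, "+")
  array(pmax(res, 0), c(H, Wd, Cout))
}

maxpool2 <- function(x) {
  H <- dim(x)[1] %/% 2L; W <- dim(x)[2] %/% 2L; C <- dim(x)[3]
  out <- array(0, c(H, W, C))
  a <- x[seq_len(2L * H), seq_len(2L * W), , drop = FALSE]
  out <- pmax(a[seq(1, 2 * H, 2), seq(1, 2 * W, 2), , drop = FALSE],
              a[seq(2, 2 * H, 2), seq(1, 2 * W, 2), , drop = FALSE],
              a[seq(1, 2 * H, 2), seq(2, 2 * W, 2), , drop = FALSE],
              a[seq(2, 2 * H, 2), seq(2, 2 * W, 2), , drop = FALSE])
  out
}

vggish_forward <- function(patch, layers) {
  x <- array(patch, c(dim(patch), 1L))
  vec <- NULL
  for (l in layers) {
    if (l$type == "conv") {
      x <- conv3x3_relu(x, l$W, l$shape, l$b)
    } else if (l$type == "pool") {
      x <- maxpool2(x)
    } else if (l$type == "dense") {
      if (is.null(vec)) vec <- as.vector(x)
      Wm <- matrix(l$W, l$shape[1], l$shape[2])
      vec <- as.vector(pmax(crossprod(Wm, vec) + l$b, 0))
    } else stopf("unknown layer type '%s'", l$type)
  }
  if (is.null(vec)) vec <- as.vector(x)
  vec
}

#' Embed log-mel patches
#'
#' Maps each patch to a fixed-length feature vector through the given
#' backend, preserving patch order. Deterministic given the backend.
#'
#' @param patches a [logmel_patches()] object.
#' @param backend an `embedding_backend` from [surrogate_backend()] or
#'   [vggish_backend()].
#' @return Object of class `embedding_set`: list with `values` (matrix
#'   `n_patches x out_dim`), `patch_t0`, `backend` (type string), plus the
#'   clip's site/start metadata.
#' @export
embed <- function(patches, backend) {
  stopifnot(inherits(patches, "logmel_patches"))
  if (!inherits(backend, "embedding_backend"))
    stop("backend not initialized: construct it with surrogate_backend() or vggish_backend()",
         call. = FALSE)
  n <- n_patches(patches)
  if (n == 0L) {
    E <- matrix(numeric(0), 0L, backend$out_dim)
  } else if (backend$type == "surrogate") {
    d <- dim(patches$values)
    X <- matrix(aperm(patches$values, c(2L, 3L, 1L)), nrow = d[2] * d[3], ncol = d[1])
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    Xs <- sweep(X, 2L, mu, "-")
    nz <- sdv > 0
    Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2L, sdv[nz], "/")
    Xs[, !nz] <- 0
    E <- crossprod(Xs, backend$projection)
  } else {
    E <- t(vapply(seq_len(n),
                  function(i) vggish_forward(patches$values[i, , ], backend$layers),
                  numeric(backend$out_dim)))
  }
  colnames(E) <- sprintf("e%03d", seq_len(ncol(E)) - 1L)
  structure(list(values = E, patch_t0 = patches$t0, backend = backend$type,
                 site = patches$clip_site, start = patches$clip_start),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d vectors x %d dims (backend=%s)\n",
              nrow(x$values), ncol(x$values), x$backend))
  invisible(x)
}

#' Write an embedding set as a columnar CSV
#'
#' Columns: site, start_iso, patch_index, e000...e127, backend.
#'
#' @param emb an `embedding_set`.
#' @param path output CSV path.
#' @export
write_embeddings_csv <- function(emb, path) {
  df <- data.frame(site = emb$site %||% NA_character_,
                   start_iso = format(emb$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   patch_index = seq_len(nrow(emb$values)) - 1L)
  df <- cbind(df, as.data.frame(emb$values))
  df$backend <- emb$backend
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
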