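#' Fit a 2-D principal-component projection of the feature space
#'
#' Computes the top-2 principal components of the minute-feature table
#' (data centred; optionally standardized). The projection is learned from
#' the full table rather than from the K cluster centres, so that the plane
#' reflects the data's dominant variance. Loadings follow a deterministic
#' sign convention: in each component, the largest-magnitude coordinate is
#' positive.
#'
#' @param X numeric matrix or `minute_features` table.
#' @param standardize divide each feature by its standard deviation before
#'   the PCA (default `FALSE`: embedding dimensions share a scale).
#' @return Object of class `soundscape_projection` with `loadings` (2 x d,
#'   orthonormal rows), `center`, `explained_variance_ratio`.
#' @export
fit_pca <- function(X, standardize = FALSE) {
  if (inherits(X, "minute_features")) X <- feature_matrix(X)
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows to fit the projection", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) stop("zero-variance data: no principal directions", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  W <- t(pc$rotation[, 1:2, drop = FALSE])
  for (i in 1:2) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = W, center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 explained_variance_ratio = evr[1:2]),
            class = "soundscape_projection")
}

#' Project mixture centres and covariances into the PCA plane
#'
#' Maps each cluster mean through `W (mu - center)` and each covariance
#' through the congruence `W Sigma W'`, then derives the 2-standard-
#' deviation ellipse of every cluster from the eigendecomposition of its
#' projected covariance (axis lengths `2 sqrt(lambda)`).
#'
#' @param model a `soundscape_gmm`.
#' @param proj a `soundscape_projection` fitted on the same feature space.
#' @return The projection object with `centers_2d` (K x 2), `cov_2d`
#'   (K x 2 x 2), `ellipse_params` (K x 3: major, minor, angle in radians)
#'   and `weights` filled in.
#' @export
project_model <- function(model, proj) {
  stopifnot(inherits(model, "soundscape_gmm"),
            inherits(proj, "soundscape_projection"))
  W <- proj$loadings
  if (ncol(W) != model$dim)
    stopf("dimension mismatch: projection is for %d dims, model has %d",
          ncol(W), model$dim)
  M <- sweep(model$means, 2L, proj$center)
  if (!is.null(proj$scale)) M <- sweep(M, 2L, proj$scale, "/")
  centers_2d <- M %*% t(W)
  K <- model$K
  cov_2d <- array(0, c(K, 2L, 2L))
  ell <- matrix(0, K, 3L, dimnames = list(NULL, c("major", "minor", "angle")))
  for (k in seq_len(K)) {
    S <- if (model$cov_type == "diag") {
      v <- model$covariances[k, ]
      if (!is.null(proj$scale)) v <- v / proj$scale^2
      sweep(W, 2L, v, "*") %*% t(W)
    } else {
      Sk <- model$covariances[k, , ]
      if (!is.null(proj$scale)) Sk <- Sk / tcrossprod(proj$scale)
      W %*% Sk %*% t(W)
    }
    S <- (S + t(S)) / 2
    cov_2d[k, , ] <- S
    eg <- eigen(S, symmetric = TRUE)
    ell[k, ] <- c(2 * sqrt(max(eg$values[1], 0)), 2 * sqrt(max(eg$values[2], 0)),
                  atan2(eg$vectors[2, 1], eg$vectors[1, 1]))
  }
  proj$centers_2d <- centers_2d
  proj$cov_2d <- cov_2d
  proj$ellipse_params <- ell
  proj$weights <- model$weights
  proj
}

#' @export
print.soundscape_projection <- function(x, ...) {
  cat(sprintf("<soundscape_projection> 2 x %d loadings; explained variance %.1f%% + %.1f%%\n",
              ncol(x$loadings), 100 * x$explained_variance_ratio[1],
              100 * x$explained_variance_ratio[2]))
  if (!is.null(x$centers_2d))
    cat(sprintf("  %d projected cluster centres with 2-SD ellipses\n", nrow(x$centers_2d)))
  invisible(x)
}

#' Scatter plot of projected cluster centres with 2-SD ellipses
#'
#' Marker area is proportional to mixture weight; shaded ellipses mark two
#' standard deviations of each projected cluster covariance.
#'
#' @param x a `soundscape_projection` with centres filled in by
#'   [project_model()].
#' @param components optional per-cluster component labels used to colour
#'   the clusters.
#' @param ... passed to [graphics::plot()].
#' @export
plot.soundscape_projection <- function(x, components = NULL, ...) {
  if (is.null(x$centers_2d))
    stop("no projected centres: call project_model() first", call. = FALSE)
  K <- nrow(x$centers_2d)
  cols <- if (is.null(components)) rep("steelblue", K)
          else grDevices::hcl.colors(length(unique(components)), "Dark 3")[
            as.integer(factor(components))]
  th <- seq(0, 2 * pi, length.out = 100L)
  lim <- range(x$centers_2d) + c(-1, 1) * max(x$ellipse_params[, "major"])
  graphics::plot(NA, xlim = lim, ylim = lim, xlab = "PCA1", ylab = "PCA2", ...)
  for (k in seq_len(K)) {
    a <- x$ellipse_params[k, "major"]; b <- x$ellipse_params[k, "minor"]
    ang <- x$ellipse_params[k, "angle"]
    ex <- a * cos(th) * cos(ang) - b * sin(th) * sin(ang) + x$centers_2d[k, 1]
    ey <- a * cos(th) * sin(ang) + b * sin(th) * cos(ang) + x$centers_2d[k, 2]
    graphics::polygon(ex, ey, col = grDevices::adjustcolor(cols[k], 0.15), border = NA)
  }
  graphics::points(x$centers_2d, pch = 19, col = cols,
                   cex = 0.5 + 3 * x$weights / max(x$weights))
  invisible(x)
}

#' Write projected centres and ellipses as CSV
#' @param proj a filled `soundscape_projection`.
#' @param path output CSV path.
#' @export
write_projection_csv <- function(proj, path) {
  if (is.null(proj$centers_2d)) stop("call project_model() first", call. = FALSE)
  df <- data.frame(cluster = seq_len(nrow(proj$centers_2d)) - 1L,
                   pca1 = proj$centers_2d[, 1], pca2 = proj$centers_2d[, 2],
                   weight = proj$weights,
                   ellipse_major = proj$ellipse_params[, "major"],
                   ellipse_minor = proj$ellipse_params[, "minor"],
                   ellipse_angle = proj$ellipse_params[, "angle"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
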