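# Gaussian mixture clustering with BIC model selection.
#
# The EM fitter is written here (rather than wrapping an existing mixture
# package) because the cluster-count selection by BIC over a wide grid, with
# a ridge-regularized choice of full or diagonal covariances in 128
# dimensions, is the methodological core of the pipeline; tests cross-check
# it against independent likelihood oracles and against mclust on small
# instances.

# Per-component log density matrix (n x K).
gmm_logdens <- function(X, means, covs, cov_type) {
  n <- nrow(X); d <- ncol(X); K <- nrow(means)
  out <- matrix(0, n, K)
  if (cov_type == "diag") {
    X2 <- X^2
    for (k in seq_len(K)) {
      v <- covs[k, ]
      mu <- means[k, ]
      quad <- X2 %*% (1 / v) - 2 * (X %*% (mu / v)) + sum(mu^2 / v)
      out[, k] <- -0.5 * (d * log(2 * pi) + sum(log(v)) + quad)
    }
  } else {
    for (k in seq_len(K)) {
      C <- chol(covs[k, , ])
      logdet <- 2 * sum(log(diag(C)))
      Y <- backsolve(C, t(X) - means[k, ], transpose = TRUE)
      out[, k] <- -0.5 * (d * log(2 * pi) + logdet + colSums(Y^2))
    }
  }
  out
}

gmm_free_params <- function(K, d, cov_type) {
  cov_p <- if (cov_type == "diag") K * d else K * d * (d + 1) / 2
  (K - 1) + K * d + cov_p
}

regularize_cov <- function(S, ridge) {
  diag(S) <- diag(S) + ridge
  S
}

gmm_mstep_cov <- function(X, resp, means, Nk, cov_type, ridge) {
  K <- length(Nk); d <- ncol(X)
  if (cov_type == "diag") {
    covs <- matrix(0, K, d)
    X2 <- X^2
    for (k in seq_len(K)) {
      ex2 <- crossprod(resp[, k], X2) / Nk[k]
      covs[k, ] <- pmax(as.vector(ex2) - means[k, ]^2, 0) + ridge
    }
  } else {
    covs <- array(0, c(K, d, d))
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, means[k, ])
      S <- crossprod(Xc * resp[, k], Xc) / Nk[k]
      covs[k, , ] <- regularize_cov((S + t(S)) / 2, ridge)
    }
  }
  covs
}

# One EM run from a k-means initialization.
gmm_em_once <- function(X, K, cov_type, seed, tol, max_iter, ridge) {
  n <- nrow(X); d <- ncol(X)
  assign0 <- with_seed(seed, {
    if (K == 1L) rep(1L, n)
    else {
      km <- tryCatch(stats::kmeans(X, centers = K, nstart = 1L, iter.max = 30L),
                     error = function(e) NULL)
      if (is.null(km)) sample(rep_len(seq_len(K), n)) else km$cluster
    }
  })
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), assign0)] <- 1
  ll_prev <- -Inf; ll <- -Inf; converged <- FALSE
  means <- NULL; covs <- NULL; weights <- NULL
  for (it in seq_len(max_iter)) {
    Nk <- pmax(colSums(resp), 1e-10)
    weights <- Nk / n
    means <- crossprod(resp, X) / Nk
    covs <- tryCatch(gmm_mstep_cov(X, resp, means, Nk, cov_type, ridge),
                     error = function(e) NULL)
    ld <- if (is.null(covs)) NULL else
      tryCatch(gmm_logdens(X, means, covs, cov_type), error = function(e) NULL)
    if (is.null(ld)) {
      # escalate the ridge before giving up
      ridge <- ridge * 100
      covs <- tryCatch(gmm_mstep_cov(X, resp, means, Nk, cov_type, ridge),
                       error = function(e) NULL)
      ld <- if (is.null(covs)) NULL else
        tryCatch(gmm_logdens(X, means, covs, cov_type), error = function(e) NULL)
      if (is.null(ld))
        stop(paste("singular component covariance despite regularization;",
                   "use cov_type = 'diag' or increase cov_reg"), call. = FALSE)
    }
    lw <- sweep(ld, 2L, log(weights), "+")
    lse <- logsumexp_rows(lw)
    ll <- sum(lse)
    resp <- exp(lw - lse)
    if (is.finite(ll_prev) && abs(ll - ll_prev) / n < tol) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(weights = as.vector(weights), means = means, covs = covs,
       loglik = ll, resp = resp, converged = converged, ridge = ridge)
}

gmm_em <- function(X, K, cov_type, seed, n_init, tol, max_iter, ridge) {
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- gmm_em_once(X, K, cov_type, derive_seed(seed, (K * 131L + i)),
                       tol, max_iter, ridge)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' BIC of a fitted mixture
#'
#' `BIC = -2 loglik + p ln(n)` with `p` the free-parameter count of the
#' chosen covariance structure; lower is better.
#' @param loglik fitted log-likelihood.
#' @param K,d,n cluster count, dimension, sample size.
#' @param cov_type `"full"` or `"diag"`.
#' @export
gmm_bic <- function(loglik, K, d, n, cov_type = c("full", "diag")) {
  cov_type <- match.arg(cov_type)
  -2 * loglik + gmm_free_params(K, d, cov_type) * log(n)
}

#' Sweep Gaussian-mixture fits over a grid of cluster counts
#'
#' Fits a GMM by EM at every K in `grid` (with `n_init` seeded k-means
#' restarts each, keeping the best log-likelihood) and records the BIC.
#' The default grid is 5 to 200 in steps of 5, the sweep used to size the
#' soundscape cluster inventory.
#'
#' @param X numeric matrix (rows = minute vectors) or a `minute_features`
#'   table.
#' @param grid strictly increasing integer vector of cluster counts.
#' @param cov_type `"full"` (default; per-component full covariance with a
#'   diagonal ridge) or `"diag"`.
#' @param seed integer seed controlling all restarts.
#' @param n_init number of EM restarts per K (default 3).
#' @param tol EM convergence tolerance on the mean per-sample log-likelihood
#'   change (default 1e-4).
#' @param max_iter maximum EM iterations (default 500).
#' @param cov_reg diagonal ridge added to every covariance (default 1e-4).
#' @return A `bic_curve` data frame with columns K, bic, loglik, converged.
#' @export
bic_sweep <- function(X, grid = seq(5L, 200L, by = 5L),
                      cov_type = c("full", "diag"), seed = 1L, n_init = 3L,
                      tol = 1e-4, max_iter = 500L, cov_reg = 1e-4) {
  cov_type <- match.arg(cov_type)
  if (inherits(X, "minute_features")) X <- feature_matrix(X)
  X <- as.matrix(X)
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (nrow(X) <= max(grid))
    stopf("need more rows (%d) than the largest K in the grid (%d)", nrow(X), max(grid))
  res <- lapply(grid, function(K) {
    fit <- gmm_em(X, K, cov_type, seed, n_init, tol, max_iter, cov_reg)
    if (!fit$converged)
      warnf("EM did not converge for K = %d within %d iterations", K, max_iter)
    data.frame(K = K, bic = gmm_bic(fit$loglik, K, ncol(X), nrow(X), cov_type),
               loglik = fit$loglik, converged = fit$converged)
  })
  out <- do.call(rbind, res)
  attr(out, "cov_type") <- cov_type
  attr(out, "n") <- nrow(X)
  attr(out, "d") <- ncol(X)
  class(out) <- c("bic_curve", "data.frame")
  out
}

#' @export
print.bic_curve <- function(x, ...) {
  cat(sprintf("<bic_curve> %d cluster counts (K = %d..%d), cov_type=%s\n",
              nrow(x), min(x$K), max(x$K), attr(x, "cov_type")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.bic_curve <- function(x, ...) {
  graphics::plot(x$K, x$bic, type = "b", xlab = "number of clusters K",
                 ylab = "BIC", pch = ifelse(x$converged, 19, 1), ...)
  ksel <- select_k(x)
  graphics::abline(v = ksel, lty = 2)
  invisible(x)
}

#' Select the cluster count from a BIC curve
#'
#' `global_min` takes the converged K with the smallest BIC; ties break
#' toward smaller K. `first_local_min` takes the smallest K whose BIC lies
#' below both neighbours, falling back to the global minimum (with a
#' warning) when the curve is monotone.
#'
#' @param curve a `bic_curve`.
#' @param strategy `"global_min"` (default) or `"first_local_min"`.
#' @return The selected K (integer).
#' @export
select_k <- function(curve, strategy = c("global_min", "first_local_min")) {
  strategy <- match.arg(strategy)
  conv <- curve[curve$converged, , drop = FALSE]
  if (nrow(conv) == 0L) stop("no converged fit in the BIC curve", call. = FALSE)
  global <- conv$K[which.min(conv$bic)]  # which.min takes the first = smallest K
  if (strategy == "global_min") return(global)
  b <- conv$bic
  if (nrow(conv) >= 3L) {
    for (i in 2:(nrow(conv) - 1L))
      if (b[i] < b[i - 1L] && b[i] < b[i + 1L]) return(conv$K[i])
  }
  warnf("no interior local minimum in the BIC curve; falling back to the global minimum")
  global
}

#' Fit the final Gaussian mixture at a chosen K
#'
#' Runs EM at the selected cluster count and returns the full model:
#' mixture weights, means, covariances, per-row posteriors and hard
#' assignments (cluster ids are 0-based, `0..K-1`, following the cluster
#' numbering convention of the component taxonomy workflow).
#'
#' @inheritParams bic_sweep
#' @param K number of mixture components.
#' @return An object of class `soundscape_gmm`.
#' @export
fit_final <- function(X, K, cov_type = c("full", "diag"), seed = 1L,
                      n_init = 3L, tol = 1e-4, max_iter = 500L, cov_reg = 1e-4) {
  cov_type <- match.arg(cov_type)
  tab <- if (inherits(X, "minute_features")) X else NULL
  if (!is.null(tab)) X <- feature_matrix(X)
  X <- as.matrix(X)
  if (nrow(X) <= K) stopf("need more rows (%d) than clusters (%d)", nrow(X), K)
  fit <- gmm_em(X, K, cov_type, seed, n_init, tol, max_iter, cov_reg)
  if (!fit$converged)
    warnf("EM did not converge for K = %d within %d iterations", K, max_iter)
  post <- fit$resp
  assignments <- max.col(post, ties.method = "first") - 1L
  structure(list(K = as.integer(K), weights = fit$weights, means = fit$means,
                 covariances = fit$covs, cov_type = cov_type,
                 assignments = assignments, posteriors = post,
                 loglik = fit$loglik,
                 bic = gmm_bic(fit$loglik, K, ncol(X), nrow(X), cov_type),
                 n_obs = nrow(X), dim = ncol(X), seed = as.integer(seed),
                 n_init = as.integer(n_init), tol = tol,
                 cov_reg = fit$ridge, converged = fit$converged),
            class = "soundscape_gmm")
}

#' @export
print.soundscape_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture soundscape model: K = %d clusters (%s covariance)\n",
              x$K, x$cov_type))
  cat(sprintf("  fitted on %d minute-vectors in %d dims; loglik = %.2f, BIC = %.2f\n",
              x$n_obs, x$dim, x$loglik, x$bic))
  invisible(x)
}

#' @export
summary.soundscape_gmm <- function(object, ...) {
  sizes <- tabulate(object$assignments + 1L, nbins = object$K)
  out <- data.frame(cluster = seq_len(object$K) - 1L, weight = object$weights,
                    n = sizes)
  cat(sprintf("Gaussian mixture soundscape model (K = %d, %s covariance, seed %d)\n\n",
              object$K, object$cov_type, object$seed))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
logLik.soundscape_gmm <- function(object, ...) {
  structure(object$loglik,
            df = gmm_free_params(object$K, object$dim, object$cov_type),
            nobs = object$n_obs, class = "logLik")
}

#' Posterior cluster membership for new minute vectors
#'
#' @param object a `soundscape_gmm`.
#' @param newdata matrix or `minute_features` table; omitted = training data
#'   posteriors.
#' @param ... unused.
#' @return List with `assignment` (0-based) and `posterior` (n x K matrix).
#' @export
predict.soundscape_gmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(list(assignment = object$assignments, posterior = object$posteriors))
  X <- if (inherits(newdata, "minute_features")) feature_matrix(newdata)
       else as.matrix(newdata)
  if (ncol(X) != object$dim)
    stopf("newdata has %d columns; model expects %d", ncol(X), object$dim)
  ld <- gmm_logdens(X, object$means, object$covariances, object$cov_type)
  lw <- sweep(ld, 2L, log(object$weights), "+")
  post <- exp(lw - logsumexp_rows(lw))
  list(assignment = max.col(post, ties.method = "first") - 1L, posterior = post)
}

#' @export
plot.soundscape_gmm <- function(x, ...) {
  sizes <- tabulate(x$assignments + 1L, nbins = x$K)
  graphics::barplot(sizes, names.arg = seq_len(x$K) - 1L,
                    xlab = "cluster", ylab = "minute-vectors", ...)
  invisible(x)
}

#' Exemplar minutes closest to each cluster centre
#'
#' For each cluster, the `n` assigned rows with smallest Euclidean distance
#' to the cluster mean, sorted ascending by distance — the review material a
#' listener uses to name the cluster's soundscape component. Clusters with
#' fewer than `n` members return all members with a warning.
#'
#' @param model a `soundscape_gmm` fitted on `table`.
#' @param table the `minute_features` table the model was fitted on.
#' @param n exemplars per cluster (default 10).
#' @return Data frame: cluster, site, start, minute_index, distance.
#' @export
exemplars <- function(model, table, n = 10L) {
  stopifnot(inherits(model, "soundscape_gmm"))
  X <- feature_matrix(table)
  if (nrow(X) != model$n_obs)
    stop("table does not match the data the model was fitted on", call. = FALSE)
  out <- lapply(seq_len(model$K) - 1L, function(k) {
    idx <- which(model$assignments == k)
    if (length(idx) == 0L) return(NULL)
    dists <- sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2L, model$means[k + 1L, ])^2))
    if (length(idx) < n)
      warnf("cluster %d has only %d member(s); returning all of them", k, length(idx))
    ord <- order(dists)[seq_len(min(n, length(idx)))]
    data.frame(cluster = k, site = table$site[idx[ord]],
               start = table$start[idx[ord]],
               minute_index = table$minute_index[idx[ord]],
               distance = dists[ord])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
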