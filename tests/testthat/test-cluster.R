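suppressMessages(library(mclust))

# Independent likelihood oracle: evaluates the mixture log-likelihood of a
# fitted model by direct density computation (solve/mahalanobis for full
# covariances, dnorm products for diagonal), then the BIC formula.
oracle_loglik <- function(X, model) {
  n <- nrow(X); K <- model$K
  dens <- matrix(0, n, K)
  for (k in seq_len(K)) {
    mu <- model$means[k, ]
    if (model$cov_type == "diag") {
      v <- model$covariances[k, ]
      dens[, k] <- exp(rowSums(sapply(seq_along(mu), function(j)
        dnorm(X[, j], mu[j], sqrt(v[j]), log = TRUE))))
    } else {
      S <- model$covariances[k, , ]
      d <- ncol(X)
      md <- stats::mahalanobis(X, mu, S)
      dens[, k] <- exp(-0.5 * (d * log(2 * pi) + determinant(S)$modulus[1] + md))
    }
  }
  sum(log(dens %*% model$weights))
}

oracle_bic <- function(X, model) {
  d <- ncol(X); K <- model$K
  p <- if (model$cov_type == "diag") (K - 1) + K * d + K * d
       else (K - 1) + K * d + K * d * (d + 1) / 2
  -2 * oracle_loglik(X, model) + p * log(nrow(X))
}

test_that("single-Gaussian BIC matches the closed form", {
  set.seed(1)
  X <- matrix(rnorm(200 * 3), 200, 3)
  m <- fit_final(X, K = 1, cov_type = "full", seed = 1, cov_reg = 1e-12)
  n <- nrow(X); d <- ncol(X)
  S <- cov(X) * (n - 1) / n
  ll <- -n / 2 * (d * log(2 * pi) + determinant(S)$modulus[1] + d)
  p <- d + d * (d + 1) / 2
  expect_equal(m$bic, as.numeric(-2 * ll + p * log(n)), tolerance = 1e-6)
})

test_that("reported BIC equals the independent oracle on small instances", {
  set.seed(2)
  for (cov_type in c("full", "diag")) {
    for (K in c(1, 2, 3)) {
      X <- rbind(matrix(rnorm(60 * 2), 60, 2),
                 matrix(rnorm(60 * 2, mean = 4), 60, 2))
      m <- fit_final(X, K = K, cov_type = cov_type, seed = 3)
      expect_equal(m$bic, oracle_bic(X, m), tolerance = 1e-6,
                   label = sprintf("BIC (K=%d, %s)", K, cov_type))
    }
  }
})

test_that("the BIC sweep recovers the true cluster count on easy mixtures", {
  ds <- synth_embedding_dataset(k_true = 3, n_per_cluster = 100, dim = 16,
                                separation = 6, seed = 17)
  curve <- bic_sweep(ds$table, grid = 2:5, cov_type = "diag", seed = 1, n_init = 2)
  expect_equal(nrow(curve), 4L)
  expect_true(all(curve$converged))
  expect_equal(select_k(curve), 3L)
  # coincident clusters: BIC must not prefer 3 over 1
  d0 <- synth_embedding_dataset(3, 100, dim = 8, separation = 0, seed = 17)
  c0 <- bic_sweep(d0$table, grid = c(1L, 3L), cov_type = "diag", seed = 1, n_init = 2)
  expect_equal(select_k(c0), 1L)
})

test_that("select_k handles turning points, monotone curves and ties", {
  mk <- function(bic, conv = TRUE) {
    df <- data.frame(K = seq(5, by = 5, length.out = length(bic)), bic = bic,
                     loglik = 0, converged = conv)
    class(df) <- c("bic_curve", "data.frame")
    df
  }
  v <- mk(c(50, 30, 20, 25, 40))
  expect_equal(select_k(v, "global_min"), 15)
  expect_equal(select_k(v, "first_local_min"), 15)
  mono <- mk(c(50, 40, 30, 20))
  expect_equal(select_k(mono, "global_min"), 20)
  expect_warning(kf <- select_k(mono, "first_local_min"), "falling back")
  expect_equal(kf, 20)
  tie <- mk(c(30, 20, 20, 40))
  expect_equal(select_k(tie), 10)  # smaller K wins the tie
  # non-converged points are excluded; none converged is an error
  part <- mk(c(10, 20, 30), conv = c(FALSE, TRUE, TRUE))
  expect_equal(select_k(part), 10)  # K = 5 is excluded as non-converged
  expect_error(select_k(mk(c(1, 2), conv = FALSE)), "no converged")
})

test_that("the final fit satisfies the mixture-model contracts", {
  ds <- synth_embedding_dataset(3, 80, dim = 8, separation = 6, seed = 23)
  m <- fit_final(ds$table, K = 3, cov_type = "full", seed = 5)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  expect_true(all(m$weights >= 0))
  expect_equal(rowSums(m$posteriors), rep(1, m$n_obs), tolerance = 1e-9)
  expect_equal(m$assignments, max.col(m$posteriors) - 1L)
  # covariances symmetric positive definite after regularization
  for (k in 1:3) {
    S <- m$covariances[k, , ]
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  # refitting with the same seed reproduces identical assignments
  m2 <- fit_final(ds$table, K = 3, cov_type = "full", seed = 5)
  expect_identical(m$assignments, m2$assignments)
  # label recovery on a well-separated mixture
  expect_gte(mclust::adjustedRandIndex(m$assignments, ds$labels), 0.95)
})

test_that("recovered means match the truth on separated spherical mixtures", {
  k <- 3; dim <- 8
  ds <- synth_embedding_dataset(k, 2000, dim = dim, separation = 8, seed = 29)
  m <- fit_final(ds$table, K = k, cov_type = "diag", seed = 7)
  X <- feature_matrix(ds$table)
  true_means <- t(sapply(0:(k - 1), function(l) colMeans(X[ds$labels == l, ])))
  # align labels by nearest true mean, then compare per coordinate
  perm <- apply(m$means, 1, function(mu)
    which.min(colSums((t(true_means) - mu)^2)))
  expect_equal(sort(perm), 1:k)  # a bijection: every cluster found
  # truth here = empirical class means; fitted means within 0.1 per coordinate
  expect_lt(max(abs(m$means - true_means[perm, ])), 0.1)
})

test_that("agreement with an independent mixture implementation", {
  set.seed(31)
  X <- rbind(matrix(rnorm(150 * 2), 150, 2),
             matrix(rnorm(150 * 2, mean = 5), 150, 2),
             sweep(matrix(rnorm(150 * 2), 150, 2), 2, c(0, 9), "+"))
  m <- fit_final(X, K = 3, cov_type = "full", seed = 2, cov_reg = 1e-8)
  mc <- mclust::Mclust(X, G = 3, modelNames = "VVV", verbose = FALSE)
  expect_gte(mclust::adjustedRandIndex(m$assignments, mc$classification), 0.95)
  expect_equal(m$loglik, mc$loglik, tolerance = 1e-3 * abs(mc$loglik))
})

test_that("exemplars are the closest members of their clusters", {
  ds <- synth_embedding_dataset(3, 40, dim = 6, separation = 6, seed = 37)
  m <- fit_final(ds$table, K = 3, cov_type = "diag", seed = 1)
  ex <- exemplars(m, ds$table)  # default n = 10
  expect_true(all(table(ex$cluster) == 10))
  for (k in 0:2) {
    dk <- ex$distance[ex$cluster == k]
    expect_true(!is.unsorted(dk))
    # oracle: the true minimum distance within the cluster
    X <- feature_matrix(ds$table)
    idx <- which(m$assignments == k)
    dists <- sqrt(rowSums(sweep(X[idx, ], 2, m$means[k + 1, ])^2))
    expect_equal(min(dists), dk[1])
  }
  # a small cluster returns all members with a warning
  m_small <- m
  m_small$assignments[m$assignments == 0][-1] <- 1L
  expect_warning(ex2 <- exemplars(m_small, ds$table), "only 1 member")
  expect_equal(sum(ex2$cluster == 0), 1L)
})
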