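# Diagonal-covariance Gaussian mixture fit by EM with seeded k-means
# restarts.  Features frequently outnumber entities in residue-wise distance
# clustering, so full covariances are not identifiable; a diagonal model with
# a variance floor is used throughout.

gmm_loglik <- function(X, pi_k, mu, var) {
  n <- nrow(X); K <- length(pi_k)
  logd <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lv <- log(2 * pi * var[k, ])
    z <- sweep(X, 2, mu[k, ])
    logd[, k] <- log(pi_k[k]) -
      0.5 * (sum(lv) + rowSums(sweep(z^2, 2, var[k, ], `/`)))
  }
  m <- apply(logd, 1, max)
  ll <- m + log(rowSums(exp(logd - m)))
  list(loglik = sum(ll), resp = exp(logd - m - log(rowSums(exp(logd - m)))))
}

gmm_em_once <- function(X, K, init_labels, max_iter = 100, tol = 1e-8,
                        var_floor = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), init_labels)] <- 1
  ll_old <- -Inf
  pi_k <- NULL; mu <- NULL; var <- NULL
  for (it in seq_len(max_iter)) {
    nk <- colSums(resp) + 1e-10
    pi_k <- nk / sum(nk)
    mu <- crossprod(resp, X) / nk
    var <- matrix(var_floor, K, d)
    for (k in seq_len(K)) {
      z <- sweep(X, 2, mu[k, ])
      var[k, ] <- pmax(colSums(resp[, k] * z^2) / nk[k], var_floor)
    }
    e <- gmm_loglik(X, pi_k, mu, var)
    resp <- e$resp
    if (is.finite(ll_old) && abs(e$loglik - ll_old) <
        tol * (abs(ll_old) + 1)) {
      ll_old <- e$loglik
      break
    }
    ll_old <- e$loglik
  }
  list(loglik = ll_old, resp = resp, pi = pi_k, mu = mu, var = var)
}

#' Cluster entities on a feature matrix with a Gaussian mixture model
#'
#' Fits a `K`-component diagonal-covariance Gaussian mixture by EM with
#' several seeded k-means initializations and keeps the best-likelihood fit;
#' labels are the maximum-responsibility component assignments.  The result
#' is deterministic for a fixed `seed` and `restarts`.
#'
#' @param features numeric matrix, one row per entity (e.g. from
#'   [residue_features()]).  A matrix with zero columns (all features
#'   filtered out) yields a degenerate single-label clustering flagged by
#'   `attr(, "uninformative")`.
#' @param k number of mixture components (states), `K >= 1`.
#' @param seed integer RNG seed.
#' @param restarts number of k-means-initialized EM restarts (default 10).
#' @return integer vector of labels in `1..K`, with attribute
#'   `uninformative` (TRUE when the clustering is degenerate).
#' @export
cluster_entities <- function(features, k, seed = 0L, restarts = 10L) {
  features <- as.matrix(features)
  n <- nrow(features)
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  if (n < k) stopf("fewer entities (%d) than clusters (%d)", n, k)
  if (ncol(features) == 0L || k == 1L) {
    return(structure(rep(1L, n), uninformative = TRUE))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(derive_seed(seed, r), {
      km <- tryCatch(kmeans(features, centers = k, nstart = 1L,
                            iter.max = 20L)$cluster,
                     error = function(e) NULL)
      if (is.null(km)) sample(rep_len(seq_len(k), n)) else km
    })
    fit <- gmm_em_once(features, k, init)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  labels <- max.col(best$resp, ties.method = "first")
  structure(as.integer(labels),
            uninformative = length(unique(labels)) < 2L)
}
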