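#' Fuzzy c-means configuration
#'
#' @param n_clusters number of preliminary clusters (the pipeline uses 10).
#' @param fuzzifier_m fuzziness exponent m > 1 (default 2).
#' @param tol convergence threshold on the maximum membership change.
#' @param max_iter iteration cap.
#' @param seed integer seed for the k-means++-style centroid initialization.
#' @return list of class `fcm_config`.
#' @export
fcm_config <- function(n_clusters = 10, fuzzifier_m = 2, tol = 1e-5,
                       max_iter = 300, seed = 1L) {
  stopifnot(n_clusters >= 1, fuzzifier_m > 1, tol > 0, max_iter >= 1)
  structure(list(n_clusters = as.integer(n_clusters), fuzzifier_m = fuzzifier_m,
                 tol = tol, max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fcm_config")
}

# k-means++ style seeding: first centroid uniform, the rest proportional to
# squared distance to the nearest chosen centroid.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = probs)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
    }
  }
  centers
}

#' Fuzzy c-means clustering of voxel intensity vectors
#'
#' Standard FCM: memberships `u_ik` proportional to
#' `1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centroids the `u^m`-weighted means,
#' iterated until the maximum membership change falls below `tol`. A point
#' coinciding with a centroid receives membership 1 for that centroid
#' (the usual singularity rule). Clusters that end up with no hard-assigned
#' point are dropped and labels compacted; if the data carry fewer distinct
#' rows than requested clusters the cluster count is reduced with a warning.
#'
#' @param X numeric matrix (n points x p features), e.g. in-mask voxels by the
#'   four z-scored sequence intensities.
#' @param config an [fcm_config()].
#' @return list of class `fcm_fit`: `membership` (n x c, rows sum to 1),
#'   `centers`, `labels` (hard arg-max labels), `objective` (per-iteration
#'   value of `sum(u^m d^2)`), `iterations`.
#' @export
fcm_cluster <- function(X, config = fcm_config()) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)))
  n <- nrow(X)
  c0 <- config$n_clusters
  n_distinct <- nrow(unique(X))
  k <- min(c0, n_distinct)
  if (k < c0) warning("fewer distinct points than clusters; using ", k, " clusters")
  if (n < k) stop("need at least as many points as clusters")
  m <- config$fuzzifier_m
  with_seed(derive_seed(config$seed, "fcm"), {
    centers <- kmeanspp_init(unique(X), k)
    U <- matrix(1 / k, n, k)
    obj <- numeric(0)
    xx <- rowSums(X^2)
    for (it in seq_len(config$max_iter)) {
      d2 <- outer(xx, rep(1, k)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      d2[d2 < 0] <- 0
      Unew <- matrix(0, n, k)
      zero <- d2 <= .Machine$double.eps
      has_zero <- rowSums(zero) > 0
      if (any(has_zero)) {
        Unew[has_zero, ] <- zero[has_zero, , drop = FALSE] /
          rowSums(zero[has_zero, , drop = FALSE])
      }
      if (any(!has_zero)) {
        w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
        Unew[!has_zero, ] <- w / rowSums(w)
      }
      obj <- c(obj, sum(Unew^m * d2))
      delta <- max(abs(Unew - U))
      U <- Unew
      um <- U^m
      centers <- (t(um) %*% X) / colSums(um)
      if (delta < config$tol && it > 1) break
    }
    labels <- max.col(U, ties.method = "first")
    keep <- sort(unique(labels))
    if (length(keep) < k) {
      U <- U[, keep, drop = FALSE]
      U <- U / rowSums(U)
      centers <- centers[keep, , drop = FALSE]
      labels <- match(labels, keep)
    }
    structure(list(membership = U, centers = centers, labels = labels,
                   objective = obj, iterations = length(obj)),
              class = "fcm_fit")
  })
}
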