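# Variational Bayesian Gaussian mixture (full covariance, Dirichlet weight
# prior). Written from the standard variational update equations; used to
# merge the preliminary FCM clusters into the final subregions. The Dirichlet
# concentration prior alpha0 = 1/K shrinks unused components to (near) zero
# weight, so the effective number of components is selected automatically.

log_wishart_B <- function(W, nu) {
  d <- ncol(W)
  -0.5 * nu * determinant(W, logarithm = TRUE)$modulus[1] -
    0.5 * nu * d * log(2) - 0.25 * d * (d - 1) * log(pi) -
    sum(lgamma(0.5 * (nu + 1 - seq_len(d))))
}

vbgmm_fit_once <- function(X, K, r, alpha0, max_iter = 200, tol = 1e-7,
                           prior_scale = 8) {
  n <- nrow(X); d <- ncol(X)
  beta0 <- 1
  m0 <- colMeans(X)
  nu0 <- d + 2
  Psi0 <- if (n > d + 1) {
    (stats::cov(X) + diag(1e-6, d)) / prior_scale
  } else {
    diag(pmax(apply(X, 2, stats::var), 1e-6), d) / prior_scale
  }
  W0 <- solve(Psi0) / nu0
  W0inv <- Psi0 * nu0

  elbo_prev <- -Inf
  elbo <- -Inf
  for (iter in seq_len(max_iter)) {
    Nk <- colSums(r) + 1e-10
    xbar <- t(r) %*% X / Nk
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    nu <- nu0 + Nk
    m <- matrix(0, K, d)
    W <- vector("list", K)
    Sk <- vector("list", K)
    for (k in seq_len(K)) {
      m[k, ] <- (beta0 * m0 + Nk[k] * xbar[k, ]) / beta[k]
      xc <- sweep(X, 2, xbar[k, ], "-")
      Sk[[k]] <- crossprod(xc * r[, k], xc) / Nk[k]
      dm <- xbar[k, ] - m0
      Winv <- W0inv + Nk[k] * Sk[[k]] +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dm)
      W[[k]] <- solve(Winv + diag(1e-10, d))
    }

    Elogpi <- digamma(alpha) - digamma(sum(alpha))
    Elogdet <- vapply(seq_len(K), function(k) {
      sum(digamma(0.5 * (nu[k] + 1 - seq_len(d)))) + d * log(2) +
        determinant(W[[k]], logarithm = TRUE)$modulus[1]
    }, numeric(1))

    logrho <- matrix(0, n, K)
    for (k in seq_len(K)) {
      xc <- sweep(X, 2, m[k, ], "-")
      quad <- d / beta[k] + nu[k] * rowSums((xc %*% W[[k]]) * xc)
      logrho[, k] <- Elogpi[k] + 0.5 * Elogdet[k] - 0.5 * d * log(2 * pi) - 0.5 * quad
    }
    mx <- apply(logrho, 1, max)
    r_new <- exp(logrho - mx)
    r_new <- r_new / rowSums(r_new)

    # evidence lower bound (computed with the just-updated responsibilities)
    r_use <- r_new
    Nk2 <- colSums(r_use) + 1e-12
    e_pX <- 0
    for (k in seq_len(K)) {
      xc <- sweep(X, 2, m[k, ], "-")
      quad <- d / beta[k] + nu[k] * rowSums((xc %*% W[[k]]) * xc)
      e_pX <- e_pX + sum(r_use[, k] * (0.5 * Elogdet[k] - 0.5 * d * log(2 * pi) - 0.5 * quad))
    }
    e_pZ <- sum(sweep(r_use, 2, Elogpi, "*"))
    e_ppi <- lgamma(K * alpha0) - K * lgamma(alpha0) + (alpha0 - 1) * sum(Elogpi)
    e_pmuL <- 0
    for (k in seq_len(K)) {
      dmk <- m[k, ] - m0
      e_pmuL <- e_pmuL + 0.5 * (d * log(beta0 / (2 * pi)) + Elogdet[k] -
        d * beta0 / beta[k] - beta0 * nu[k] * sum((dmk %*% W[[k]]) * dmk)) +
        log_wishart_B(W0, nu0) + 0.5 * (nu0 - d - 1) * Elogdet[k] -
        0.5 * nu[k] * sum(diag(W0inv %*% W[[k]]))
    }
    e_qZ <- sum(r_use[r_use > 0] * log(r_use[r_use > 0]))
    e_qpi <- lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * Elogpi)
    e_qmuL <- 0
    for (k in seq_len(K)) {
      H <- -log_wishart_B(W[[k]], nu[k]) - 0.5 * (nu[k] - d - 1) * Elogdet[k] +
        0.5 * nu[k] * d
      e_qmuL <- e_qmuL + 0.5 * Elogdet[k] + 0.5 * d * log(beta[k] / (2 * pi)) -
        0.5 * d - H
    }
    elbo <- e_pX + e_pZ + e_ppi + e_pmuL - e_qZ - e_qpi - e_qmuL
    r <- r_new
    if (is.finite(elbo) && abs(elbo - elbo_prev) < tol * (abs(elbo) + 1)) break
    elbo_prev <- elbo
  }
  weights <- (alpha0 + colSums(r)) / (K * alpha0 + nrow(r))
  list(responsibilities = r, weights = weights, elbo = elbo, means = m)
}

#' Merge preliminary clusters with a variational Bayesian Gaussian mixture
#'
#' Fits a full-covariance variational Bayesian Gaussian mixture with
#' `max_components` components and a sparsity-inducing Dirichlet weight prior
#' (concentration `1/max_components`) to the rows of `scores` (one row per
#' preliminary cluster, columns are PCA scores of the secondary radiomic
#' features). Components whose posterior weight falls below `weight_floor` or
#' that attract no row are discarded; the surviving components define the
#' final subregions. The best of `restarts` seeded initializations (by
#' evidence lower bound) is kept.
#'
#' @param scores numeric matrix (rows = preliminary clusters).
#' @param max_components upper bound on components; defaults to
#'   `min(10, nrow(scores))`.
#' @param seed integer seed.
#' @param weight_floor minimum posterior weight of a surviving component.
#' @param restarts number of random restarts.
#' @return list of class `bgmm_fit`: `assignment` (per-row subregion label
#'   `1..V`), `V`, `weights`, `elbo`.
#' @export
cluster_subregions_bgmm <- function(scores, max_components = NULL, seed = 1L,
                                    weight_floor = 0.01, restarts = 10,
                                    prior_scale = 8) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (n == 1) {
    return(structure(list(assignment = 1L, V = 1L, weights = 1, elbo = NA_real_),
                     class = "bgmm_fit"))
  }
  K <- min(max_components %||% 10L, n, 10L)
  if (max(apply(X, 2, function(c) diff(range(c)))) < 1e-12) {
    return(structure(list(assignment = rep(1L, n), V = 1L, weights = 1,
                          elbo = NA_real_), class = "bgmm_fit"))
  }
  alpha0 <- 1 / K
  best <- NULL
  with_seed(derive_seed(seed, "bgmm"), {
    n_distinct <- nrow(unique(X))
    hard_init <- function(cl) {
      r0 <- matrix(1e-3, n, K)
      r0[cbind(seq_len(n), cl)] <- 1
      r0 / rowSums(r0)
    }
    inits <- list()
    if (n <= K) inits <- c(inits, list(hard_init(seq_len(n))))  # one row/component
    k_max <- min(K, n_distinct - 1, 6)
    for (k in (if (k_max >= 2) 2:k_max else integer(0))) {
      cl <- tryCatch(stats::kmeans(X, centers = k, nstart = 5)$cluster,
                     error = function(e) NULL)
      if (!is.null(cl)) inits <- c(inits, list(hard_init(cl)))
    }
    while (length(inits) < restarts) {
      r0 <- matrix(stats::rgamma(n * K, 1), n, K)
      inits <- c(inits, list(r0 / rowSums(r0)))
    }
    for (r in inits[seq_len(max(restarts, length(inits)))]) {
      fit <- vbgmm_fit_once(X, K, r, alpha0, prior_scale = prior_scale)
      if (is.null(best) || (is.finite(fit$elbo) && fit$elbo > best$elbo)) best <- fit
    }
  })
  hard <- max.col(best$responsibilities, ties.method = "first")
  effective <- which(best$weights >= weight_floor & tabulate(hard, K) > 0)
  if (length(effective) == 0) effective <- which.max(best$weights)
  # reassign rows stuck on discarded components to their best effective one
  hard <- vapply(seq_len(n), function(i) {
    if (hard[i] %in% effective) hard[i]
    else effective[which.max(best$responsibilities[i, effective])]
  }, integer(1))
  sizes <- table(factor(hard, levels = effective))
  ord <- effective[order(-as.numeric(sizes))]
  assignment <- match(hard, ord)
  structure(list(assignment = as.integer(assignment), V = length(ord),
                 weights = best$weights, elbo = best$elbo),
            class = "bgmm_fit")
}
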