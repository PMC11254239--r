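# Feature-selection cascade: ICC reproducibility filter, univariate logistic
# screen, pairwise-correlation pruning, LASSO, stepwise AIC — plus the
# clinicoradiological variable-selection procedure.

#' Two-way random-effects single-measure absolute-agreement ICC
#'
#' ICC(2,1) from the two-way ANOVA mean squares: with n subjects and k
#' raters, `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings numeric matrix, subjects x raters.
#' @return the ICC (may be `NA` when between-subject variance is 0).
#' @export
icc21 <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  row_m <- rowMeans(x); col_m <- colMeans(x); mu <- mean(x)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  msc <- n * sum((col_m - mu)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && mse == 0)) return(NA_real_)
  (msr - mse) / denom
}

#' Reproducibility (ICC) feature filter
#'
#' Computes, per feature, the interobserver ICC(2,1) between rater 1 and
#' rater 2 and the intraobserver ICC(2,1) between rater 1's two sessions;
#' features are kept iff both exceed `threshold`. Features with undefined
#' ICC (no between-subject variance) are dropped with a warning.
#'
#' @param features_rater1,features_rater2,features_rater1_repeat data frames
#'   or matrices with identical feature columns over the same subjects.
#' @param threshold ICC cutoff (default 0.75).
#' @return list with `kept` (feature names) and `icc` (tibble of per-feature
#'   inter/intra ICCs).
#' @export
icc_filter <- function(features_rater1, features_rater2, features_rater1_repeat,
                       threshold = 0.75) {
  f1 <- as.matrix(features_rater1)
  f2 <- as.matrix(features_rater2)
  f3 <- as.matrix(features_rater1_repeat)
  stopifnot(identical(dim(f1), dim(f2)), identical(dim(f1), dim(f3)),
            nrow(f1) >= 2)
  feats <- colnames(f1)
  inter <- vapply(seq_along(feats), function(j) icc21(cbind(f1[, j], f2[, j])),
                  numeric(1))
  intra <- vapply(seq_along(feats), function(j) icc21(cbind(f1[, j], f3[, j])),
                  numeric(1))
  undef <- is.na(inter) | is.na(intra)
  if (any(undef)) warning(sum(undef), " features with undefined ICC dropped")
  kept <- feats[!undef & inter > threshold & intra > threshold]
  list(kept = kept,
       icc = tibble::tibble(feature = feats, icc_inter = inter,
                            icc_intra = intra,
                            kept = feature %in% kept))
}

#' Univariate logistic screen
#'
#' Fits a single-covariate logistic regression per feature and keeps those
#' with Wald p below `alpha`. Features that separate the classes completely
#' (the Wald test degenerates) are kept and flagged. Constant features are
#' dropped with a warning.
#'
#' @param X data frame / matrix of features.
#' @param y binary outcome (0/1), both classes present.
#' @param alpha significance threshold (default 0.05).
#' @return tibble with `feature`, `estimate`, `p_value`, `separation`, `kept`.
#' @export
univariate_screen <- function(X, y, alpha = 0.05) {
  X <- as.data.frame(X)
  stopifnot(length(unique(y)) == 2)
  res <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    if (stats::sd(x) == 0) {
      warning("constant feature ", nm, " dropped")
      return(tibble::tibble(feature = nm, estimate = NA_real_, p_value = NA_real_,
                            separation = FALSE, kept = FALSE))
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    co <- summary(fit)$coefficients
    est <- co["x", "Estimate"]
    p <- co["x", "Pr(>|z|)"]
    sep <- !fit$converged || abs(est) > 15
    tibble::tibble(feature = nm, estimate = est, p_value = p,
                   separation = sep, kept = sep || p < alpha)
  })
  dplyr::bind_rows(res)
}

#' Redundancy pruning by pairwise correlation
#'
#' Iteratively finds the feature pair with the largest absolute Pearson
#' correlation above `threshold` and removes, of the two, the one with the
#' larger mean absolute correlation to all remaining features. Ties are
#' broken by feature-id order, so the result is deterministic.
#'
#' @param X data frame / matrix of features (>= 2 columns).
#' @param threshold correlation cutoff (default 0.75).
#' @return character vector of kept feature names.
#' @export
correlation_prune <- function(X, threshold = 0.75) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  keep <- colnames(X)
  r <- abs(stats::cor(X))
  diag(r) <- 0
  while (length(keep) > 1) {
    sub <- r[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    pair <- keep[sort(hit)]
    mean_r <- rowMeans(sub[pair, , drop = FALSE])
    drop <- pair[which.max(mean_r)]   # ties: which.max takes the first (id order)
    keep <- setdiff(keep, drop)
  }
  keep
}

# Stratified fold assignment (both classes spread over folds).
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# Grouped stratified folds: groups (e.g. patients) stay within one fold.
grouped_folds <- function(groups, y, n_folds, seed) {
  g <- unique(groups)
  gy <- vapply(g, function(gg) max(y[groups == gg]), numeric(1))
  gf <- stratified_folds(gy, n_folds, seed)
  gf[match(groups, g)]
}

#' LASSO feature selection with cross-validated AUC
#'
#' L1-penalized logistic regression over a log-spaced lambda path; the
#' penalty is chosen to maximize the mean validation AUC over stratified
#' folds (ties resolved toward the stronger penalty), and the features with
#' nonzero coefficients at that penalty are kept.
#'
#' @param X numeric matrix of (standardized) features.
#' @param y binary outcome.
#' @param n_folds folds for cross-validation (default 10).
#' @param seed integer seed (fold assignment).
#' @param criterion `"max_auc"` (default) or `"1se"`.
#' @return list with `kept`, `lambda`, `path` (tibble lambda x mean CV AUC),
#'   and the full-data `fit`.
#' @export
lasso_select <- function(X, y, n_folds = 10, seed = 1L,
                         criterion = c("max_auc", "1se")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    warning("fewer than 2 observations in a class; LASSO step skipped")
    return(list(kept = colnames(X), lambda = NA_real_,
                path = tibble::tibble(lambda = numeric(0),
                                      mean_cv_auc = numeric(0)),
                fit = NULL))
  }
  full <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                         standardize = FALSE)
  lambdas <- full$lambda
  n_folds <- max(2L, min(n_folds, sum(y == 1), sum(y == 0)))
  folds <- stratified_folds(y, n_folds, derive_seed(seed, "lasso-folds"))
  aucs <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (min(table(factor(y[tr], levels = c(0, 1)))) < 2 ||
        length(unique(y[!tr])) < 2) next
    # folds whose fit or prediction degenerates are skipped
    pred <- tryCatch({
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 1, lambda = lambdas, standardize = FALSE)
      stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
    }, error = function(e) NULL)
    if (is.null(pred)) next
    aucs[f, seq_len(ncol(pred))] <- apply(pred, 2, function(p) auc_mw(p, y[!tr]))
  }
  if (all(is.na(aucs))) {
    # no valid resampling split: penalized-likelihood AIC along the path
    warning("cross-validation infeasible for LASSO; using AIC along the path")
    dev <- (1 - full$dev.ratio) * full$nulldev
    best <- which.min(dev + 2 * full$df)
    mean_auc <- rep(NA_real_, length(lambdas))
  } else {
    mean_auc <- colMeans(aucs, na.rm = TRUE)
    se_auc <- apply(aucs, 2, function(a) stats::sd(a, na.rm = TRUE) / sqrt(sum(!is.na(a))))
    best <- if (criterion == "max_auc") {
      min(which(mean_auc == max(mean_auc, na.rm = TRUE)))  # largest lambda among ties
    } else {
      thr <- max(mean_auc, na.rm = TRUE) - se_auc[which.max(mean_auc)]
      min(which(mean_auc >= thr))
    }
  }
  co <- as.matrix(stats::coef(full, s = lambdas[best]))[-1, 1]
  kept <- names(co)[co != 0]
  if (length(kept) == 0) warning("LASSO selected no features")
  list(kept = kept, lambda = lambdas[best],
       path = tibble::tibble(lambda = lambdas, mean_cv_auc = mean_auc),
       fit = full)
}

#' Bidirectional stepwise selection by AIC
#'
#' Starts from the logistic model containing all candidate features and
#' performs bidirectional stepwise selection minimizing AIC
#' (`-2 loglik + 2k`), stopping when no single addition or removal lowers
#' the AIC.
#'
#' @param X data frame of candidate features (at most 30, the post-LASSO
#'   scale).
#' @param y binary outcome.
#' @return list with `kept` (feature names), `aic_sequence` and the final
#'   `fit`.
#' @export
stepwise_aic <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) <= 30)
  dat <- cbind(X, .y = as.numeric(y))
  full <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  scope <- list(lower = .y ~ 1, upper = stats::formula(full))
  fit <- suppressWarnings(MASS::stepAIC(full, scope = scope, direction = "both",
                                        trace = 0))
  kept <- setdiff(all.vars(stats::formula(fit)), ".y")
  aic_seq <- fit$anova$AIC
  list(kept = kept, aic_sequence = aic_seq, fit = fit)
}

#' Run the radiomic feature-selection cascade
#'
#' The fixed order: optional ICC reproducibility filter, univariate logistic
#' screen, pairwise-correlation pruning, LASSO with cross-validated penalty,
#' bidirectional stepwise AIC. Each step only ever removes features, and the
#' returned trace records every step's input, output and statistics, so any
#' elimination can be re-derived.
#'
#' @param X data frame / matrix of standardized features (rows = training
#'   regions or patients).
#' @param y binary outcome aligned with the rows of `X`.
#' @param icc_kept optional character vector from [icc_filter()]; when
#'   supplied, features outside it are removed first.
#' @param alpha univariate threshold (default 0.05).
#' @param cor_threshold correlation-pruning threshold (default 0.75).
#' @param n_folds LASSO cross-validation folds.
#' @param seed integer seed.
#' @param max_stepwise candidate cap ahead of the stepwise step.
#' @return list of class `selection_trace`: `kept` (final feature set) and
#'   `steps` (named list with per-step results).
#' @export
select_radiomic_features <- function(X, y, icc_kept = NULL, alpha = 0.05,
                                     cor_threshold = 0.75, n_folds = 10,
                                     seed = 1L, max_stepwise = 30) {
  X <- as.data.frame(X)
  steps <- list()
  if (!is.null(icc_kept)) {
    X <- X[, intersect(names(X), icc_kept), drop = FALSE]
    steps$icc <- list(kept = names(X))
  }
  uni <- univariate_screen(X, y, alpha)
  keep_u <- uni$feature[uni$kept]
  steps$univariate <- list(kept = keep_u, table = uni)
  if (length(keep_u) == 0) {
    return(structure(list(kept = character(0), steps = steps),
                     class = "selection_trace"))
  }
  X <- X[, keep_u, drop = FALSE]
  keep_c <- if (ncol(X) >= 2) correlation_prune(X, cor_threshold) else names(X)
  steps$correlation <- list(kept = keep_c)
  X <- X[, keep_c, drop = FALSE]
  if (ncol(X) >= 2) {
    las <- lasso_select(as.matrix(X), y, n_folds = n_folds, seed = seed)
    keep_l <- las$kept
    steps$lasso <- list(kept = keep_l, lambda = las$lambda, path = las$path)
  } else {
    keep_l <- names(X)
    steps$lasso <- list(kept = keep_l, lambda = NA_real_)
  }
  if (length(keep_l) == 0) {
    return(structure(list(kept = character(0), steps = steps),
                     class = "selection_trace"))
  }
  X <- X[, keep_l, drop = FALSE]
  if (ncol(X) > max_stepwise) {
    # rank by univariate |z| and cap (deterministic scan order)
    z <- abs(uni$estimate[match(names(X), uni$feature)] /
               ifelse(uni$p_value[match(names(X), uni$feature)] > 0,
                      stats::qnorm(pmax(uni$p_value[match(names(X), uni$feature)] / 2,
                                        1e-300), lower.tail = FALSE), Inf))
    X <- X[, order(-z)[seq_len(max_stepwise)], drop = FALSE]
  }
  st <- stepwise_aic(X, y)
  steps$stepwise <- list(kept = st$kept, aic_sequence = st$aic_sequence)
  structure(list(kept = st$kept, steps = steps), class = "selection_trace")
}

#' Clinicoradiological variable selection
#'
#' Univariate logistic screening of each clinicoradiological variable
#' (multi-level factors tested with a likelihood-ratio test) at `p < 0.1`,
#' bidirectional stepwise AIC on the screened set, and retention of the
#' variables with multivariable p below 0.05. Odds ratios with 95%
#' confidence intervals are reported per non-reference level of every
#' retained variable. If nothing survives, the clinicoradiological model
#' falls back to intercept-only with a warning.
#'
#' @param clinical data frame of covariates (factors dummy-coded by the
#'   model functions; reference levels: low location, N0).
#' @param y binary MSI outcome.
#' @param screen_alpha univariate threshold (default 0.1).
#' @param final_alpha multivariable threshold (default 0.05).
#' @return list of class `clinical_selection`: `kept` (variable names),
#'   `univariate` (tibble), `odds_ratios` (tibble per retained level),
#'   `fit` (final glm or NULL).
#' @export
select_clinical_variables <- function(clinical, y, screen_alpha = 0.1,
                                      final_alpha = 0.05) {
  clinical <- as.data.frame(clinical)
  vars <- names(clinical)
  uni <- lapply(vars, function(v) {
    dat <- data.frame(.y = as.numeric(y), x = clinical[[v]])
    fit <- suppressWarnings(stats::glm(.y ~ x, data = dat, family = stats::binomial()))
    null <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
    p <- stats::anova(null, fit, test = "LRT")$`Pr(>Chi)`[2]
    tibble::tibble(variable = v, p_value = p)
  })
  uni <- dplyr::bind_rows(uni)
  screened <- uni$variable[!is.na(uni$p_value) & uni$p_value < screen_alpha]
  if (length(screened) == 0) {
    warning("no clinicoradiological variable passed the univariate screen")
    return(structure(list(kept = character(0), univariate = uni,
                          odds_ratios = tibble::tibble(), fit = NULL),
                     class = "clinical_selection"))
  }
  dat <- cbind(clinical[, screened, drop = FALSE], .y = as.numeric(y))
  full <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  st <- suppressWarnings(MASS::stepAIC(full, scope = list(lower = .y ~ 1,
                                                          upper = stats::formula(full)),
                                       direction = "both", trace = 0))
  st_vars <- intersect(screened, all.vars(stats::formula(st)))
  # retain variables significant in the multivariable model (LRT per variable)
  kept <- character(0)
  for (v in st_vars) {
    reduced_vars <- setdiff(st_vars, v)
    f_full <- stats::glm(stats::reformulate(st_vars, ".y"), data = dat,
                         family = stats::binomial())
    f_red <- stats::glm(stats::reformulate(if (length(reduced_vars)) reduced_vars else "1", ".y"),
                        data = dat, family = stats::binomial())
    p <- stats::anova(f_red, f_full, test = "LRT")$`Pr(>Chi)`[2]
    if (!is.na(p) && p < final_alpha) kept <- c(kept, v)
  }
  if (length(kept) == 0) {
    warning("no clinicoradiological variable retained; intercept-only model")
    return(structure(list(kept = character(0), univariate = uni,
                          odds_ratios = tibble::tibble(), fit = NULL),
                     class = "clinical_selection"))
  }
  fit <- stats::glm(stats::reformulate(kept, ".y"), data = dat,
                    family = stats::binomial())
  co <- summary(fit)$coefficients
  rows <- rownames(co)[-1]
  ors <- tibble::tibble(
    term = rows,
    odds_ratio = exp(co[rows, "Estimate"]),
    ci_low = exp(co[rows, "Estimate"] - 1.96 * co[rows, "Std. Error"]),
    ci_high = exp(co[rows, "Estimate"] + 1.96 * co[rows, "Std. Error"]),
    p_value = co[rows, "Pr(>|z|)"])
  structure(list(kept = kept, univariate = uni, odds_ratios = ors, fit = fit),
            class = "clinical_selection")
}
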