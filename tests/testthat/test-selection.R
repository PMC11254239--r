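test_that("ICC(2,1) matches a two-way ANOVA computation and filters correctly", {
  # 6-subject, 2-rater table; reference via aov() mean squares
  x <- matrix(c(9, 2, 5, 8, 6, 7,
                10, 4, 6, 9, 7, 8), ncol = 2)
  dat <- data.frame(y = as.vector(x),
                    subj = factor(rep(1:6, 2)), rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, dat))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  ref <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(icc21(x), ref, tolerance = 1e-10)

  withr::with_seed(1, {
    base <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
    same <- base
    noise <- matrix(rnorm(30 * 4), 30, 4, dimnames = dimnames(base))
  })
  res <- icc_filter(base, same, same)
  expect_setequal(res$kept, colnames(base))   # perfect agreement keeps all
  res2 <- icc_filter(base, noise, noise)
  expect_length(res2$kept, 0)                 # independent noise keeps none
})

test_that("univariate screen handles null, perfect and 2x2 cases", {
  withr::with_seed(2, {
    y <- rep(c(0, 1), each = 50)
    X <- data.frame(null_f = rnorm(100),
                    perfect = y + rnorm(100, sd = 1e-4),
                    binary = rbinom(100, 1, ifelse(y == 1, 0.8, 0.3)))
  })
  res <- univariate_screen(X, y, alpha = 0.05)
  expect_false(res$kept[res$feature == "null_f"])
  expect_true(res$kept[res$feature == "perfect"])
  expect_true(res$separation[res$feature == "perfect"])
  # Wald z^2 from the 2x2 table: log-OR / SE with SE = sqrt(sum of 1/cells)
  tab <- table(X$binary, y)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]))
  se <- sqrt(sum(1 / tab))
  z2 <- (lor / se)^2
  expect_equal(res$estimate[res$feature == "binary"], lor, tolerance = 1e-6)
  fit_z2 <- stats::qnorm(res$p_value[res$feature == "binary"] / 2,
                         lower.tail = FALSE)^2
  expect_equal(fit_z2, z2, tolerance = 1e-4)
  # constant feature dropped with warning
  expect_warning(res3 <- univariate_screen(data.frame(c1 = rep(1, 100)), y),
                 "constant")
  expect_false(any(res3$kept))
})

test_that("correlation pruning drops the hub feature first", {
  skip_if_not_installed("MASS")
  # A correlates strongly with both B and C; B-C only weakly: the rule must
  # remove the "hub" A first and then stop
  S <- matrix(c(1, 0.85, 0.80,
                0.85, 1, 0.45,
                0.80, 0.45, 1), 3, 3)
  X <- MASS::mvrnorm(200, mu = rep(0, 3), Sigma = S, empirical = TRUE)
  colnames(X) <- c("A", "B", "C")
  kept <- correlation_prune(X, threshold = 0.75)
  expect_setequal(kept, c("B", "C"))   # A has the highest mean |r|
  # duplicates: exactly one removed
  X2 <- cbind(a = rnorm(50), b = rnorm(50))
  X2 <- cbind(X2, a2 = X2[, "a"])
  expect_length(correlation_prune(X2, 0.75), 2)
  # orthogonal features all kept
  X3 <- MASS::mvrnorm(100, rep(0, 3), diag(3), empirical = TRUE)
  colnames(X3) <- paste0("o", 1:3)
  expect_setequal(correlation_prune(X3, 0.75), colnames(X3))
  # output invariant: no remaining pair exceeds the threshold
  withr::with_seed(3, X4 <- matrix(rnorm(100 * 8), 100, 8) %*% diag(8) +
                     rnorm(100))
  colnames(X4) <- paste0("v", 1:8)
  k4 <- correlation_prune(X4, 0.75)
  if (length(k4) > 1) {
    r <- abs(stats::cor(X4[, k4])); diag(r) <- 0
    expect_lte(max(r), 0.75)
  }
})

test_that("LASSO keeps a strong predictor and drops a null design", {
  hits <- 0
  for (s in 1:10) {
    withr::with_seed(1000 + s, {
      n <- 200
      X <- matrix(rnorm(n * 51), n, 51,
                  dimnames = list(NULL, c("strong", paste0("noise", 1:50))))
      eta <- 2 * X[, "strong"]
      y <- rbinom(n, 1, plogis(eta))
    })
    res <- lasso_select(X, y, n_folds = 5, seed = s)
    if ("strong" %in% res$kept) hits <- hits + 1
  }
  expect_gte(hits, 9)   # >= 90% of seeds on a 2-sigma effect
  # y independent of X: the conservative (1-SE) rule selects nothing in most
  # draws — the L1 path shrinks every coefficient to zero
  sizes <- vapply(1:5, function(s) {
    withr::with_seed(2000 + s, {
      X <- matrix(rnorm(100 * 20), 100, 20,
                  dimnames = list(NULL, paste0("n", 1:20)))
      y <- rbinom(100, 1, 0.3)
    })
    length(suppressWarnings(lasso_select(X, y, n_folds = 5, seed = s,
                                         criterion = "1se"))$kept)
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(sizes)))), 0L)
  # penalty limit: at the largest path lambda every coefficient is zero
  withr::with_seed(99, {
    Xl <- matrix(rnorm(500), 100, 5); yl <- rbinom(100, 1, 0.4)
  })
  fl <- glmnet::glmnet(Xl, yl, family = "binomial", alpha = 1)
  expect_true(all(as.matrix(fl$beta)[, 1] == 0))
})

test_that("stepwise AIC matches the exhaustive best subset on 4 candidates", {
  withr::with_seed(7, {
    n <- 500
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
    y <- rbinom(n, 1, plogis(1.5 * X$a - 1.2 * X$b))
  })
  st <- stepwise_aic(X, y)
  # exhaustive 2^4 subset search
  best_aic <- Inf; best_set <- NULL
  for (m in 0:15) {
    vars <- names(X)[as.logical(bitwAnd(m, c(1, 2, 4, 8)))]
    f <- if (length(vars)) stats::reformulate(vars, "y") else y ~ 1
    a <- stats::AIC(stats::glm(f, data = cbind(X, y = y), family = binomial()))
    if (a < best_aic) { best_aic <- a; best_set <- vars }
  }
  expect_setequal(st$kept, best_set)
  expect_setequal(st$kept, c("a", "b"))   # noise dropped, informative kept
})

test_that("clinical variable selection recovers planted associations", {
  cl <- generate_clinical_cohort(800, 0.25, location_or = c(middle = 1.35,
                                                            high = 3),
                                 nstage_or = 0.4, seed = 31)
  sel <- select_clinical_variables(
    as.data.frame(cl[, c("age", "sex", "cea", "ca19_9", "location",
                         "t_stage", "n_stage")]), cl$msi)
  expect_true(all(c("location", "n_stage") %in% sel$kept))
  or_high <- sel$odds_ratios$odds_ratio[grepl("high", sel$odds_ratios$term)]
  or_n <- sel$odds_ratios$odds_ratio[grepl("N1-N2", sel$odds_ratios$term)]
  expect_gt(or_high, 1.5)
  expect_lt(or_n, 0.8)
  # a null covariate is rarely selected: check the screen level on new draws
  null_hits <- vapply(1:10, function(s) {
    cln <- generate_clinical_cohort(400, 0.25, seed = 400 + s)
    u <- suppressWarnings(select_clinical_variables(
      as.data.frame(cln[, c("age", "sex", "cea", "ca19_9", "location",
                            "t_stage", "n_stage")]), cln$msi))
    "cea" %in% u$kept
  }, logical(1))
  expect_lte(mean(null_hits), 0.15)
})

test_that("the full cascade is monotone and reproducible", {
  withr::with_seed(11, {
    n <- 120
    X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
    X[, 2] <- X[, 1] * 0.95 + rnorm(n, sd = 0.2)   # redundant pair
    y <- rbinom(n, 1, plogis(1.5 * X[, 1] - X[, 5]))
  })
  tr1 <- suppressWarnings(select_radiomic_features(X, y, seed = 5))
  tr2 <- suppressWarnings(select_radiomic_features(X, y, seed = 5))
  expect_identical(tr1$kept, tr2$kept)
  expect_true(all(tr1$kept %in% tr1$steps$univariate$kept))
  expect_true(all(tr1$steps$lasso$kept %in% tr1$steps$correlation$kept))
})
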