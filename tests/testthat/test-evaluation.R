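test_that("AUC equals the concordant-pair count and pROC agrees", {
  withr::with_seed(3, {
    y <- c(rep(1, 4), rep(0, 6))
    s <- round(rnorm(10), 2)
  })
  a <- roc_auc_ci(s, y)
  # brute-force pair counting
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  conc <- mean((s[pairs$i] > s[pairs$j]) + 0.5 * (s[pairs$i] == s[pairs$j]))
  expect_equal(a$auc, conc, tolerance = 1e-12)
  # DeLong variance from the placement values, computed directly
  v10 <- vapply(which(y == 1), function(i) mean((s[i] > s[y == 0]) +
                                                0.5 * (s[i] == s[y == 0])), numeric(1))
  v01 <- vapply(which(y == 0), function(j) mean((s[y == 1] > s[j]) +
                                                0.5 * (s[y == 1] == s[j])), numeric(1))
  expect_equal(a$se^2, var(v10) / 4 + var(v01) / 6, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(y, s, quiet = TRUE, levels = c(0, 1), direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- suppressWarnings(pROC::ci.auc(pr, method = "delong"))
  expect_equal(a$ci_low, max(0, ci[1]), tolerance = 1e-6)
  expect_equal(a$ci_high, min(1, ci[3]), tolerance = 1e-6)
})

test_that("AUC degenerate and invariance properties", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc_ci(c(1, 2, 3, 4), y)$auc, 1)
  expect_error(roc_auc_ci(1:4, c(1, 1, 1, 1)), "both classes")
  withr::with_seed(4, { s <- rnorm(40); y2 <- rbinom(40, 1, 0.5) })
  expect_equal(roc_auc_ci(s, y2)$auc, roc_auc_ci(exp(s), y2)$auc)
})

test_that("DeLong test: self-comparison, rank invariance, pROC agreement", {
  withr::with_seed(5, {
    y <- rbinom(40, 1, 0.4)
    a <- rnorm(40) + y
    b <- rnorm(40) + 0.5 * y
  })
  expect_warning(d_same <- delong_test(a, a, y), "zero variance")
  expect_equal(d_same$p_value, 1)
  d_mono <- delong_test(a, plogis(2 * a - 1), y)
  expect_equal(d_mono$p_value, 1)   # monotone transform: identical ranks
  d <- delong_test(a, b, y)
  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(d$p_value, pr$p.value, tolerance = 1e-9)
})

test_that("classification metrics match hand arithmetic on a fixed table", {
  # TP=9, FN=2, FP=13, TN=69
  y <- c(rep(1, 11), rep(0, 82))
  s <- c(rep(0.9, 9), rep(0.1, 2), rep(0.9, 13), rep(0.1, 69))
  m <- classification_metrics(s, y, cutoff = 0.5, n_boot = 50, seed = 1)
  val <- setNames(m$value, m$metric)
  expect_equal(val[["sensitivity"]], 9 / 11)
  expect_equal(val[["specificity"]], 69 / 82)
  expect_equal(val[["f1"]], 2 * 9 / (2 * 9 + 13 + 2))
  expect_equal(val[["accuracy"]], (9 + 69) / 93)
  expect_true(all(m$ci_low <= m$value & m$value <= m$ci_high))
  # all-negative predictions on prevalence-pi data
  m0 <- classification_metrics(rep(0, 93), y, cutoff = 0.5, n_boot = 10, seed = 1)
  v0 <- setNames(m0$value, m0$metric)
  expect_equal(v0[["sensitivity"]], 0)
  expect_equal(v0[["specificity"]], 1)
  expect_equal(v0[["accuracy"]], 82 / 93)
  expect_error(classification_metrics(s, y), "cutoff")
})

test_that("decision curves match hand arithmetic and limits", {
  # toy cohort, threshold 0.2: TP=5, FP=3 of n=20
  y <- c(rep(1, 6), rep(0, 14))
  s <- c(rep(0.8, 5), 0.1, rep(0.8, 3), rep(0.05, 11))
  dc <- decision_curve(s, y, thresholds = 0.2)
  expect_equal(dc$net_benefit, 5 / 20 - (3 / 20) * 0.2 / 0.8)
  expect_equal(dc$treat_all, 6 / 20 - (14 / 20) * 0.2 / 0.8)
  expect_equal(dc$treat_none, 0)
  # treat-all tends to prevalence as t -> 0+
  dc2 <- decision_curve(s, y, thresholds = 1e-6)
  expect_equal(dc2$treat_all, mean(y), tolerance = 1e-5)
  # a model that never predicts positive has NB = 0 everywhere
  dc3 <- decision_curve(rep(0, 20), y)
  expect_true(all(dc3$net_benefit == 0))
  # NB never exceeds prevalence
  withr::with_seed(6, { sr <- runif(200); yr <- rbinom(200, 1, 0.3) })
  dcr <- decision_curve(sr, yr)
  expect_lte(max(dcr$net_benefit), mean(yr))
})

test_that("Hosmer-Lemeshow: perfect calibration, hand example, type-I error", {
  # construct two risk groups whose event rates equal their probabilities
  p <- c(rep(0.2, 50), rep(0.8, 50))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 40), rep(0, 10))
  hl <- hosmer_lemeshow(p, y, n_groups = 2)
  expect_equal(hl$statistic, 0)
  # hand computation for an imperfect two-group split
  y2 <- c(rep(1, 15), rep(0, 35), rep(1, 35), rep(0, 15))
  hl2 <- hosmer_lemeshow(p, y2, n_groups = 2)
  ref <- (15 - 10)^2 / (10 * (1 - 10 / 50)) + (35 - 40)^2 / (40 * (1 - 40 / 50))
  expect_equal(hl2$statistic, ref, tolerance = 1e-10)
  # type-I error of a well-specified model (reduced replicate count)
  rej <- vapply(1:200, function(i) {
    withr::with_seed(5000 + i, {
      x <- rnorm(300)
      pr <- plogis(-1 + x)
      yy <- rbinom(300, 1, pr)
    })
    fit <- glm(yy ~ x, family = binomial())
    hosmer_lemeshow(fitted(fit), yy)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("Youden cutoff matches an exhaustive midpoint scan", {
  withr::with_seed(7, {
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(12), 2)
  })
  yc <- youden_cutoff(s, y)
  u <- sort(unique(s))
  cands <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  js <- vapply(cands, function(ct) {
    sens <- mean(s[y == 1] >= ct); spec <- mean(s[y == 0] < ct)
    sens + spec - 1
  }, numeric(1))
  expect_equal(yc$youden, max(js), tolerance = 1e-12)
  # perfectly separated scores give index 1
  expect_equal(youden_cutoff(c(1, 2, 3, 10, 11, 12),
                             c(0, 0, 0, 1, 1, 1))$youden, 1)
})

test_that("Kaplan-Meier matches the hand product-limit on a textbook example", {
  # classic 6-subject example: events at 6, 6, censored 6, event 7, censored
  # 9, event 10 (all one group) - compare against survfit and hand values
  t1 <- c(6, 6, 6, 7, 9, 10)
  e1 <- c(1, 1, 0, 1, 0, 1)
  km <- km_logrank(c(t1, t1), c(e1, e1), rep(c("A", "B"), each = 6))
  a <- km$curves[km$curves$group == "A", ]
  # hand product-limit: S(6) = 1 - 2/6; S(7) = S(6) * (1 - 1/3); S(10) = 0
  expect_equal(a$surv[a$time == 6], 4 / 6)
  expect_equal(a$surv[a$time == 7], 4 / 6 * 2 / 3, tolerance = 1e-12)
  expect_equal(a$surv[a$time == 10], 0)
  expect_gt(km$logrank_p, 0.99)   # identical groups
  # no censoring: KM equals the empirical survivor function
  t2 <- c(2, 4, 4, 7, 9)
  km2 <- km_logrank(c(t2, 100 + t2), rep(1, 10),
                    rep(c("A", "B"), each = 5))
  a2 <- km2$curves[km2$curves$group == "A", ]
  ecdf_surv <- 1 - ecdf(t2)(a2$time)
  expect_equal(a2$surv, ecdf_surv, tolerance = 1e-12)
  # monotone non-increasing
  expect_true(all(diff(a2$surv) <= 0))
})

test_that("log-rank power at hazard ratio 4 exceeds 95%", {
  hits <- vapply(1:40, function(i) {
    cl <- generate_clinical_cohort(200, 0.5, hazard_ratio_mss_msi = 4,
                                   seed = 6000 + i)
    km <- suppressWarnings(km_logrank(cl$dfs_time, cl$dfs_event,
                                      ifelse(cl$msi == 1, "MSI", "MSS")))
    km$logrank_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
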