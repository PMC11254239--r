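# Model comparison and prognostic statistics: AUC with DeLong variance,
# DeLong paired test, threshold metrics with bootstrap CIs, decision curves,
# Hosmer-Lemeshow calibration, Youden cutoff, Kaplan-Meier / log-rank.

# Mann-Whitney AUC with tie correction.
auc_mw <- function(scores, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (per positive) and V01 (per negative).
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the tie-corrected Mann-Whitney statistic; its variance is
#' estimated from the DeLong placement values and the confidence interval
#' uses the normal approximation, clipped to `[0, 1]`.
#'
#' @param scores numeric risk scores.
#' @param y binary outcome (both classes required).
#' @return tibble with `auc`, `ci_low`, `ci_high`, `se`.
#' @export
roc_auc_ci <- function(scores, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required for AUC")
  auc <- auc_mw(scores, y)
  pl <- delong_placements(scores, y)
  safe_var <- function(v) if (length(v) < 2) 0 else stats::var(v)
  v <- safe_var(pl$v10) / length(pl$v10) + safe_var(pl$v01) / length(pl$v01)
  se <- sqrt(v)
  tibble::tibble(auc = auc,
                 ci_low = max(0, auc - stats::qnorm(0.975) * se),
                 ci_high = min(1, auc + stats::qnorm(0.975) * se),
                 se = se)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two models' AUCs on the same subjects via the
#' structural components (placement values); the difference is tested with a
#' two-sided normal z-test.
#'
#' @param scores_a,scores_b risk scores of the two models on the same
#'   subjects.
#' @param y binary outcome.
#' @return tibble with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, y) {
  y <- as.numeric(y)
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) == length(y))
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  safe_cov <- function(a, b) {
    if (length(a) < 2) matrix(0, 2, 2) else stats::cov(cbind(a, b))
  }
  s10 <- safe_cov(pa$v10, pb$v10)
  s01 <- safe_cov(pa$v01, pb$v01)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (var_diff <= 0) {
    warning("zero variance of the AUC difference; p = 1")
    return(tibble::tibble(auc_a = auc_a, auc_b = auc_b, z = 0, p_value = 1))
  }
  z <- (auc_a - auc_b) / sqrt(var_diff)
  tibble::tibble(auc_a = auc_a, auc_b = auc_b, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Threshold classification metrics with bootstrap confidence intervals
#'
#' F1, accuracy, sensitivity and specificity of the rule `score >= cutoff`,
#' with stratified bootstrap percentile confidence intervals. An explicit
#' cutoff is required — there is no silent 0.5 default.
#'
#' @param scores numeric risk scores.
#' @param y binary outcome.
#' @param cutoff decision threshold.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return tibble with one row per metric: `metric`, `value`, `ci_low`,
#'   `ci_high`.
#' @export
classification_metrics <- function(scores, y, cutoff, n_boot = 2000, seed = 1L) {
  if (missing(cutoff)) stop("a cutoff must be supplied")
  y <- as.numeric(y)
  point <- compute_metrics_at(scores, y, cutoff)
  pos <- which(y == 1); neg <- which(y == 0)
  boot <- with_seed(derive_seed(seed, "metric-boot"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      compute_metrics_at(scores[idx], y[idx], cutoff)
    }, numeric(4))
  })
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  tibble::tibble(metric = names(point), value = unname(point),
                 ci_low = ci[1, ], ci_high = ci[2, ])
}

compute_metrics_at <- function(scores, y, cutoff) {
  pred <- as.numeric(scores >= cutoff)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / length(y)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  c(f1 = f1, accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Decision-curve analysis
#'
#' Net benefit of the rule `score >= t` at each threshold probability `t`:
#' `NB(t) = TP/n - (FP/n) t/(1-t)`, together with the treat-all
#' (`pi - (1-pi) t/(1-t)`) and treat-none (0) reference policies.
#'
#' @param scores numeric risk scores (probability scale).
#' @param y binary outcome.
#' @param thresholds grid of threshold probabilities in (0, 1).
#' @return tibble with `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(scores, y, thresholds = seq(0.01, 0.60, by = 0.01)) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  y <- as.numeric(y)
  n <- length(y)
  pi_hat <- mean(y)
  nb <- vapply(thresholds, function(t) {
    pred <- scores >= t
    sum(pred & y == 1) / n - sum(pred & y == 0) / n * t / (1 - t)
  }, numeric(1))
  tibble::tibble(threshold = thresholds, net_benefit = nb,
                 treat_all = pi_hat - (1 - pi_hat) * thresholds / (1 - thresholds),
                 treat_none = 0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping of the predicted probabilities; within each
#' group the observed event count O is compared with the expected count E
#' via `sum (O - E)^2 / (E (1 - E/n_g))`, referred to a chi-squared
#' distribution with `n_groups - 2` degrees of freedom. Groups with expected
#' counts of 0 are merged with their neighbour (with a warning).
#'
#' @param probs predicted probabilities.
#' @param y binary outcome.
#' @param n_groups number of risk groups (default 10).
#' @return tibble with `statistic`, `df`, `p_value`, `n_groups`.
#' @export
hosmer_lemeshow <- function(probs, y, n_groups = 10) {
  y <- as.numeric(y)
  stopifnot(length(probs) >= 2 * n_groups)
  br <- unique(stats::quantile(probs, probs = seq(0, 1, length.out = n_groups + 1),
                               type = 7))
  if (length(br) < 3) stop("too few distinct probabilities to form groups")
  grp <- cut(probs, breaks = br, include.lowest = TRUE)
  tab <- tapply(y, grp, length)
  keep <- !is.na(tab) & tab > 0
  ng <- as.vector(tab[keep])
  og <- as.vector(tapply(y, grp, sum)[keep])
  eg <- as.vector(tapply(probs, grp, sum)[keep])
  if (any(eg <= 0) || any(eg >= ng)) {
    warning("degenerate expected counts; merging groups")
    ok <- eg > 0 & eg < ng
    og <- og[ok]; eg <- eg[ok]; ng <- ng[ok]
  }
  stat <- sum((og - eg)^2 / (eg * (1 - eg / ng)))
  df <- length(ng) - 2
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n_groups = length(ng))
}

#' Cutoff maximizing the Youden index
#'
#' Scans the midpoints between consecutive unique scores and returns the
#' cutoff maximizing `sensitivity + specificity - 1`; ties are broken toward
#' the higher cutoff (higher specificity).
#'
#' @param scores numeric risk scores.
#' @param y binary outcome.
#' @return list with `cutoff` and `youden`.
#' @export
youden_cutoff <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(unique(y)) == 2)
  u <- sort(unique(scores))
  cands <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  cands <- c(min(u) - 1e-9, cands, max(u) + 1e-9)
  j <- vapply(cands, function(ct) {
    m <- compute_metrics_at(scores, y, ct)
    m["sensitivity"] + m["specificity"] - 1
  }, numeric(1))
  best <- max(j)
  cutoff <- max(cands[j >= best - 1e-12])   # ties -> higher specificity
  list(cutoff = cutoff, youden = best)
}

#' Kaplan-Meier curves, log-rank test and 3-year survival
#'
#' Product-limit survival estimates per group with a two-group log-rank
#' test; the 3-year disease-free survival is the step function evaluated at
#' 36 months.
#'
#' @param times survival times (months, > 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level grouping (e.g. predicted MSI vs MSS).
#' @param eval_months time at which per-group survival is reported.
#' @return list with `curves` (tibble time/surv per group), `logrank_p`,
#'   `chisq`, `survival_at` (tibble group / survival at `eval_months`).
#' @export
km_logrank <- function(times, events, groups, eval_months = 36) {
  stopifnot(all(times > 0))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  for (g in levels(groups)) {
    if (sum(events[groups == g]) == 0) {
      warning("group ", g, " has no events")
    }
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit)
  curves <- tibble::tibble(
    group = sub("^groups=", "", as.character(sm$strata)),
    time = sm$time, surv = sm$surv,
    n_risk = sm$n.risk, n_event = sm$n.event)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  s36 <- summary(fit, times = eval_months, extend = TRUE)
  survival_at <- tibble::tibble(
    group = sub("^groups=", "", as.character(s36$strata)),
    months = eval_months, survival = s36$surv)
  list(curves = curves, logrank_p = p, chisq = sd_$chisq,
       survival_at = survival_at)
}
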