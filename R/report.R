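#' Evaluate a fitted model suite on both cohorts
#'
#' Produces the full comparison report: per model and cohort the AUC with
#' DeLong confidence interval and the threshold metrics (F1, accuracy,
#' sensitivity, specificity, bootstrap CIs) at each model's training-cohort
#' Youden cutoff; pairwise DeLong tests between models within each cohort;
#' decision curves; Hosmer-Lemeshow calibration of the designated optimal
#' model; and, when the clinical table carries disease-free survival,
#' Kaplan-Meier curves with the log-rank test and 3-year DFS of the
#' predicted MSI vs MSS groups (stratified at the optimal model's
#' training-cohort Youden cutoff).
#'
#' @param suite a `model_suite` from [build_model_suite()].
#' @param clinical the clinicoradiological table used to build the suite
#'   (needs `dfs_time`/`dfs_event` for the survival section).
#' @param optimal_model model used for calibration and survival
#'   stratification (default `"subregion_clinical"`).
#' @param n_boot bootstrap replicates for metric CIs.
#' @param seed integer seed for the bootstrap.
#' @return object of class `evaluation_report` with elements `metrics`,
#'   `delong`, `decision_curves`, `calibration`, `cutoffs`, `survival`.
#' @export
evaluate_model_suite <- function(suite, clinical,
                                 optimal_model = "subregion_clinical",
                                 n_boot = 2000, seed = 1L) {
  stopifnot(inherits(suite, "model_suite"))
  sc <- suite$scores
  models <- unique(sc$model)
  cohorts <- levels(factor(sc$cohort))

  cutoffs <- purrr::map_dfr(models, function(m) {
    tr <- sc[sc$model == m & sc$cohort == "training", ]
    yc <- youden_cutoff(tr$score, tr$msi)
    tibble::tibble(model = m, cutoff = yc$cutoff, youden = yc$youden)
  })

  metrics <- purrr::map_dfr(models, function(m) {
    purrr::map_dfr(cohorts, function(ch) {
      d <- sc[sc$model == m & sc$cohort == ch, ]
      a <- roc_auc_ci(d$score, d$msi)
      ct <- cutoffs$cutoff[cutoffs$model == m]
      cm <- classification_metrics(d$score, d$msi, ct, n_boot = n_boot,
                                   seed = derive_seed(seed, paste(m, ch)))
      dplyr::bind_rows(
        tibble::tibble(metric = "auc", value = a$auc, ci_low = a$ci_low,
                       ci_high = a$ci_high),
        cm) |>
        dplyr::mutate(model = m, cohort = ch, .before = 1)
    })
  })

  pairs <- utils::combn(models, 2, simplify = FALSE)
  delong <- purrr::map_dfr(cohorts, function(ch) {
    purrr::map_dfr(pairs, function(pr) {
      da <- sc[sc$model == pr[1] & sc$cohort == ch, ]
      db <- sc[sc$model == pr[2] & sc$cohort == ch, ]
      db <- db[match(da$patient_id, db$patient_id), ]
      dt <- delong_test(da$score, db$score, da$msi)
      tibble::tibble(cohort = ch, model_a = pr[1], model_b = pr[2],
                     auc_a = dt$auc_a, auc_b = dt$auc_b, p_value = dt$p_value)
    })
  })

  dca <- purrr::map_dfr(models, function(m) {
    purrr::map_dfr(cohorts, function(ch) {
      d <- sc[sc$model == m & sc$cohort == ch, ]
      dplyr::mutate(decision_curve(d$score, d$msi), model = m, cohort = ch,
                    .before = 1)
    })
  })

  calib <- purrr::map_dfr(cohorts, function(ch) {
    d <- sc[sc$model == optimal_model & sc$cohort == ch, ]
    if (nrow(d) < 20) return(tibble::tibble())
    hl <- tryCatch(hosmer_lemeshow(d$score, d$msi),
                   error = function(e) NULL)   # e.g. near-constant scores
    if (is.null(hl)) tibble::tibble() else dplyr::mutate(hl, cohort = ch, .before = 1)
  })

  surv <- NULL
  if (all(c("dfs_time", "dfs_event") %in% names(clinical))) {
    ct <- cutoffs$cutoff[cutoffs$model == optimal_model]
    d <- sc[sc$model == optimal_model, ] |>
      dplyr::left_join(clinical[, c("patient_id", "dfs_time", "dfs_event")],
                       by = "patient_id") |>
      dplyr::mutate(predicted = ifelse(.data$score >= ct, "predicted_MSI",
                                       "predicted_MSS"))
    surv <- lapply(cohorts, function(ch) {
      dd <- d[d$cohort == ch, ]
      if (length(unique(dd$predicted)) < 2) return(NULL)
      km <- km_logrank(dd$dfs_time, dd$dfs_event, dd$predicted)
      km$cohort <- ch
      km
    })
    names(surv) <- cohorts
  }

  structure(list(metrics = metrics, delong = delong, decision_curves = dca,
                 calibration = calib, cutoffs = cutoffs, survival = surv,
                 optimal_model = optimal_model),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  auc <- x$metrics[x$metrics$metric == "auc", c("model", "cohort", "value")]
  print(tidyr::pivot_wider(auc, names_from = "cohort", values_from = "value"))
  invisible(x)
}

#' Table of per-model performance in the layout of a publication table
#'
#' @param report an `evaluation_report`.
#' @return wide tibble: one row per model x cohort, columns per metric with
#'   95% CIs.
#' @export
report_table <- function(report) {
  report$metrics |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f-%.2f)", .data$value, .data$ci_low,
                                 .data$ci_high)) |>
    dplyr::select("model", "cohort", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
}
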