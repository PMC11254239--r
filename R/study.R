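#' Replicated subregion-vs-classical model comparison
#'
#' Monte-Carlo design for the package's central comparison: a pool of
#' phantom patients is simulated once (imaging processed through the
#' habitat-clustering and feature-extraction stages). Each replicate draws a
#' stratified training cohort from the pool, reruns the feature-selection
#' cascade and all model fits on those training patients only, and evaluates
#' every model's AUC on the remaining pool patients, which act as that
#' replicate's held-out cohort. Holding the evaluation set large keeps the
#' per-replicate AUC comparison from being dominated by test-sampling noise,
#' so the replicate distribution reflects training variability and the
#' true model ordering. Sharing the simulated pool across replicates keeps
#' the study tractable on one CPU.
#'
#' @param n_pool patients simulated in the pool.
#' @param n_train training patients drawn (stratified, without replacement)
#'   per replicate; the other `n_pool - n_train` patients form the held-out
#'   evaluation cohort.
#' @param n_replicates number of replicates.
#' @param phantom a [phantom_params()] (set `msi_effect` mean shift and
#'   texture multipliers to 0/1 for a null study).
#' @param msi_prevalence MSI fraction of the pool.
#' @param model a [model_config()].
#' @param alpha_univariate univariate screen threshold.
#' @param seed master seed.
#' @param pool optional prebuilt pool from [simulate_feature_pool()]; when
#'   supplied, `n_pool`, `phantom` and `msi_prevalence` are ignored.
#' @param eval_pool optional second, independently simulated pool used as the
#'   held-out cohort of every replicate. Without it, each replicate is
#'   evaluated on the non-training remainder of `pool`; with it, evaluation
#'   patients are fully disjoint from the training pool, which removes the
#'   finite-pool coupling between the drawn and the left-out minority-class
#'   patients (relevant for null-calibration studies, where that coupling
#'   biases the held-out AUC below one half).
#' @return list with `replicates` (tibble: replicate, model, cohort, auc),
#'   `pool_clinical`, and `win_rate` (fraction of replicates with held-out
#'   subregion AUC above classical AUC).
#' @export
model_comparison_study <- function(n_pool = 120, n_train = 48,
                                   n_replicates = 50,
                                   phantom = phantom_params(grid_shape = c(20, 20, 16)),
                                   msi_prevalence = 53 / 475,
                                   model = model_config(
                                     l1_ratio = c(0, 0.5, 1),
                                     C = 10^seq(-2, 1, length.out = 4),
                                     n_folds = 5),
                                   alpha_univariate = 0.05,
                                   seed = 1L, pool = NULL, eval_pool = NULL) {
  if (is.null(pool)) pool <- simulate_feature_pool(n_pool, phantom,
                                                   msi_prevalence, seed)
  n_pool <- nrow(pool$clinical)
  stopifnot(n_train < n_pool || !is.null(eval_pool))
  if (!is.null(eval_pool)) {
    # keep the two pools' patient ids disjoint
    rename <- function(df) dplyr::mutate(df, patient_id = paste0("EV-", .data$patient_id))
    eval_pool$clinical <- rename(eval_pool$clinical)
    eval_pool$subregion_features <- rename(eval_pool$subregion_features)
    eval_pool$classical_features <- rename(eval_pool$classical_features)
  }
  pos <- pool$clinical$patient_id[pool$clinical$msi == 1]
  neg <- pool$clinical$patient_id[pool$clinical$msi == 0]
  n_pos_train <- max(3L, round(n_train * length(pos) / n_pool))
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, paste0("rep", r))
    train_ids <- with_seed(rs, c(sample(pos, min(n_pos_train, length(pos) - 2L)),
                                 sample(neg, n_train - min(n_pos_train,
                                                           length(pos) - 2L))))
    if (is.null(eval_pool)) {
      clin <- pool$clinical
      sub_f <- pool$subregion_features
      cls_f <- pool$classical_features
    } else {
      keep <- pool$clinical$patient_id %in% train_ids
      clin <- dplyr::bind_rows(pool$clinical[keep, ], eval_pool$clinical)
      sub_f <- dplyr::bind_rows(
        pool$subregion_features[pool$subregion_features$patient_id %in% train_ids, ],
        eval_pool$subregion_features)
      cls_f <- dplyr::bind_rows(
        pool$classical_features[pool$classical_features$patient_id %in% train_ids, ],
        eval_pool$classical_features)
    }
    clin$cohort <- factor(ifelse(clin$patient_id %in% train_ids,
                                 "training", "external_test"),
                          levels = c("training", "external_test"))
    suite <- tryCatch(
      suppressWarnings(build_model_suite(
        sub_f, cls_f, clin,
        config = model, seed = derive_seed(rs, "models"),
        alpha_univariate = alpha_univariate)),
      error = function(e) NULL)
    if (is.null(suite)) next
    auc_tbl <- suite$scores |>
      dplyr::group_by(.data$model, .data$cohort) |>
      dplyr::summarise(auc = auc_mw(.data$score, .data$msi), .groups = "drop") |>
      dplyr::mutate(replicate = r)
    reps[[r]] <- auc_tbl
  }
  replicates <- dplyr::bind_rows(reps)
  test_auc <- replicates[replicates$cohort == "external_test", ]
  wide <- tidyr::pivot_wider(test_auc[, c("replicate", "model", "auc")],
                             names_from = "model", values_from = "auc")
  win_rate <- mean(wide$subregion > wide$classical, na.rm = TRUE)
  list(replicates = replicates, pool_clinical = pool$clinical,
       win_rate = win_rate)
}

#' Simulate a patient pool through the imaging stages
#'
#' Generates phantoms, preprocesses them, builds subregion maps and extracts
#' the subregion and whole-tumor feature tables — everything upstream of the
#' (training-dependent) selection and modelling stages.
#'
#' @inheritParams model_comparison_study
#' @param n_pool patients to simulate.
#' @param seed integer seed.
#' @return list with `clinical`, `subregion_features`, `classical_features`,
#'   `V` (per-patient subregion counts).
#' @export
simulate_feature_pool <- function(n_pool, phantom = phantom_params(),
                                  msi_prevalence = 53 / 475, seed = 1L) {
  cohort <- generate_cohort(n_pool, msi_prevalence, params = phantom, seed = seed)
  pre_cfg <- preprocess_config(bias_correction = phantom$bias_field_amplitude > 0)
  sub_rows <- cls_rows <- list()
  Vs <- integer(0)
  for (pid in cohort$clinical$patient_id) {
    pre <- preprocess_volumes(cohort$imaging[[pid]]$volumes, pre_cfg)
    hc <- habitat_config(restarts = 5,
                         seed = derive_seed(seed, paste0("habitat-", pid)))
    map <- suppressWarnings(build_subregion_map(pre, hc))
    Vs[pid] <- map$V
    sub_rows[[pid]] <- extract_feature_table(pre, map$labels, patient_id = pid)
    cls_rows[[pid]] <- extract_feature_table(pre, pre$tumor_mask, patient_id = pid)
  }
  list(clinical = cohort$clinical,
       subregion_features = dplyr::bind_rows(sub_rows),
       classical_features = dplyr::bind_rows(cls_rows),
       V = Vs)
}
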