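# The five MSI prediction models: elastic-net logistic regression with
# grid-searched (l1_ratio, C), balanced class weights and stratified
# (optionally patient-grouped) cross-validation; per-subregion rad-scores
# aggregated to the patient level by their arithmetic mean.

#' Model-fitting configuration
#'
#' @param l1_ratio grid of elastic-net mixing values (0 = ridge, 1 = lasso).
#' @param C grid of inverse regularization strengths.
#' @param n_folds cross-validation folds (default 10).
#' @param tol convergence threshold of the coordinate-descent solver.
#' @param max_iter iteration cap of the solver.
#' @return list of class `model_config`.
#' @export
model_config <- function(l1_ratio = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1),
                         C = 10^seq(-3, 2, length.out = 7),
                         n_folds = 10, tol = 1e-7, max_iter = 1e5) {
  structure(list(l1_ratio = l1_ratio, C = C, n_folds = as.integer(n_folds),
                 tol = tol, max_iter = max_iter), class = "model_config")
}

#' Elastic-net logistic regression with grid-searched penalty
#'
#' Fits an L1/L2-penalized logistic regression for every point of the
#' `(l1_ratio, C)` grid, scoring each point by the mean validation AUC over
#' stratified cross-validation folds (grouped by `groups` when given, so
#' that all rows of one patient stay in one fold). Class weights are inverse
#' to the class frequencies ("balanced"). The best point — ties resolved
#' toward stronger regularization (smaller C, then larger l1_ratio) — is
#' refitted on the full training data. The penalty parameterization matches
#' the common machine-learning convention: the glmnet penalty is
#' `lambda = 1 / (C n)` at mixing `alpha = l1_ratio`.
#'
#' @param X numeric matrix of standardized features.
#' @param y binary outcome (0/1).
#' @param config a [model_config()].
#' @param seed integer seed (fold assignment).
#' @param groups optional grouping vector (same length as `y`).
#' @return object of class `enet_logistic` with elements `intercept`,
#'   `coefficients` (named), `l1_ratio`, `C`, `lambda`, `cv_results`
#'   (tibble over the grid), `features`.
#' @export
fit_elasticnet_logistic <- function(X, y, config = model_config(), seed = 1L,
                                    groups = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(unique(y)) == 2)
  single_col <- ncol(X) == 1
  if (single_col) X <- cbind(X, .zero. = 0)  # glmnet needs >= 2 columns
  n <- nrow(X)
  w <- n / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))  # balanced
  n_minor <- min(sum(y == 1), sum(y == 0))
  n_folds <- max(2L, min(config$n_folds, n_minor))
  folds <- if (is.null(groups)) {
    stratified_folds(y, n_folds, derive_seed(seed, "enet-folds"))
  } else {
    grouped_folds(groups, y, n_folds, derive_seed(seed, "enet-folds"))
  }
  usable <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    min(table(factor(y[tr], levels = c(0, 1)))) >= 2 &&
      length(unique(y[!tr])) == 2
  }, logical(1))
  grid <- expand.grid(l1_ratio = config$l1_ratio, C = config$C)
  cv_auc <- rep(NA_real_, nrow(grid))
  if (any(usable)) {
    for (gidx in seq_len(nrow(grid))) {
      alpha <- grid$l1_ratio[gidx]; C <- grid$C[gidx]
      aucs <- c()
      ok <- TRUE
      for (f in sort(unique(folds))[usable]) {
        tr <- folds != f
        p <- tryCatch({
          fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                                alpha = alpha, lambda = 1 / (C * sum(tr)),
                                weights = w[tr], standardize = FALSE,
                                thresh = config$tol, maxit = config$max_iter)
          stats::predict(fit, X[!tr, , drop = FALSE], type = "response")[, 1]
        }, error = function(e) NULL)
        if (is.null(p)) { ok <- FALSE; break }
        aucs <- c(aucs, auc_mw(p, y[!tr]))
      }
      if (ok && length(aucs)) cv_auc[gidx] <- mean(aucs, na.rm = TRUE)
    }
  }
  if (all(is.na(cv_auc))) {
    # too few minority observations for any valid resampling split: fall back
    # to the most regularized grid point that fits on the full data
    warning("cross-validation infeasible; using the most regularized grid point")
    ord <- order(grid$C, -grid$l1_ratio)
    best <- NULL
    for (gidx in ord) {
      fit <- tryCatch(
        glmnet::glmnet(X, y, family = "binomial", alpha = grid$l1_ratio[gidx],
                       lambda = 1 / (grid$C[gidx] * n), weights = w,
                       standardize = FALSE, thresh = config$tol,
                       maxit = config$max_iter),
        error = function(e) NULL)
      if (!is.null(fit)) { best <- gidx; break }
    }
    if (is.null(best)) stop("every grid point failed to converge")
  } else {
    best_score <- max(cv_auc, na.rm = TRUE)
    cand <- which(!is.na(cv_auc) & cv_auc >= best_score - 1e-12)
    cand <- cand[order(grid$C[cand], -grid$l1_ratio[cand])]  # strongest penalty
    best <- cand[1]
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = grid$l1_ratio[best],
                        lambda = 1 / (grid$C[best] * n), weights = w,
                        standardize = FALSE, thresh = config$tol,
                        maxit = config$max_iter)
  beta <- as.matrix(stats::coef(fit))[, 1]
  if (single_col) beta <- beta[names(beta) != ".zero."]
  structure(list(intercept = unname(beta[1]),
                 coefficients = beta[-1],
                 l1_ratio = grid$l1_ratio[best], C = grid$C[best],
                 lambda = 1 / (grid$C[best] * n),
                 cv_results = tibble::tibble(l1_ratio = grid$l1_ratio,
                                             C = grid$C, mean_cv_auc = cv_auc),
                 features = setdiff(colnames(X), ".zero.")),
            class = "enet_logistic")
}

#' Score patients (or subregions) with a fitted model
#'
#' Probability-scale scores `plogis(b0 + X b)`; all training features must be
#' present in `newdata`.
#'
#' @param model an `enet_logistic` (or intercept-only fallback) model.
#' @param newdata data frame / matrix containing the model's features.
#' @return numeric vector of probabilities.
#' @export
score_patients <- function(model, newdata) {
  if (inherits(model, "intercept_model")) {
    return(rep(stats::plogis(model$intercept), nrow(as.data.frame(newdata))))
  }
  stopifnot(inherits(model, "enet_logistic"))
  nd <- as.data.frame(newdata)
  missing_cols <- setdiff(model$features, names(nd))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  Xm <- as.matrix(nd[, model$features, drop = FALSE])
  as.numeric(stats::plogis(model$intercept + Xm %*% model$coefficients))
}

#' Aggregate subregion rad-scores to one patient-level score
#'
#' The patient-level subregion rad-score is the arithmetic mean of the
#' patient's V subregion scores: `sum_i rad_score_i / V`.
#'
#' @param region_scores numeric vector of per-subregion scores (length V >= 1).
#' @return the patient-level score.
#' @export
aggregate_subregion_score <- function(region_scores) {
  if (length(region_scores) == 0) stop("no subregion scores supplied")
  stopifnot(all(is.finite(region_scores)))
  mean(region_scores)
}

# fit an elastic net when the data can support one, else intercept-only
fit_or_intercept <- function(X, y, config, seed, groups = NULL) {
  if (is.null(dim(X)) || ncol(X) == 0 ||
      min(table(factor(y, levels = c(0, 1)))) < 2) {
    warning("degenerate training block; falling back to intercept-only model")
    return(intercept_model(y))
  }
  fit_elasticnet_logistic(X, y, config, seed = seed, groups = groups)
}

# intercept-only fallback when a block selects no features
intercept_model <- function(y) {
  structure(list(intercept = stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6)),
                 features = character(0)), class = "intercept_model")
}

guard_no_test_rows <- function(patient_ids, test_ids, stage) {
  leaked <- intersect(unique(patient_ids), test_ids)
  if (length(leaked)) {
    stop("leakage guard: external-test patients reached the ", stage,
         " stage: ", paste(utils::head(leaked, 5), collapse = ", "))
  }
}

standardize_block <- function(df, feature_cols, train_rows) {
  mu <- vapply(df[train_rows, feature_cols, drop = FALSE], mean, numeric(1))
  sd_ <- vapply(df[train_rows, feature_cols, drop = FALSE], stats::sd, numeric(1))
  keep <- feature_cols[sd_ > 0]
  out <- df
  for (f in keep) out[[f]] <- (df[[f]] - mu[f]) / sd_[f]
  list(data = out, features = keep, center = mu[keep], scale = sd_[keep])
}

clinical_design <- function(clinical) {
  vars <- c("age", "sex", "cea", "ca19_9", "location", "t_stage", "n_stage")
  vars <- intersect(vars, names(clinical))
  mm <- stats::model.matrix(stats::reformulate(vars),
                            data = as.data.frame(clinical[, vars]))[, -1, drop = FALSE]
  tibble::as_tibble(as.data.frame(mm))
}

#' Fit the five MSI prediction models
#'
#' Trains, on the training cohort only, the clinicoradiological model, the
#' subregion radiomics model (rows = subregions, cross-validation folds
#' grouped by patient; patient score = mean of the subregion scores), the
#' classical (whole-tumor) radiomics model, the subregion-clinicoradiological
#' model (patient-level subregion rad-score + selected clinicoradiological
#' variables) and the combined model (both rad-scores + clinicoradiological
#' variables). Feature standardization, selection, penalty tuning and
#' fitting use training rows exclusively; a leakage guard raises an error if
#' an external-test patient reaches any fitting stage.
#'
#' @param subregion_features tibble from [extract_feature_table()] over
#'   subregion label maps (all patients; rows = subregions).
#' @param classical_features tibble over whole-tumor masks (rows = patients).
#' @param clinical clinicoradiological table with `patient_id`, covariates,
#'   `msi`, `cohort`.
#' @param config a [model_config()].
#' @param seed integer seed.
#' @param selection_seed seed of the selection cascade (defaults to `seed`).
#' @param icc_kept optional reproducibility-filtered feature whitelist.
#' @param alpha_univariate univariate screen threshold for radiomic blocks.
#' @return object of class `model_suite`: `models` (named list of 5),
#'   `scores` (long tibble patient x model), `selection` (traces),
#'   `scalers`, `config`.
#' @export
build_model_suite <- function(subregion_features, classical_features, clinical,
                              config = model_config(), seed = 1L,
                              selection_seed = NULL, icc_kept = NULL,
                              alpha_univariate = 0.05) {
  selection_seed <- selection_seed %||% seed
  stopifnot(all(c("patient_id", "msi", "cohort") %in% names(clinical)))
  train_ids <- clinical$patient_id[clinical$cohort == "training"]
  test_ids <- setdiff(clinical$patient_id, train_ids)
  feat_cols <- setdiff(names(classical_features),
                       c("patient_id", "region_id", "n_voxels"))

  msi_of <- stats::setNames(clinical$msi, clinical$patient_id)

  # ---- subregion block (rows = subregions)
  sub <- subregion_features
  sub_train <- sub$patient_id %in% train_ids
  sub_std <- standardize_block(sub, feat_cols, sub_train)
  guard_no_test_rows(sub$patient_id[sub_train], test_ids, "subregion selection")
  sel_sub <- select_radiomic_features(
    sub_std$data[sub_train, sub_std$features, drop = FALSE],
    msi_of[sub$patient_id[sub_train]], icc_kept = icc_kept,
    alpha = alpha_univariate, n_folds = config$n_folds,
    seed = derive_seed(selection_seed, "sel-sub"))
  m_sub <- if (length(sel_sub$kept)) {
    fit_or_intercept(
      as.matrix(sub_std$data[sub_train, sel_sub$kept, drop = FALSE]),
      msi_of[sub$patient_id[sub_train]], config,
      seed = derive_seed(seed, "fit-sub"),
      groups = sub$patient_id[sub_train])
  } else intercept_model(msi_of[sub$patient_id[sub_train]])
  region_scores <- score_patients(m_sub, sub_std$data)
  rad_sub <- tibble::tibble(patient_id = sub$patient_id, score = region_scores) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(rad_score_subregion = aggregate_subregion_score(.data$score),
                     V = dplyr::n(), .groups = "drop")

  # ---- classical block (rows = patients)
  cls <- classical_features
  cls_train <- cls$patient_id %in% train_ids
  cls_std <- standardize_block(cls, feat_cols, cls_train)
  sel_cls <- select_radiomic_features(
    cls_std$data[cls_train, cls_std$features, drop = FALSE],
    msi_of[cls$patient_id[cls_train]], icc_kept = icc_kept,
    alpha = alpha_univariate, n_folds = config$n_folds,
    seed = derive_seed(selection_seed, "sel-cls"))
  m_cls <- if (length(sel_cls$kept)) {
    fit_or_intercept(
      as.matrix(cls_std$data[cls_train, sel_cls$kept, drop = FALSE]),
      msi_of[cls$patient_id[cls_train]], config,
      seed = derive_seed(seed, "fit-cls"))
  } else intercept_model(msi_of[cls$patient_id[cls_train]])
  rad_cls <- tibble::tibble(patient_id = cls$patient_id,
                            rad_score_classical = score_patients(m_cls, cls_std$data))

  # ---- clinicoradiological block
  cl_train_rows <- clinical$cohort == "training"
  sel_clin <- select_clinical_variables(
    as.data.frame(clinical[cl_train_rows,
                           intersect(c("age", "sex", "cea", "ca19_9", "location",
                                       "t_stage", "n_stage"), names(clinical))]),
    clinical$msi[cl_train_rows])
  design <- clinical_design(clinical)
  clin_cols <- if (length(sel_clin$kept)) {
    keep_terms <- unlist(lapply(sel_clin$kept, function(v) {
      grep(paste0("^", v), names(design), value = TRUE)
    }))
    unique(keep_terms)
  } else character(0)

  patient_tbl <- clinical |>
    dplyr::select("patient_id", "msi", "cohort") |>
    dplyr::bind_cols(design) |>
    dplyr::left_join(rad_sub, by = "patient_id") |>
    dplyr::left_join(rad_cls, by = "patient_id")

  fit_patient_model <- function(cols, label) {
    if (length(cols) == 0) {
      return(list(model = intercept_model(patient_tbl$msi[cl_train_rows]),
                  scaler = NULL))
    }
    std <- standardize_block(patient_tbl, cols, cl_train_rows)
    guard_no_test_rows(patient_tbl$patient_id[cl_train_rows], test_ids, label)
    m <- fit_or_intercept(
      as.matrix(std$data[cl_train_rows, std$features, drop = FALSE]),
      patient_tbl$msi[cl_train_rows], config,
      seed = derive_seed(seed, paste0("fit-", label)))
    list(model = m, scaler = std, data = std$data)
  }

  f_clin <- fit_patient_model(clin_cols, "clinicoradiological")
  f_subcl <- fit_patient_model(c("rad_score_subregion", clin_cols),
                               "subregion_clinical")
  f_comb <- fit_patient_model(c("rad_score_subregion", "rad_score_classical",
                                clin_cols), "combined")

  models <- list(clinicoradiological = f_clin$model,
                 subregion = m_sub,
                 classical = m_cls,
                 subregion_clinical = f_subcl$model,
                 combined = f_comb$model)

  score_with <- function(f) {
    if (is.null(f$scaler)) score_patients(f$model, patient_tbl) else
      score_patients(f$model, f$data)
  }
  scores <- dplyr::bind_rows(
    tibble::tibble(patient_id = patient_tbl$patient_id,
                   model = "clinicoradiological", score = score_with(f_clin)),
    rad_sub |> dplyr::transmute(.data$patient_id, model = "subregion",
                                score = .data$rad_score_subregion),
    rad_cls |> dplyr::transmute(.data$patient_id, model = "classical",
                                score = .data$rad_score_classical),
    tibble::tibble(patient_id = patient_tbl$patient_id,
                   model = "subregion_clinical", score = score_with(f_subcl)),
    tibble::tibble(patient_id = patient_tbl$patient_id,
                   model = "combined", score = score_with(f_comb))) |>
    dplyr::left_join(clinical |> dplyr::select("patient_id", "msi", "cohort"),
                     by = "patient_id")

  structure(list(models = models, scores = scores,
                 selection = list(subregion = sel_sub, classical = sel_cls,
                                  clinical = sel_clin),
                 rad_scores = dplyr::left_join(rad_sub, rad_cls, by = "patient_id"),
                 scalers = list(subregion = sub_std[c("features", "center", "scale")],
                                classical = cls_std[c("features", "center", "scale")]),
                 config = config, seed = seed),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite> 5 models:", paste(names(x$models), collapse = ", "), "\n")
  nf <- vapply(x$models, function(m) length(m$features), integer(1))
  cat("  features per model:", paste(names(nf), nf, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted elastic-net model
#'
#' @param x an `enet_logistic`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`.
#' @export
tidy.enet_logistic <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.enet_logistic
#' @export
glance.enet_logistic <- function(x, ...) {
  tibble::tibble(l1_ratio = x$l1_ratio, C = x$C, lambda = x$lambda,
                 n_features = length(x$features),
                 n_nonzero = sum(x$coefficients != 0),
                 best_cv_auc = max(x$cv_results$mean_cv_auc, na.rm = TRUE))
}

#' Tidy all models of a suite
#'
#' @param x a `model_suite`.
#' @param ... unused.
#' @return tibble with `model`, `term`, `estimate`.
#' @export
tidy.model_suite <- function(x, ...) {
  purrr::map_dfr(names(x$models), function(nm) {
    m <- x$models[[nm]]
    if (inherits(m, "intercept_model")) {
      tibble::tibble(model = nm, term = "(Intercept)", estimate = m$intercept)
    } else {
      dplyr::mutate(tidy(m), model = nm, .before = 1)
    }
  })
}

#' @rdname tidy.model_suite
#' @export
glance.model_suite <- function(x, ...) {
  purrr::map_dfr(names(x$models), function(nm) {
    m <- x$models[[nm]]
    tibble::tibble(model = nm,
                   n_features = length(m$features),
                   intercept_only = inherits(m, "intercept_model"))
  })
}
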