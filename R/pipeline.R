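#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end analysis. Unknown
#' arguments are rejected (R's argument matching), so a config file with a
#' misspelled or unsupported key fails loudly.
#'
#' @param n_patients cohort size of the simulation.
#' @param msi_prevalence expected MSI fraction.
#' @param phantom a [phantom_params()].
#' @param preprocess a [preprocess_config()].
#' @param habitat a [habitat_config()].
#' @param model a [model_config()].
#' @param alpha_univariate univariate screen threshold of the radiomic
#'   cascade.
#' @param icc_subjects number of training patients used for the
#'   reproducibility (ICC) filter; 0 disables the filter.
#' @param icc_threshold ICC cutoff.
#' @param n_boot bootstrap replicates in the evaluation.
#' @param write_nifti write per-patient NIfTI volumes into the run directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 60, msi_prevalence = 53 / 475,
                            phantom = phantom_params(),
                            preprocess = preprocess_config(bias_correction = FALSE),
                            habitat = habitat_config(),
                            model = model_config(),
                            alpha_univariate = 0.05,
                            icc_subjects = 0, icc_threshold = 0.75,
                            n_boot = 500, write_nifti = FALSE, seed = 1L) {
  structure(list(n_patients = n_patients, msi_prevalence = msi_prevalence,
                 phantom = phantom, preprocess = preprocess, habitat = habitat,
                 model = model, alpha_univariate = alpha_univariate,
                 icc_subjects = as.integer(icc_subjects),
                 icc_threshold = icc_threshold, n_boot = n_boot,
                 write_nifti = isTRUE(write_nifti), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full habitat-radiomics analysis on a simulated cohort
#'
#' Executes the stages in their fixed order: simulate the phantom cohort,
#' preprocess every patient, build the subregion label maps, extract
#' subregion and whole-tumor (classical) feature tables, optionally compute
#' the reproducibility (ICC) feature filter from simulated second-rater and
#' repeat segmentations, run the selection cascade and fit the five models,
#' and evaluate them. With an `outdir`, all tabular artifacts are written as
#' CSV/JSON together with a manifest (config echo, seed, MD5 content hashes),
#' so a rerun with the same config and seed reproduces the artifacts
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created; must not already
#'   contain a manifest).
#' @return object of class `habitat_run`: `clinical`, `maps` (per-patient
#'   subregion maps), `subregion_features`, `classical_features`, `suite`,
#'   `report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- generate_cohort(config$n_patients, config$msi_prevalence,
                            params = config$phantom, seed = seed)
  clinical <- cohort$clinical

  pre_list <- lapply(cohort$imaging, function(p) {
    preprocess_volumes(p$volumes, config$preprocess)
  })

  maps <- list()
  sub_rows <- list()
  cls_rows <- list()
  for (pid in clinical$patient_id) {
    hc <- config$habitat
    hc$seed <- derive_seed(seed, paste0("habitat-", pid))
    maps[[pid]] <- build_subregion_map(pre_list[[pid]], hc)
    sub_rows[[pid]] <- extract_feature_table(pre_list[[pid]], maps[[pid]]$labels,
                                             patient_id = pid)
    cls_rows[[pid]] <- extract_feature_table(pre_list[[pid]],
                                             pre_list[[pid]]$tumor_mask,
                                             patient_id = pid)
  }
  subregion_features <- dplyr::bind_rows(sub_rows)
  classical_features <- dplyr::bind_rows(cls_rows)

  icc_kept <- NULL
  if (config$icc_subjects > 0) {
    train_ids <- clinical$patient_id[clinical$cohort == "training"]
    icc_ids <- utils::head(train_ids, config$icc_subjects)
    feat_cols <- setdiff(names(classical_features),
                         c("patient_id", "region_id", "n_voxels"))
    get_feats <- function(pid, mask) {
      as.data.frame(t(extract_region_features(pre_list[[pid]],
                                              array(as.integer(mask > 0), dim(mask)), 1L)))
    }
    f1 <- f2 <- f3 <- list()
    for (pid in icc_ids) {
      mask <- pre_list[[pid]]$tumor_mask
      f1[[pid]] <- get_feats(pid, mask)
      f2[[pid]] <- get_feats(pid, generate_rater_perturbation(
        mask, seed = derive_seed(seed, paste0("rater2-", pid)), flip_prob = 0.10))
      f3[[pid]] <- get_feats(pid, generate_rater_perturbation(
        mask, seed = derive_seed(seed, paste0("repeat-", pid)), flip_prob = 0.05))
    }
    icc_res <- icc_filter(dplyr::bind_rows(f1)[, feat_cols],
                          dplyr::bind_rows(f2)[, feat_cols],
                          dplyr::bind_rows(f3)[, feat_cols],
                          threshold = config$icc_threshold)
    icc_kept <- icc_res$kept
  }

  suite <- build_model_suite(subregion_features, classical_features, clinical,
                             config = config$model,
                             seed = derive_seed(seed, "models"),
                             icc_kept = icc_kept,
                             alpha_univariate = config$alpha_univariate)
  report <- evaluate_model_suite(suite, clinical, n_boot = config$n_boot,
                                 seed = derive_seed(seed, "eval"))

  run <- structure(list(clinical = clinical, maps = maps,
                        subregion_features = subregion_features,
                        classical_features = classical_features,
                        icc_kept = icc_kept, suite = suite, report = report,
                        config = config),
                   class = "habitat_run")
  if (!is.null(outdir)) write_run(run, outdir, imaging = cohort$imaging)
  run
}

#' @export
print.habitat_run <- function(x, ...) {
  cat("<habitat_run>", nrow(x$clinical), "patients;",
      sum(x$clinical$cohort == "training"), "training /",
      sum(x$clinical$cohort == "external_test"), "external test\n")
  print(x$report)
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' Writes the clinicoradiological table, both feature tables, per-patient
#' scores, the performance table and selection summaries as CSV/JSON under
#' `outdir`, plus a `manifest.json` recording the configuration, the master
#' seed and the MD5 hash of every artifact. Optionally writes each patient's
#' volumes, mask and subregion label map as NIfTI.
#'
#' @param run a `habitat_run`.
#' @param outdir output directory; refuses to overwrite an existing manifest.
#' @param imaging optional imaging list (from [generate_cohort()]) for NIfTI
#'   export.
#' @return the manifest, invisibly.
#' @export
write_run <- function(run, outdir, imaging = NULL) {
  if (file.exists(file.path(outdir, "manifest.json"))) {
    stop("outdir already contains a run manifest; refusing to overwrite")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    w(run$clinical, "clinical.csv"),
    w(run$subregion_features, "subregion_features.csv"),
    w(run$classical_features, "classical_features.csv"),
    w(run$suite$scores, "scores.csv"),
    w(run$report$metrics, "metrics.csv"),
    w(report_table(run$report), "performance_table.csv"),
    w(run$report$delong, "delong.csv"),
    w(run$report$decision_curves, "decision_curves.csv"))
  sel_path <- file.path(outdir, "selection.json")
  jsonlite::write_json(
    list(subregion = run$suite$selection$subregion$kept,
         classical = run$suite$selection$classical$kept,
         clinical = run$suite$selection$clinical$kept,
         icc_kept = run$icc_kept),
    sel_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, sel_path)
  if (run$config$write_nifti && !is.null(imaging)) {
    for (pid in names(imaging)) {
      prefix <- file.path(outdir, "nifti", pid)
      write_volume_set(imaging[[pid]]$volumes, prefix)
      write_subregion_map(run$maps[[pid]], prefix,
                          imaging[[pid]]$volumes$voxel_spacing_mm)
    }
  }
  manifest <- list(
    seed = run$config$seed,
    n_patients = run$config$n_patients,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    artifacts = lapply(stats::setNames(paths, basename(paths)),
                       function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
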