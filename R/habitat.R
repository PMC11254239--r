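#' Secondary radiomic features of the preliminary clusters
#'
#' For clustering (not for prediction), each preliminary FCM cluster is
#' described by 18 first-order + 74 texture features per sequence — no shape
#' block — giving 92 x 4 = 368 columns. Clusters smaller than `min_voxels`
#' are merged into the nearest neighbouring cluster (by intensity centroid
#' distance) with a warning, because texture matrices are unstable on tiny
#' regions.
#'
#' @param pre a `preprocessed_volumes` object.
#' @param prelim_labels integer label volume of preliminary clusters.
#' @param min_voxels minimum cluster size (default 10).
#' @return list with `features` (matrix, rows = surviving clusters, 368
#'   columns named `<sequence>_<family>_<name>`) and `labels` (the possibly
#'   merged label volume, labels compacted to `1..n`).
#' @export
extract_secondary_features <- function(pre, prelim_labels, min_voxels = 10) {
  stopifnot(inherits(pre, "preprocessed_volumes"))
  labels <- prelim_labels
  # merge clusters below min_voxels into their nearest (centroid) neighbour
  repeat {
    ids <- sort(setdiff(unique(as.vector(labels)), 0))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(r) sum(labels == r), numeric(1))
    if (all(sizes >= min_voxels)) break
    cent <- t(vapply(ids, function(r) {
      vapply(SEQUENCE_NAMES, function(nm) mean(pre$sequences[[nm]][labels == r]),
             numeric(1))
    }, numeric(length(SEQUENCE_NAMES))))
    small <- ids[which.min(sizes)]
    others <- setdiff(ids, small)
    d2 <- colSums((t(cent[match(others, ids), , drop = FALSE]) -
                   cent[match(small, ids), ])^2)
    target <- others[which.min(d2)]
    warning("cluster ", small, " below ", min_voxels,
            " voxels; merged into cluster ", target)
    labels[labels == small] <- target
  }
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  compact <- array(0L, dim(labels))
  for (i in seq_along(ids)) compact[labels == ids[i]] <- i
  labels <- compact
  ids <- seq_along(ids)

  rows <- lapply(ids, function(r) {
    region <- labels == r
    disc_region <- function(nm) {
      a <- array(0L, dim(labels)); a[region] <- pre$discrete[[nm]][region]; a
    }
    out <- numeric(0)
    for (nm in SEQUENCE_NAMES) {
      vals <- pre$sequences[[nm]][region]
      fo <- first_order_features(vals, pre$discrete[[nm]][region],
                                 prod(pre$voxel_spacing_mm))
      tex <- texture_features(texture_matrices(disc_region(nm), pre$n_gray_levels))
      pfx <- seq_prefix(nm)
      out <- c(out, stats::setNames(fo, paste0(pfx, "_firstorder_", names(fo))),
               stats::setNames(tex, paste0(pfx, "_", names(tex))))
    }
    out
  })
  list(features = do.call(rbind, rows), labels = labels)
}

#' Reduce secondary features by PCA
#'
#' Columns are standardized to zero mean and unit variance (zero-variance
#' columns dropped with a warning), then projected onto the smallest number
#' of leading principal components whose cumulative explained-variance ratio
#' reaches `retained_fraction`.
#'
#' @param feature_matrix numeric matrix (rows = preliminary clusters).
#' @param retained_fraction minimum cumulative explained-variance ratio
#'   (default 0.85).
#' @return matrix of PCA scores with attributes `explained_variance_ratio`
#'   (per retained component) and `cumulative_evr`.
#' @export
reduce_pca <- function(feature_matrix, retained_fraction = 0.85) {
  X <- as.matrix(feature_matrix)
  stopifnot(nrow(X) >= 2, retained_fraction > 0, retained_fraction <= 1)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance columns dropped before PCA")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(evr) >= retained_fraction - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "explained_variance_ratio") <- evr[seq_len(k)]
  attr(scores, "cumulative_evr") <- sum(evr[seq_len(k)])
  scores
}

#' Habitat-clustering configuration
#'
#' @param fcm an [fcm_config()] for the preliminary voxel clustering.
#' @param retained_fraction PCA explained-variance target (default 0.85).
#' @param max_components upper bound on final subregions (default 10).
#' @param min_voxels minimum preliminary cluster size.
#' @param weight_floor,restarts,prior_scale passed to
#'   [cluster_subregions_bgmm()].
#' @param seed master seed of the habitat stage.
#' @return list of class `habitat_config`.
#' @export
habitat_config <- function(fcm = fcm_config(n_clusters = 10),
                           retained_fraction = 0.85, max_components = 10,
                           min_voxels = 10, weight_floor = 0.01, restarts = 10,
                           prior_scale = 8, seed = 1L) {
  structure(list(fcm = fcm, retained_fraction = retained_fraction,
                 max_components = as.integer(max_components),
                 min_voxels = as.integer(min_voxels),
                 weight_floor = weight_floor, restarts = as.integer(restarts),
                 prior_scale = prior_scale, seed = as.integer(seed)),
            class = "habitat_config")
}

#' Build the adaptive subregion label map of one patient
#'
#' The full habitat-clustering stage: (1) FCM clustering of the in-mask
#' voxel 4-vectors (z-scored intensities of the four sequences) into the
#' preliminary clusters; (2) 368 secondary radiomic features per preliminary
#' cluster; (3) PCA retaining `retained_fraction` of the information;
#' (4) variational Bayesian Gaussian-mixture merging of radiomically similar
#' clusters. Every preliminary cluster maps to exactly one final subregion,
#' so the final map is a coarsening of the FCM partition.
#'
#' @param pre a `preprocessed_volumes` object.
#' @param config a [habitat_config()].
#' @return object of class `subregion_map`: `labels` (integer volume, 0
#'   outside the tumor), `V` (number of final subregions), `provenance`
#'   (tibble preliminary cluster -> subregion), plus diagnostic elements
#'   (`fcm_objective`, `pca_cumulative_evr`, `bgmm`).
#' @export
build_subregion_map <- function(pre, config = habitat_config()) {
  stopifnot(inherits(pre, "preprocessed_volumes"))
  mask_idx <- which(pre$tumor_mask > 0)
  X <- vapply(SEQUENCE_NAMES, function(nm) pre$sequences[[nm]][mask_idx],
              numeric(length(mask_idx)))
  fcm_cfg <- config$fcm
  fcm_cfg$seed <- derive_seed(config$seed, "fcm-stage")
  fit <- fcm_cluster(X, fcm_cfg)
  prelim <- array(0L, dim(pre$tumor_mask))
  prelim[mask_idx] <- fit$labels

  sec <- extract_secondary_features(pre, prelim, config$min_voxels)
  n_clust <- nrow(sec$features)
  if (n_clust == 1) {
    labels <- sec$labels
    prov <- tibble::tibble(preliminary = 1L, subregion = 1L)
    bg <- NULL
    V <- 1L
    evr <- NA_real_
  } else {
    scores <- reduce_pca(sec$features, config$retained_fraction)
    evr <- attr(scores, "cumulative_evr")
    bg <- cluster_subregions_bgmm(scores,
                                  max_components = min(config$max_components, n_clust),
                                  seed = derive_seed(config$seed, "bgmm-stage"),
                                  weight_floor = config$weight_floor,
                                  restarts = config$restarts,
                                  prior_scale = config$prior_scale)
    V <- bg$V
    labels <- array(0L, dim(sec$labels))
    for (i in seq_len(n_clust)) labels[sec$labels == i] <- bg$assignment[i]
    prov <- tibble::tibble(preliminary = seq_len(n_clust),
                           subregion = as.integer(bg$assignment))
  }
  structure(list(labels = labels, V = as.integer(V), provenance = prov,
                 fcm_objective = fit$objective, pca_cumulative_evr = evr,
                 n_preliminary = n_clust, bgmm = bg),
            class = "subregion_map")
}

#' @export
print.subregion_map <- function(x, ...) {
  cat("<subregion_map> V =", x$V, "subregions from", x$n_preliminary,
      "preliminary clusters\n")
  invisible(x)
}

#' Write a subregion label map as NIfTI with a JSON sidecar
#'
#' @param map a `subregion_map`.
#' @param prefix output path prefix.
#' @param spacing voxel spacing recorded in the NIfTI header.
#' @return the written file paths, invisibly.
#' @export
write_subregion_map <- function(map, prefix, spacing = c(1, 1, 1)) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  p1 <- paste0(prefix, "_subregions.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(map$labels, pixdim = spacing), p1)
  p2 <- paste0(prefix, "_subregions.json")
  jsonlite::write_json(list(V = map$V, provenance = map$provenance,
                            pca_cumulative_evr = map$pca_cumulative_evr),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
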