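#' Parameters of the synthetic tumor phantom
#'
#' Defines the generative model for one phantom patient: an ellipsoidal tumor
#' on a regular grid, partitioned into `n_habitats_true` spatially contiguous
#' habitats (nearest-seed/Voronoi growth from random seed voxels). Each
#' habitat has, per MRI sequence, a mean intensity and a spatially correlated
#' Gaussian texture field (correlation length `habitat_texture_scale`, in mm)
#' so that habitats differ in both first-order and texture features. An MSI
#' positive patient has the parameters of the habitats listed in
#' `msi_effect$habitats` displaced: means shifted by `msi_effect$mean_shift`
#' and texture modified by the two multipliers. This plants a habitat-level
#' signal that is diluted at the whole-tumor level, emulating focal
#' heterogeneity. A per-patient random intensity offset (`patient_effect_sd`)
#' emulates scanner/patient global intensity variation.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing_mm numeric length-3 (mm).
#' @param n_habitats_true integer in 1..10.
#' @param habitat_intensity_means `n_habitats_true` x 4 matrix of mean
#'   intensities (columns ordered as [SEQUENCE_NAMES]); default is a fixed
#'   well-separated design.
#' @param habitat_texture_scale per-habitat spatial correlation length (mm).
#' @param habitat_texture_sd per-habitat texture standard deviation.
#' @param noise_sd additive white-noise SD.
#' @param bias_field_amplitude amplitude of the multiplicative smooth bias
#'   field (0 disables it).
#' @param patient_effect_sd SD of the per-patient global intensity offset.
#' @param mask_semi_axes_frac ellipsoid semi-axes as a fraction of the grid.
#' @param habitat_seed_method `"random"` (default) draws habitat seed voxels
#'   uniformly from the mask; `"spread"` uses farthest-point sampling so the
#'   habitats have comparable volumes (no degenerate slivers) — useful for
#'   planted-recovery experiments.
#' @param habitat_volume_weights per-habitat multiplicative Voronoi weights;
#'   values below 1 shrink a habitat's share of the tumor. The default makes
#'   the first (MSI-effect) habitat focal — roughly half the volume share of
#'   the others — so the planted signal is diluted at the whole-tumor level.
#' @param msi_effect list with `habitats` (indices of affected habitats),
#'   `mean_shift` (added to those habitats' means, recycled over sequences),
#'   `texture_scale_mult` and `texture_sd_mult` (multipliers on their texture
#'   parameters).
#' @param seed integer master seed for this phantom.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(32, 32, 24),
                           voxel_spacing_mm = c(1, 1, 1),
                           n_habitats_true = 3,
                           habitat_intensity_means = NULL,
                           habitat_texture_scale = NULL,
                           habitat_texture_sd = NULL,
                           noise_sd = 5,
                           bias_field_amplitude = 0,
                           patient_effect_sd = 10,
                           mask_semi_axes_frac = c(0.34, 0.34, 0.34),
                           habitat_seed_method = c("random", "spread"),
                           habitat_volume_weights = NULL,
                           msi_effect = list(habitats = 1L, mean_shift = 4,
                                             texture_scale_mult = 2.5,
                                             texture_sd_mult = 2),
                           seed = 1L) {
  n <- as.integer(n_habitats_true)
  if (n < 1 || n > 10) stop("n_habitats_true must be in 1..10")
  if (noise_sd < 0 || bias_field_amplitude < 0) {
    stop("noise_sd and bias_field_amplitude must be >= 0")
  }
  if (is.null(habitat_intensity_means)) {
    base <- c(120, 100, 140, 160)
    offsets <- rbind(
      c(0, 0, 0, 0), c(25, -20, 30, -15), c(-25, 20, -20, 30),
      c(20, 25, -30, -20), c(-20, -25, 20, 15), c(30, 15, 25, 20),
      c(15, -30, -25, 10), c(-30, 10, 15, -25), c(10, 30, -15, 25),
      c(-10, -15, 25, -30))
    habitat_intensity_means <- sweep(offsets[seq_len(n), , drop = FALSE], 2, base, "+")
  }
  habitat_intensity_means <- as.matrix(habitat_intensity_means)
  stopifnot(nrow(habitat_intensity_means) == n, ncol(habitat_intensity_means) == 4)
  if (is.null(habitat_texture_scale)) {
    habitat_texture_scale <- rep(c(2.5, 1.2, 4, 2, 3, 1.6, 2.2, 3.5, 1.4, 2.8), length.out = n)
  }
  if (is.null(habitat_texture_sd)) habitat_texture_sd <- rep(12, n)
  if (is.null(habitat_volume_weights)) {
    habitat_volume_weights <- if (n > 1) c(0.72, rep(1, n - 1)) else 1
  }
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    n_habitats_true = n,
    habitat_intensity_means = habitat_intensity_means,
    habitat_texture_scale = rep(habitat_texture_scale, length.out = n),
    habitat_texture_sd = rep(habitat_texture_sd, length.out = n),
    noise_sd = noise_sd,
    bias_field_amplitude = bias_field_amplitude,
    patient_effect_sd = patient_effect_sd,
    mask_semi_axes_frac = rep(mask_semi_axes_frac, length.out = 3),
    habitat_seed_method = match.arg(habitat_seed_method),
    habitat_volume_weights = rep(habitat_volume_weights, length.out = n),
    msi_effect = msi_effect,
    seed = as.integer(seed)
  ), class = "phantom_params")
}

# Spatially correlated unit-variance Gaussian field on the full grid.
random_texture_field <- function(grid_shape, corr_len_vox) {
  f <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  f <- gaussian_smooth3d(f, corr_len_vox)
  s <- stats::sd(f)
  if (s == 0) return(f)
  f / s
}

#' Generate one phantom patient
#'
#' Builds the ellipsoidal tumor mask, grows the habitats by nearest-seed
#' assignment, realizes the four sequences from the habitat parameter model
#' (displaced by `msi_effect` when `msi = 1`), and applies the optional bias
#' field and additive noise. Identical `params` (including `params$seed`) and
#' `msi` reproduce the volumes bit-identically.
#'
#' @param params a [phantom_params()].
#' @param msi 0 (MSS) or 1 (MSI).
#' @return list with `volumes` (a [volume_set()]), `truth` (integer habitat
#'   label array, 0 outside the tumor) and `msi`.
#' @export
generate_phantom <- function(params, msi = 0) {
  stopifnot(inherits(params, "phantom_params"), msi %in% c(0, 1))
  d <- params$grid_shape
  sp <- params$voxel_spacing_mm
  # the same seed stream is used for both MSI states: the label changes the
  # generative parameters, not the geometry or noise realization
  with_seed(derive_seed(params$seed, "phantom"), {
    ctr <- (d + 1) / 2
    semi <- params$mask_semi_axes_frac * d
    g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3])))
    inside <- ((g[, 1] - ctr[1]) / semi[1])^2 + ((g[, 2] - ctr[2]) / semi[2])^2 +
      ((g[, 3] - ctr[3]) / semi[3])^2 <= 1
    mask <- array(as.integer(inside), d)
    mask_idx <- which(inside)
    n_hab <- params$n_habitats_true
    if (n_hab > length(mask_idx)) stop("more habitats than tumor voxels")

    if ((params$habitat_seed_method %||% "random") == "spread" && n_hab > 1) {
      # farthest-point sampling: roughly balanced habitat volumes
      seeds <- sample(mask_idx, 1)
      vox_xyz <- g[mask_idx, , drop = FALSE]
      d2min <- rowSums(sweep(vox_xyz, 2, g[seeds[1], ], "-")^2)
      for (h in 2:n_hab) {
        nxt <- mask_idx[which.max(d2min)]
        seeds <- c(seeds, nxt)
        d2min <- pmin(d2min, rowSums(sweep(vox_xyz, 2, g[nxt, ], "-")^2))
      }
    } else {
      seeds <- sample(mask_idx, n_hab)
    }
    seed_xyz <- g[seeds, , drop = FALSE]
    vox_mm <- sweep(g[mask_idx, , drop = FALSE], 2, sp, "*")
    seed_mm <- sweep(seed_xyz, 2, sp, "*")
    d2 <- outer(rowSums(vox_mm^2), rep(1, n_hab)) - 2 * vox_mm %*% t(seed_mm) +
      outer(rep(1, length(mask_idx)), rowSums(seed_mm^2))
    # multiplicative weighted Voronoi: smaller weights shrink a habitat
    d2 <- sweep(d2, 2, params$habitat_volume_weights^2, "/")
    hab <- max.col(-d2, ties.method = "first")
    truth <- array(0L, d)
    truth[mask_idx] <- hab

    means <- params$habitat_intensity_means
    tex_scale <- params$habitat_texture_scale
    tex_sd <- params$habitat_texture_sd
    if (msi == 1) {
      eff <- params$msi_effect
      hs <- eff$habitats
      means[hs, ] <- means[hs, , drop = FALSE] +
        matrix(rep(eff$mean_shift, length.out = 4), length(hs), 4, byrow = TRUE)
      tex_scale[hs] <- tex_scale[hs] * (eff$texture_scale_mult %||% 1)
      tex_sd[hs] <- tex_sd[hs] * (eff$texture_sd_mult %||% 1)
    }

    pat_off <- stats::rnorm(4, 0, params$patient_effect_sd)
    seqs <- list()
    for (s in seq_along(SEQUENCE_NAMES)) {
      vol <- array(abs(stats::rnorm(prod(d), 10, 3)), d)  # positive background
      for (h in seq_len(n_hab)) {
        vox <- mask_idx[hab == h]
        base <- means[h, s] + pat_off[s]
        if (tex_sd[h] > 0) {
          fld <- random_texture_field(d, tex_scale[h] / sp)
          vol[vox] <- base + tex_sd[h] * fld[vox]
        } else {
          vol[vox] <- base
        }
      }
      if (params$noise_sd > 0) {
        vol <- vol + array(stats::rnorm(prod(d), 0, params$noise_sd), d)
      }
      if (params$bias_field_amplitude > 0) {
        bf <- random_texture_field(d, d / 3)
        bias <- exp(params$bias_field_amplitude * bf)
        bias <- bias / mean(bias)
        vol <- vol * bias
      }
      vol[vol <= 0] <- 1e-3  # keep volumes strictly positive
      seqs[[SEQUENCE_NAMES[s]]] <- vol
    }
    list(volumes = volume_set(seqs, mask, sp), truth = truth, msi = msi)
  })
}

#' Generate the clinicoradiological table of a synthetic cohort
#'
#' Draws MSI labels at the requested prevalence, clinicoradiological
#' covariates whose association with MSI mirrors the published cohort (higher
#' tumor location raises MSI odds, nodal involvement lowers them; the other
#' covariates are null), and exponential disease-free survival with a
#' configurable MSS:MSI hazard ratio and administrative censoring at 60
#' months. Patients are split 80/20 into training and external test cohorts;
#' if either cohort ends up single-class the labels are redrawn (up to
#' `max_retry` times, with a warning).
#'
#' @param n_patients number of patients (>= 2).
#' @param msi_prevalence expected MSI fraction in (0, 1).
#' @param location_or odds ratios (middle, high) vs low tumor location for MSI.
#' @param nstage_or odds ratio N1-N2 vs N0 for MSI.
#' @param dfs_mss_3yr 3-year disease-free survival fraction of the MSS group.
#' @param hazard_ratio_mss_msi MSS:MSI hazard ratio (> 1 means MSI does better).
#' @param censor_admin_months administrative censoring horizon (months).
#' @param censor_rate rate of the independent exponential dropout process.
#' @param seed integer seed.
#' @param max_retry label redraw limit for degenerate cohorts.
#' @return A tibble with one row per patient (covariates, `msi`, `dfs_time`,
#'   `dfs_event`, `cohort`).
#' @export
generate_clinical_cohort <- function(n_patients, msi_prevalence = 53 / 475,
                                     location_or = c(middle = 1.35, high = 3.0),
                                     nstage_or = 0.4,
                                     dfs_mss_3yr = 0.35,
                                     hazard_ratio_mss_msi = 4,
                                     censor_admin_months = 60,
                                     censor_rate = 1 / 80,
                                     seed = 1L,
                                     max_retry = 20L) {
  stopifnot(n_patients >= 2, msi_prevalence > 0, msi_prevalence < 1)
  with_seed(derive_seed(seed, "clinical"), {
    n_train <- max(1L, round(0.8 * n_patients))
    cohort <- c(rep("training", n_train), rep("external_test", n_patients - n_train))
    cohort <- sample(cohort)
    msi <- stats::rbinom(n_patients, 1, msi_prevalence)
    tries <- 0
    degenerate <- function(m) {
      any(vapply(split(m, cohort), function(x) length(unique(x)) < 2, logical(1)))
    }
    while (degenerate(msi) && tries < max_retry) {
      if (tries == 0) warning("degenerate MSI split; redrawing labels")
      msi <- stats::rbinom(n_patients, 1, msi_prevalence)
      tries <- tries + 1
    }

    # location: baseline (MSS) multinomial odds, scaled by OR for MSI patients
    base_p <- c(low = 0.46, middle = 0.36, high = 0.18)
    odds <- base_p / base_p["low"]
    loc <- character(n_patients)
    for (i in seq_len(n_patients)) {
      o <- odds
      if (msi[i] == 1) {
        o["middle"] <- o["middle"] * location_or[["middle"]]
        o["high"] <- o["high"] * location_or[["high"]]
      }
      loc[i] <- sample(names(base_p), 1, prob = o / sum(o))
    }
    p_n1 <- 0.35
    odds_n <- p_n1 / (1 - p_n1)
    n_stage <- ifelse(
      stats::runif(n_patients) < ifelse(msi == 1,
                                        odds_n * nstage_or / (1 + odds_n * nstage_or),
                                        p_n1),
      "N1-N2", "N0")

    lambda_mss <- -log(dfs_mss_3yr) / 36
    lambda <- ifelse(msi == 1, lambda_mss / hazard_ratio_mss_msi, lambda_mss)
    t_event <- stats::rexp(n_patients, lambda)
    t_cens <- pmin(censor_admin_months, stats::rexp(n_patients, censor_rate))
    dfs_time <- pmax(0.1, pmin(t_event, t_cens))
    dfs_event <- as.integer(t_event <= t_cens)

    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      age = pmin(90, pmax(25, round(stats::rnorm(n_patients, 64, 10)))),
      sex = factor(ifelse(stats::runif(n_patients) < 0.64, "male", "female"),
                   levels = c("male", "female")),
      cea = factor(ifelse(stats::runif(n_patients) < 0.43, ">5", "<=5"),
                   levels = c("<=5", ">5")),
      ca19_9 = factor(ifelse(stats::runif(n_patients) < 0.13, ">37", "<=37"),
                      levels = c("<=37", ">37")),
      location = factor(loc, levels = c("low", "middle", "high")),
      t_stage = factor(ifelse(stats::runif(n_patients) < 0.69, "T3-T4", "T1-T2"),
                       levels = c("T1-T2", "T3-T4")),
      n_stage = factor(n_stage, levels = c("N0", "N1-N2")),
      msi = as.integer(msi),
      dfs_time = dfs_time,
      dfs_event = dfs_event,
      cohort = factor(cohort, levels = c("training", "external_test"))
    )
  })
}

#' Generate a full phantom cohort (images + clinicoradiological table)
#'
#' Couples [generate_clinical_cohort()] with per-patient phantoms from
#' [generate_phantom()]: each patient's imaging parameters are displaced by
#' the MSI effect when their MSI label is 1. All randomness derives from
#' `seed`.
#'
#' @inheritParams generate_clinical_cohort
#' @param params a [phantom_params()] shared by all patients (each patient
#'   gets a derived seed).
#' @param seed integer seed.
#' @param ... passed to [generate_clinical_cohort()].
#' @return list with `clinical` (tibble) and `imaging` (named list per
#'   patient with `volumes`, `truth`, `msi`).
#' @export
generate_cohort <- function(n_patients, msi_prevalence = 53 / 475,
                            params = phantom_params(), seed = 1L, ...) {
  clinical <- generate_clinical_cohort(n_patients, msi_prevalence, seed = seed, ...)
  imaging <- vector("list", n_patients)
  names(imaging) <- clinical$patient_id
  for (i in seq_len(n_patients)) {
    p_i <- params
    p_i$seed <- derive_seed(seed, paste0("patient", i))
    imaging[[i]] <- generate_phantom(p_i, msi = clinical$msi[i])
  }
  list(clinical = clinical, imaging = imaging)
}

#' Simulate a second-rater / repeat segmentation
#'
#' Perturbs a binary mask at its boundary: voxels in the one-voxel inner and
#' outer boundary layers are flipped with probability `flip_prob`, voxels in
#' the second layer with `flip_prob / 4` (the flip probability decays with
#' distance from the boundary). If the Dice overlap with the original drops
#' below `dice_floor`, or the mask empties, the perturbation is retried with
#' halved flip probability.
#'
#' @param mask binary 3-D array.
#' @param seed integer seed.
#' @param flip_prob boundary voxel flip probability.
#' @param dice_floor minimum acceptable Dice overlap with the original.
#' @param max_retry retry limit.
#' @return perturbed binary array of the same shape.
#' @export
generate_rater_perturbation <- function(mask, seed = 1L, flip_prob = 0.15,
                                        dice_floor = 0.8, max_retry = 10L) {
  stopifnot(sum(mask) > 0)
  m <- array(as.integer(mask > 0), dim(mask))
  if (flip_prob <= 0) return(m)
  face <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  neigh_any <- function(a, val) {
    out <- array(FALSE, dim(a))
    for (k in seq_len(nrow(face))) out <- out | (shift3d(a, face[k, ], fill = val) == val)
    out
  }
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  with_seed(derive_seed(seed, "rater"), {
    p <- flip_prob
    for (try in seq_len(max_retry)) {
      inner1 <- m == 1 & neigh_any(m, 0L)
      outer1 <- m == 0 & neigh_any(m, 1L)
      core <- m == 1 & !inner1
      inner2 <- core & neigh_any(array(as.integer(core), dim(m)), 0L)
      u <- array(stats::runif(length(m)), dim(m))
      out <- m
      out[inner1 & u < p] <- 0L
      out[outer1 & u < p] <- 1L
      out[inner2 & u < p / 4] <- 0L
      if (sum(out) > 0 && dice(out == 1, m == 1) >= dice_floor) return(out)
      p <- p / 2
    }
    warning("rater perturbation hit the retry limit; returning original mask")
    m
  })
}
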