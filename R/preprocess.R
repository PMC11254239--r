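#' Preprocessing configuration
#'
#' Controls the fixed four-step standardization applied to every sequence
#' before clustering and feature extraction: (1) multiplicative bias-field
#' correction, (2) z-score intensity standardization, (3) isotropic B-spline
#' resampling, (4) fixed-bin-count gray-level discretization. The step order
#' is part of the method and cannot be changed; supplying `order` with any
#' other permutation is a configuration error.
#'
#' @param target_spacing_mm isotropic resampling target (mm), default 1 mm.
#' @param n_gray_levels number of discretization levels, default 32.
#' @param bias_correction logical, run the bias-field correction step.
#' @param normalization_region `"volume"` (default) or `"mask"`: region over
#'   which the z-score statistics are computed.
#' @param bias_df degrees of freedom per axis of the B-spline bias model.
#' @param order must equal the canonical order; present so that a config file
#'   stating a different order fails loudly.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing_mm = c(1, 1, 1),
                              n_gray_levels = 32,
                              bias_correction = TRUE,
                              normalization_region = c("volume", "mask"),
                              bias_df = 4,
                              order = c("bias", "zscore", "resample", "discretize")) {
  normalization_region <- match.arg(normalization_region)
  if (!identical(order, c("bias", "zscore", "resample", "discretize"))) {
    stop("preprocessing order is fixed: bias -> zscore -> resample -> discretize")
  }
  stopifnot(n_gray_levels >= 2, all(target_spacing_mm > 0))
  structure(list(target_spacing_mm = rep(target_spacing_mm, length.out = 3),
                 n_gray_levels = as.integer(n_gray_levels),
                 bias_correction = isTRUE(bias_correction),
                 normalization_region = normalization_region,
                 bias_df = bias_df),
            class = "preprocess_config")
}

#' Correct a smooth multiplicative bias field
#'
#' Estimates the bias in the log domain as a tensor-product B-spline surface
#' (least squares over the fitting region) and divides it out, fixing the
#' overall gain so that the mean intensity over the mask is unchanged. This
#' realizes the N4-style contract — removal of a smooth multiplicative field
#' — without reproducing any particular N4 release bit-for-bit.
#'
#' @param volume numeric 3-D array, strictly positive where corrected.
#' @param mask binary 3-D array; the gain is fixed over this region.
#' @param df B-spline degrees of freedom per axis (smoothness of the field).
#' @param fit_region `"volume"` to fit on all positive voxels (default) or
#'   `"mask"` to fit inside the mask only.
#' @return corrected array of the same shape, with attribute `bias_field`.
#' @export
correct_bias <- function(volume, mask, df = 4, fit_region = c("volume", "mask")) {
  fit_region <- match.arg(fit_region)
  stopifnot(identical(dim(volume), dim(mask)))
  d <- dim(volume)
  msk <- mask > 0
  if (any(volume[msk] <= 0)) {
    shift <- abs(min(volume[msk])) + 1e-6
    warning("non-positive voxels inside mask; shifting volume by ", signif(shift, 3))
    volume <- volume + shift
  }
  fit_idx <- if (fit_region == "mask") which(msk) else which(volume > 0)
  if (length(fit_idx) > 40000) {
    fit_idx <- fit_idx[seq(1, length(fit_idx), length.out = 40000)]
  }
  coords <- arrayInd(fit_idx, d)
  basis <- function(x, n, dfx) splines::bs(x, df = dfx, degree = 3,
                                           Boundary.knots = c(1, n), intercept = TRUE)
  bx <- basis(coords[, 1], d[1], df)
  by <- basis(coords[, 2], d[2], df)
  bz <- basis(coords[, 3], d[3], df)
  # row-wise tensor product of the three axis bases
  tensor <- function(bx, by, bz) {
    n <- nrow(bx)
    m <- matrix(0, n, ncol(bx) * ncol(by) * ncol(bz))
    k <- 1
    for (i in seq_len(ncol(bx))) for (j in seq_len(ncol(by))) for (l in seq_len(ncol(bz))) {
      m[, k] <- bx[, i] * by[, j] * bz[, l]
      k <- k + 1
    }
    m
  }
  X <- tensor(bx, by, bz)
  yl <- log(volume[fit_idx])
  beta <- stats::lm.fit(X, yl)$coefficients
  beta[is.na(beta)] <- 0
  # evaluate the fitted log-field on the full grid
  full <- arrayInd(seq_len(prod(d)), d)
  Xf <- tensor(basis(full[, 1], d[1], df), basis(full[, 2], d[2], df),
               basis(full[, 3], d[3], df))
  logb <- array(Xf %*% beta, d)
  logb <- logb - mean(logb[msk])
  bias <- exp(logb)
  out <- volume / bias
  out <- out * (mean(volume[msk]) / mean(out[msk]))
  attr(out, "bias_field") <- bias
  out
}

#' Z-score standardize a volume
#'
#' Centers and scales intensities to mean 0 and variance 1 over the
#' configured region.
#'
#' @param volume numeric 3-D array.
#' @param mask binary array, required when `region = "mask"`.
#' @param region `"volume"` (all voxels, default) or `"mask"`.
#' @param name sequence name used in error messages.
#' @return standardized array.
#' @export
zscore_normalize <- function(volume, mask = NULL, region = c("volume", "mask"),
                             name = "volume") {
  region <- match.arg(region)
  vals <- if (region == "mask") {
    stopifnot(!is.null(mask))
    volume[mask > 0]
  } else {
    as.numeric(volume)
  }
  if (length(vals) < 2) stop("normalization region of ", name, " has < 2 voxels")
  s <- stats::sd(vals)
  if (s == 0) stop("zero intensity variance in ", name, "; cannot standardize")
  (volume - mean(vals)) / s
}

#' Resample a volume to a new voxel spacing
#'
#' Scalar volumes are interpolated with separable cubic splines (the B-spline
#' family interpolant); masks and label volumes use nearest-neighbour so that
#' labels stay integral. The output grid has `ceil(extent / out_spacing)`
#' voxels per axis and preserves the world-coordinate origin (center of the
#' first voxel).
#'
#' @param volume 3-D array.
#' @param in_spacing,out_spacing numeric length-3 voxel spacings (mm).
#' @param interpolation `"spline"` for scalar volumes, `"nearest"` for
#'   masks/labels.
#' @return resampled array.
#' @export
resample_isotropic <- function(volume, in_spacing, out_spacing,
                               interpolation = c("spline", "nearest")) {
  interpolation <- match.arg(interpolation)
  in_spacing <- rep(in_spacing, length.out = 3)
  out_spacing <- rep(out_spacing, length.out = 3)
  stopifnot(all(in_spacing > 0), all(out_spacing > 0))
  if (interpolation == "nearest" && !all(volume == round(volume))) {
    stop("nearest-neighbour interpolation expects an integer label volume")
  }
  if (all(abs(in_spacing - out_spacing) < 1e-12)) return(volume)
  a <- volume
  for (ax in 1:3) {
    d <- dim(a)
    n_in <- d[ax]
    n_out <- max(1L, as.integer(ceiling(n_in * in_spacing[ax] / out_spacing[ax])))
    old <- (seq_len(n_in) - 1) * in_spacing[ax]
    new <- (seq_len(n_out) - 1) * out_spacing[ax]
    new <- pmin(new, max(old))  # clamp to the input extent
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    mm <- matrix(m, d[ax], prod(d[-ax]))
    res <- matrix(0, n_out, ncol(mm))
    if (interpolation == "nearest") {
      idx <- vapply(new, function(x) which.min(abs(old - x)), integer(1))
      res <- mm[idx, , drop = FALSE]
    } else if (n_in < 4) {
      for (j in seq_len(ncol(mm))) res[, j] <- stats::approx(old, mm[, j], xout = new)$y
    } else {
      for (j in seq_len(ncol(mm))) {
        res[, j] <- stats::splinefun(old, mm[, j], method = "natural")(new)
      }
    }
    a <- aperm(array(res, c(n_out, d[-ax])), order(perm))
  }
  a
}

#' Discretize gray levels inside a mask
#'
#' Fixed-bin-count discretization over the in-mask intensity range:
#' `level = floor(n_levels * (x - min) / (max - min)) + 1`, capped at
#' `n_levels`. Voxels outside the mask are set to 0.
#'
#' @param volume numeric 3-D array.
#' @param mask binary 3-D array, non-empty.
#' @param n_levels number of gray levels (default 32).
#' @return integer array with in-mask values in `1..n_levels`, 0 outside.
#' @export
discretize_gray_levels <- function(volume, mask, n_levels = 32) {
  stopifnot(identical(dim(volume), dim(mask)), sum(mask) > 0, n_levels >= 2)
  vals <- volume[mask > 0]
  lo <- min(vals); hi <- max(vals)
  out <- array(0L, dim(volume))
  if (hi == lo) {
    warning("constant intensity inside mask; all voxels mapped to level 1")
    out[mask > 0] <- 1L
    return(out)
  }
  lev <- floor(n_levels * (vals - lo) / (hi - lo)) + 1
  lev[lev > n_levels] <- n_levels
  out[mask > 0] <- as.integer(lev)
  out
}

#' Run the full preprocessing chain on a volume set
#'
#' Applies, in the fixed order, bias correction, z-score standardization,
#' isotropic resampling (spline for sequences, nearest-neighbour for the
#' mask) and gray-level discretization to each sequence of a [volume_set()].
#'
#' @param vs a [volume_set()].
#' @param config a [preprocess_config()].
#' @return A `preprocessed_volumes` list: `sequences` (standardized continuous
#'   arrays), `discrete` (integer level arrays, 0 outside the tumor),
#'   `tumor_mask`, `voxel_spacing_mm`, `n_gray_levels`.
#' @export
preprocess_volumes <- function(vs, config = preprocess_config()) {
  stopifnot(inherits(vs, "volume_set"), inherits(config, "preprocess_config"))
  sp_in <- vs$voxel_spacing_mm
  sp_out <- config$target_spacing_mm
  mask0 <- vs$tumor_mask
  seqs <- disc <- list()
  mask <- resample_isotropic(mask0, sp_in, sp_out, "nearest")
  for (nm in SEQUENCE_NAMES) {
    v <- vs$sequences[[nm]]
    if (config$bias_correction) {
      v <- correct_bias(v, mask0, df = config$bias_df)
      attr(v, "bias_field") <- NULL
    }
    v <- zscore_normalize(v, mask0, region = config$normalization_region, name = nm)
    v <- resample_isotropic(v, sp_in, sp_out, "spline")
    seqs[[nm]] <- v
    disc[[nm]] <- discretize_gray_levels(v, mask, config$n_gray_levels)
  }
  structure(list(sequences = seqs, discrete = disc, tumor_mask = mask,
                 voxel_spacing_mm = sp_out, n_gray_levels = config$n_gray_levels),
            class = "preprocessed_volumes")
}
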