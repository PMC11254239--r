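#' Extract the full radiomic signature of one region
#'
#' For each of the four sequences: 18 first-order features (continuous
#' z-scored intensities plus discretized levels), 14 shape features of the
#' region geometry, and 74 texture features from the discretized levels —
#' 106 features per sequence, 424 in total. The shape block depends only on
#' the region geometry and is computed once, but is emitted under each
#' sequence's namespace so a full extraction always carries 4 x 106 = 424
#' named values. Feature ids follow `<sequence>_<family>_<name>`.
#'
#' @param pre a `preprocessed_volumes` object (see [preprocess_volumes()]).
#' @param labels integer label volume on the same grid (e.g. a subregion
#'   label map, or the tumor mask itself for whole-tumor extraction).
#' @param region_id integer label to extract (must be present in `labels`).
#' @return named numeric vector of length 424.
#' @export
extract_region_features <- function(pre, labels, region_id) {
  stopifnot(inherits(pre, "preprocessed_volumes"))
  region <- labels == region_id
  if (sum(region) == 0) stop("region ", region_id, " not present in label volume")
  voxvol <- prod(pre$voxel_spacing_mm)
  shape <- shape_features(array(as.integer(region), dim(labels)),
                          pre$voxel_spacing_mm)
  out <- numeric(0)
  for (nm in SEQUENCE_NAMES) {
    vals <- pre$sequences[[nm]][region]
    disc_full <- pre$discrete[[nm]]
    disc_region <- array(0L, dim(labels))
    disc_region[region] <- disc_full[region]
    fo <- first_order_features(vals, disc_full[region], voxvol)
    tex <- if (sum(region) >= 2) {
      texture_features(texture_matrices(disc_region, pre$n_gray_levels))
    } else {
      stats::setNames(rep(0, 74), names(texture_features(
        texture_matrices(array(c(1L, 1L, rep(0L, 6)), c(2, 2, 2)), 2))))
    }
    pfx <- seq_prefix(nm)
    out <- c(out,
             stats::setNames(fo, paste0(pfx, "_firstorder_", names(fo))),
             stats::setNames(shape, paste0(pfx, "_shape_", names(shape))),
             stats::setNames(tex, paste0(pfx, "_", names(tex))))
  }
  out
}

#' Tabulate radiomic features over regions
#'
#' Runs [extract_region_features()] for every region of a label volume and
#' returns a tibble with one row per region — the row format consumed by the
#' feature-selection and modelling stages.
#'
#' @param pre a `preprocessed_volumes` object.
#' @param labels integer label volume; regions are its positive labels.
#' @param patient_id identifier copied into every row.
#' @return tibble with `patient_id`, `region_id`, `n_voxels` and 424 feature
#'   columns.
#' @export
extract_feature_table <- function(pre, labels, patient_id = "P0001") {
  regs <- sort(setdiff(unique(as.vector(labels)), 0))
  rows <- lapply(regs, function(r) {
    fv <- extract_region_features(pre, labels, r)
    tibble::as_tibble_row(c(list(patient_id = patient_id, region_id = r,
                                 n_voxels = sum(labels == r)), as.list(fv)))
  })
  dplyr::bind_rows(rows)
}
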