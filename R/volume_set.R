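#' Bundle of co-registered multiparametric volumes for one patient
#'
#' A `volume_set` holds the four co-registered MRI sequences (T2WI, T1WI, DWI,
#' CE-T1WI) as 3-D arrays on a common grid, together with the binary tumor
#' mask and the voxel spacing in millimetres. All downstream stages
#' (preprocessing, habitat clustering, feature extraction) consume this
#' container. The constructor validates that all volumes share one grid and
#' that the mask is binary and non-empty.
#'
#' @param sequences named list of four numeric 3-D arrays; names must be
#'   `r paste(SEQUENCE_NAMES, collapse = ", ")`.
#' @param tumor_mask integer/logical 3-D array with values in \{0, 1\}.
#' @param voxel_spacing_mm numeric length-3, voxel edge lengths in mm.
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(sequences, tumor_mask, voxel_spacing_mm = c(1, 1, 1)) {
  if (!is.list(sequences) || !setequal(names(sequences), SEQUENCE_NAMES)) {
    stop("`sequences` must be a named list with names: ",
         paste(SEQUENCE_NAMES, collapse = ", "))
  }
  sequences <- sequences[SEQUENCE_NAMES]
  tumor_mask <- array(as.integer(tumor_mask > 0), dim(tumor_mask))
  d <- dim(tumor_mask)
  if (length(d) != 3) stop("tumor_mask must be a 3-D array")
  for (nm in SEQUENCE_NAMES) {
    if (!identical(dim(sequences[[nm]]), d)) {
      stop("sequence ", nm, " does not share the mask's grid shape")
    }
  }
  if (sum(tumor_mask) < 1) stop("tumor_mask has no foreground voxels")
  stopifnot(length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0))
  structure(
    list(sequences = sequences, tumor_mask = tumor_mask,
         voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
    class = "volume_set"
  )
}

#' Canonical sequence names
#'
#' The four multiparametric MRI sequences handled by the pipeline, in their
#' fixed order: T2-weighted, T1-weighted, diffusion-weighted and
#' contrast-enhanced T1-weighted imaging.
#' @export
SEQUENCE_NAMES <- c("T2WI", "T1WI", "DWI", "CE-T1WI")

# Sequence names sanitized for use inside feature identifiers.
seq_prefix <- function(nm) gsub("-", "", nm)

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$tumor_mask)
  cat("<volume_set> ", paste(d, collapse = "x"),
      " grid, spacing ", paste(x$voxel_spacing_mm, collapse = "x"), " mm, ",
      sum(x$tumor_mask), " tumor voxels\n", sep = "")
  invisible(x)
}

#' Write / read a volume set as NIfTI files
#'
#' Each sequence and the tumor mask are written as individual NIfTI files
#' (`<prefix>_<sequence>.nii.gz`, `<prefix>_mask.nii.gz`) with the voxel
#' spacing recorded in the header.
#'
#' @param vs a [volume_set()].
#' @param prefix path prefix for the output files.
#' @return `write_volume_set` returns the written paths invisibly;
#'   `read_volume_set` returns a [volume_set()].
#' @export
write_volume_set <- function(vs, prefix) {
  stopifnot(inherits(vs, "volume_set"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in SEQUENCE_NAMES) {
    p <- paste0(prefix, "_", seq_prefix(nm), ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(vs$sequences[[nm]], pixdim = vs$voxel_spacing_mm), p)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vs$tumor_mask, pixdim = vs$voxel_spacing_mm), p)
  invisible(c(paths, p))
}

#' @rdname write_volume_set
#' @export
read_volume_set <- function(prefix) {
  seqs <- list()
  for (nm in SEQUENCE_NAMES) {
    img <- RNifti::readNifti(paste0(prefix, "_", seq_prefix(nm), ".nii.gz"))
    seqs[[nm]] <- array(as.numeric(img), dim(img))
  }
  mimg <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  spacing <- RNifti::pixdim(mimg)[1:3]
  volume_set(seqs, array(as.integer(mimg), dim(mimg)), spacing)
}
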