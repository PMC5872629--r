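#' Write a DWI volume as NIfTI plus FSL-style gradient table
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval` (one row of b-values) and
#' `<prefix>.bvec` (three rows of direction components), the de facto FSL
#' dialect.
#'
#' @param volume A `dwi_volume`.
#' @param prefix Output path prefix (no extension).
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(volume, prefix) {
  stopifnot(inherits(volume, "dwi_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$voxdim, 1)   # 4-D image: spatial dims + TR slot
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  writeLines(paste(format(volume$scheme$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- t(volume$scheme$bvecs)
  writeLines(apply(bv, 1, function(row)
    paste(format(row, trim = TRUE, digits = 15), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(nii)
}

#' Read a DWI volume written by [write_dwi()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvecs <- t(matrix(scan(paste0(prefix, ".bvec"), quiet = TRUE),
                    nrow = 3, byrow = TRUE))
  scheme <- structure(list(bvals = bvals, bvecs = bvecs,
                           n_s = sum(bvals > 0)),
                      class = "gradient_scheme")
  validate_scheme(scheme)
  structure(list(data = array(as.numeric(img), dim(img)), scheme = scheme,
                 voxdim = RNifti::pixdim(img)[1:3]),
            class = "dwi_volume")
}

#' Write a scalar metric map as NIfTI (validity as a sidecar mask)
#'
#' Invalid voxels are stored as NaN in the data image and as 0 in the
#' `<prefix>_valid.nii.gz` companion mask, so zeros in the metric image
#' remain meaningful values.
#'
#' @param map A `scalar_map`.
#' @param prefix Output path prefix.
#' @return The NIfTI path, invisibly.
#' @export
write_metric_map <- function(map, prefix) {
  stopifnot(inherits(map, "scalar_map"))
  data <- map$data
  data[!map$valid] <- NaN
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- map$voxdim
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  vimg <- RNifti::asNifti(array(as.numeric(map$valid), dim(map$valid)))
  RNifti::pixdim(vimg) <- map$voxdim
  RNifti::writeNifti(vimg, paste0(prefix, "_valid.nii.gz"))
  invisible(nii)
}

#' Read a scalar metric map written by [write_metric_map()]
#'
#' @param prefix Path prefix used at write time.
#' @param metric Metric name to record on the map.
#' @return A `scalar_map`.
#' @export
read_metric_map <- function(prefix, metric = "GFA") {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  vimg <- RNifti::readNifti(paste0(prefix, "_valid.nii.gz"))
  data <- array(as.numeric(img), dim(img))
  valid <- array(as.numeric(vimg) > 0.5, dim(vimg))
  data[!valid] <- NA_real_
  scalar_map(data, valid, RNifti::pixdim(img)[1:3], metric)
}

#' Write an ROI label volume with a JSON label-table sidecar
#'
#' @param mask A [roi_mask()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return The NIfTI path, invisibly.
#' @export
write_roi_mask <- function(mask, prefix) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$labels), dim(mask$labels)))
  RNifti::pixdim(img) <- mask$voxdim
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  jsonlite::write_json(as.list(mask$label_table), paste0(prefix, ".json"),
                       auto_unbox = TRUE)
  invisible(nii)
}

#' Read an ROI label volume written by [write_roi_mask()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  tab <- unlist(jsonlite::read_json(paste0(prefix, ".json")))
  roi_mask(array(as.integer(round(as.numeric(img))), dim(img)),
           stats::setNames(as.integer(tab), names(tab)),
           RNifti::pixdim(img)[1:3])
}
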