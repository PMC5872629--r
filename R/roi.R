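#' Construct an ROI label mask
#'
#' Wraps an integer label volume and its label table.  Labels are disjoint
#' by construction (one integer per voxel); every named ROI must be
#' nonempty.
#'
#' @param labels Integer 3-D array; 0 = background.
#' @param label_table Named integer vector mapping ROI names to label codes.
#' @param voxdim Voxel size in mm.
#' @return A `roi_mask` object.
#' @export
roi_mask <- function(labels, label_table, voxdim = c(1, 1, 1)) {
  stopifnot(length(dim(labels)) == 3, length(voxdim) == 3)
  label_table <- as.integer(label_table) |> stats::setNames(names(label_table))
  if (is.null(names(label_table)) || any(!nzchar(names(label_table))))
    stop("`label_table` must be a named integer vector", call. = FALSE)
  if (anyDuplicated(label_table))
    stop("label codes must be unique", call. = FALSE)
  present <- unique(as.vector(labels))
  empty <- names(label_table)[!label_table %in% present]
  if (length(empty))
    stop("ROI(s) with no voxels: ", paste(empty, collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, label_table = label_table,
                 voxdim = as.numeric(voxdim)),
            class = "roi_mask")
}

#' ROI mask of a phantom's ground truth
#'
#' @param truth A `phantom_truth` from [build_phantom()].
#' @return A [roi_mask()] over the phantom's blocks.
#' @export
truth_roi_mask <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  roi_mask(truth$labels, truth$label_table, truth$voxdim)
}

#' Gaussian smoothing of a scalar map
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `sigma_axis = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size_axis`, so the
#' kernel width is specified in millimetres and respects anisotropic
#' voxels.  Boundaries use nearest-edge replication and invalid voxels are
#' handled by normalized convolution (smoothing the validity weights
#' alongside the data), so a constant map is an exact fixed point away from
#' and at the boundary.  `fwhm_mm = 0` is the identity.
#'
#' @param map A `scalar_map` (see [metric_map()]).
#' @param fwhm_mm Full width at half maximum of the kernel, in mm; the
#'   study protocol value is 6 mm.
#' @return A smoothed `scalar_map`.
#' @export
gaussian_smooth <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "scalar_map"))
  if (length(fwhm_mm) != 1 || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("`fwhm_mm` must be a single nonnegative width in mm", call. = FALSE)
  if (fwhm_mm == 0) return(map)
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / map$voxdim
  num <- map$data
  num[!map$valid] <- 0
  den <- array(as.numeric(map$valid), dim(map$data))
  for (axis in 1:3) {
    w <- gaussian_kernel_1d(sigmas[axis])
    if (length(w) > 1) {
      num <- convolve_axis(num, w, axis)
      den <- convolve_axis(den, w, axis)
    }
  }
  out <- num / den
  valid <- den > 1e-12 & is.finite(out)
  out[!valid] <- NA_real_
  scalar_map(out, valid, map$voxdim, map$metric)
}

# Normalized discrete Gaussian kernel, radius 4 sigma.
gaussian_kernel_1d <- function(sigma) {
  if (sigma < 1e-8) return(1)
  r <- ceiling(4 * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# 1-D convolution along one axis of a 3-D array with edge replication.
convolve_axis <- function(arr, w, axis) {
  d <- dim(arr)
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, d)
  for (j in seq_along(w)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
    idx <- switch(axis,
                  arr[src, , , drop = FALSE],
                  arr[, src, , drop = FALSE],
                  arr[, , src, drop = FALSE])
    out <- out + w[j] * idx
  }
  out
}

#' Per-ROI means of a scalar map
#'
#' Arithmetic mean of the valid voxels of `map` within each named ROI of
#' `mask`.  Invalid voxels are excluded from both the numerator and the
#' voxel count; an ROI left with no valid voxel is an error (naming the
#' ROI), never a silent zero.
#'
#' @param map A `scalar_map`.
#' @param mask A [roi_mask()] with the same geometry.
#' @return A tibble with columns `roi`, `mean`, `n_voxels`.
#' @export
roi_means <- function(map, mask) {
  stopifnot(inherits(map, "scalar_map"), inherits(mask, "roi_mask"))
  if (!identical(dim(map$data), dim(mask$labels)))
    stop("map and ROI mask geometries differ", call. = FALSE)
  res <- lapply(names(mask$label_table), function(nm) {
    sel <- mask$labels == mask$label_table[[nm]] & map$valid
    if (!any(sel))
      stop(sprintf("ROI '%s' contains no valid voxels", nm), call. = FALSE)
    tibble::tibble(roi = nm, mean = mean(map$data[sel]),
                   n_voxels = sum(sel))
  })
  do.call(rbind, res)
}

#' Per-subject, per-ROI summary of FA and GFA maps at one timepoint
#'
#' @param fa_map,gfa_map `scalar_map`s sharing the mask's geometry.
#' @param mask A [roi_mask()].
#' @param subject,timepoint Identifiers recorded in the output.
#' @return A tibble with one row per ROI: `subject`, `timepoint`, `roi`,
#'   `fa`, `gfa`, `n_voxels`.
#' @export
roi_summary <- function(fa_map, gfa_map, mask, subject = "S01",
                        timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  fa_tab <- roi_means(fa_map, mask)
  gfa_tab <- roi_means(gfa_map, mask)
  tibble::tibble(subject = subject, timepoint = timepoint, roi = fa_tab$roi,
                 fa = fa_tab$mean, gfa = gfa_tab$mean,
                 n_voxels = fa_tab$n_voxels)
}
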