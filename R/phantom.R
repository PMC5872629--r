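#' Default phantom layout: four motor-area white-matter blocks
#'
#' The phantom mimics a slab of white matter under the bilateral primary
#' motor (BA4) and premotor (BA6) cortices.  Four disjoint rectangular
#' blocks stand in for the atlas-derived ROI masks of a normalized
#' acquisition: three single-fiber blocks and one crossing-fiber block
#' (two perpendicular populations, equal fractions), so that the
#' FA-drops-at-crossings behaviour is represented.
#'
#' @param lambda Single-fiber eigenvalues (mm^2/s), default a typical
#'   healthy white-matter tensor.
#' @return Named list of block definitions (`x`, `y`, `z` index ranges and
#'   a list of [tensor_spec()] compartments), suitable for
#'   [build_phantom()].
#' @export
phantom_blocks <- function(lambda = c(1.7e-3, 0.2e-3, 0.2e-3)) {
  single <- function(dir) list(tensor_spec(lambda, dir))
  crossing <- list(tensor_spec(lambda, c(1, 0, 0), fraction = 0.5),
                   tensor_spec(lambda, c(0, 1, 0), fraction = 0.5))
  list(
    ba4_lesioned    = list(x = 3:6,  y = 3:6,  z = 2:4, tensors = single(c(1, 0, 0))),
    ba4_nonlesioned = list(x = 9:12, y = 3:6,  z = 2:4, tensors = single(c(0, 1, 0))),
    ba6_lesioned    = list(x = 3:6,  y = 9:12, z = 2:4, tensors = crossing),
    ba6_nonlesioned = list(x = 9:12, y = 9:12, z = 2:4, tensors = single(c(0, 0, 1)))
  )
}

#' Build a synthetic DWI phantom with ground truth
#'
#' Generates a 4-D diffusion-weighted volume on a voxel grid containing
#' rectangular ROI blocks of known tensor composition, with optional Rician
#' noise.  Voxel size defaults to the anisotropic clinical geometry
#' 0.9 x 0.9 x 5 mm.  Background voxels carry the reference signal `S0` in
#' b0 volumes and no coherent signal in DW volumes, so with noise they are
#' noise-only there.
#'
#' @param shape Integer length-3 voxel grid dimensions.
#' @param scheme A [make_scheme()] gradient scheme.
#' @param blocks Block definitions as from [phantom_blocks()]; may be an
#'   empty list for an all-background phantom.
#' @param S0 b0 signal in tissue blocks (and background b0), > 0.
#' @param sigma Rician noise level in signal units; `S0/30` gives the
#'   default SNR-30 acquisition, 0 is noiseless.
#' @param voxdim Voxel size in mm.
#' @param seed Optional seed for the noise draw.
#' @return List with `dwi` (a `dwi_volume`: 4-D `data`, `scheme`,
#'   `voxdim`) and `truth` (a `phantom_truth`: integer `labels` array,
#'   `label_table`, per-block `tensors`, `S0` map, `sigma`).
#' @examples
#' sch <- make_scheme(21, 1000)
#' ph <- build_phantom(c(14, 14, 5), sch, phantom_blocks(), sigma = 0)
#' table(ph$truth$labels)
#' @export
build_phantom <- function(shape, scheme, blocks = phantom_blocks(),
                          S0 = 1000, sigma = S0 / 30,
                          voxdim = c(0.9, 0.9, 5), seed = NULL) {
  validate_scheme(scheme)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), S0 > 0, sigma >= 0)
  labels <- array(0L, shape)
  nvol <- length(scheme$bvals)
  data <- array(0, c(shape, nvol))
  # background: S0 in b0 volumes only
  for (j in b0_indices(scheme)) data[, , , j] <- S0
  label_table <- integer(0)
  tensors <- list()
  for (k in seq_along(blocks)) {
    blk <- blocks[[k]]
    nm <- names(blocks)[k]
    if (max(blk$x) > shape[1] || max(blk$y) > shape[2] || max(blk$z) > shape[3] ||
        min(blk$x) < 1 || min(blk$y) < 1 || min(blk$z) < 1)
      stop(sprintf("block '%s' does not fit inside the phantom grid", nm),
           call. = FALSE)
    if (any(labels[blk$x, blk$y, blk$z] != 0))
      stop(sprintf("block '%s' overlaps a previously placed block", nm),
           call. = FALSE)
    labels[blk$x, blk$y, blk$z] <- k
    label_table[nm] <- k
    tensors[[nm]] <- blk$tensors
    sig <- tensor_signal(blk$tensors, scheme, S0)
    for (j in seq_len(nvol)) data[blk$x, blk$y, blk$z, j] <- sig[j]
  }
  if (sigma > 0) data <- add_rician_noise(data, sigma, seed = seed)
  s0map <- array(S0, shape)
  list(
    dwi = structure(list(data = data, scheme = scheme,
                         voxdim = as.numeric(voxdim)),
                    class = "dwi_volume"),
    truth = structure(list(labels = labels, label_table = label_table,
                           tensors = tensors, S0 = s0map, sigma = sigma,
                           voxdim = as.numeric(voxdim)),
                      class = "phantom_truth"))
}

#' Tissue mask of a phantom (all labelled voxels)
#'
#' @param truth A `phantom_truth`.
#' @return Logical array, `TRUE` inside any ROI block.
#' @export
truth_mask <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  truth$labels > 0L
}
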