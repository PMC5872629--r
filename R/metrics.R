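#' Per-direction ADC profile of one voxel
#'
#' For each diffusion-weighted axis `i`, the apparent diffusion coefficient
#' is `psi_i = -ln(S_i / S0bar) / b_i`, where `S0bar` is the mean of the b0
#' signals.  Magnitude noise can push `S_i` above `S0bar`, producing
#' negative ADCs; by default these are clamped to 0 (diffusivities are
#' physical quantities, and clamping keeps GFA within [0, 1]).  Set
#' `clamp = FALSE` to keep raw values, e.g. for comparison against an
#' external implementation.
#'
#' @param signals Numeric vector, one signal per volume of `scheme`.
#' @param scheme A [make_scheme()] gradient scheme.
#' @param clamp Clamp negative ADC values to 0 (default `TRUE`).
#' @return An `adc_profile` object: list with `values` (length `n_s`,
#'   mm^2/s), `mean`, `n_s` and `defined`.  When every b0 signal is
#'   nonpositive the voxel is undefined: `defined = FALSE` and the values
#'   are `NA`.
#' @examples
#' sch <- make_scheme(21, 1000)
#' s <- tensor_signal(tensor_spec(rep(1e-3, 3)), sch, 1000)
#' adc_profile(s, sch)$values[1]  # 1e-3
#' @export
adc_profile <- function(signals, scheme, clamp = TRUE) {
  validate_scheme(scheme)
  if (length(signals) != length(scheme$bvals))
    stop("`signals` length must match the scheme's volume count", call. = FALSE)
  s0 <- mean(signals[b0_indices(scheme)])
  if (!is.finite(s0) || s0 <= 0) {
    return(structure(list(values = rep(NA_real_, scheme$n_s),
                          mean = NA_real_, n_s = scheme$n_s, defined = FALSE),
                     class = "adc_profile"))
  }
  dw <- dw_indices(scheme)
  psi <- -log(signals[dw] / s0) / scheme$bvals[dw]
  if (clamp) psi <- pmax(psi, 0)
  structure(list(values = psi, mean = mean(psi), n_s = scheme$n_s,
                 defined = all(is.finite(psi))),
            class = "adc_profile")
}

#' Generalized fractional anisotropy of an ADC profile
#'
#' GFA is the sample standard deviation of the per-direction ADC values
#' divided by their root mean square:
#' `sqrt( n_s * sum((psi_i - mean)^2) / ((n_s - 1) * sum(psi_i^2)) )`.
#' For nonnegative profiles the result lies in [0, 1]: 0 for a constant
#' (isotropic) profile, 1 when all but one entry vanish.  It is invariant
#' under rescaling of the profile.
#'
#' @param profile An [adc_profile()] object or a bare numeric vector of
#'   per-direction ADC values (length >= 2).
#' @return A single dimensionless value, or `NA` when undefined (all-zero
#'   or undefined profile).
#' @examples
#' gfa_from_adc_profile(c(1, 2, 3))    # 0.46291
#' gfa_from_adc_profile(c(0, 0, 1))    # 1
#' gfa_from_adc_profile(rep(0.7, 21))  # 0
#' @export
gfa_from_adc_profile <- function(profile) {
  x <- if (inherits(profile, "adc_profile")) {
    if (!profile$defined) return(NA_real_)
    profile$values
  } else as.numeric(profile)
  n <- length(x)
  if (n < 2) stop("GFA needs at least two ADC axes", call. = FALSE)
  if (any(!is.finite(x))) return(NA_real_)
  rms2 <- sum(x^2)
  if (rms2 == 0) return(NA_real_)       # all-zero profile: 0/0, undefined
  sqrt(n * sum((x - mean(x))^2) / ((n - 1) * rms2))
}

# Vectorized GFA over rows of an ADC matrix (n_voxels x n_s).
gfa_rows <- function(adc) {
  n <- ncol(adc)
  rms2 <- rowSums(adc^2)
  ss <- rowSums((adc - rowMeans(adc))^2)
  out <- sqrt(n * ss / ((n - 1) * rms2))
  out[rms2 == 0 | !is.finite(rms2)] <- NA_real_
  out
}

#' Fit a diffusion tensor by log-linear least squares
#'
#' Solves `ln(S_i / S0bar) = -b_i g_i' D g_i` for the six unique elements of
#' the symmetric tensor `D` by ordinary least squares over the DW volumes
#' (multiple b0 volumes are averaged into `S0bar` first).
#'
#' @param signals Numeric vector, one signal per volume.
#' @param scheme A [make_scheme()] scheme with >= 6 non-collinear DW
#'   directions and >= 1 b0 volume.
#' @return A `diffusion_tensor`: list with the 3x3 `tensor` (mm^2/s),
#'   `eigenvalues` sorted descending, and unit `eigenvectors` (columns).
#' @examples
#' sch <- make_scheme(21, 1000)
#' fib <- tensor_spec(c(1.7e-3, 0.2e-3, 0.2e-3), c(0, 1, 0))
#' fit_tensor(tensor_signal(fib, sch, 1000), sch)$eigenvalues
#' @export
fit_tensor <- function(signals, scheme) {
  validate_scheme(scheme)
  if (length(signals) != length(scheme$bvals))
    stop("`signals` length must match the scheme's volume count", call. = FALSE)
  s0 <- mean(signals[b0_indices(scheme)])
  if (!is.finite(s0) || s0 <= 0)
    stop("all b0 signals nonpositive: tensor undefined at this voxel", call. = FALSE)
  X <- tensor_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < 6)
    stop("degenerate gradient scheme: tensor design matrix is rank-deficient",
         call. = FALSE)
  y <- -log(signals[dw_indices(scheme)] / s0)
  beta <- qr.coef(qrX, y)
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  e <- eigen(D, symmetric = TRUE)       # eigenvalues already descending
  structure(list(tensor = D, eigenvalues = e$values, eigenvectors = e$vectors),
            class = "diffusion_tensor")
}

# Design matrix: rows b_i * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz) over DW volumes.
tensor_design <- function(scheme) {
  dw <- dw_indices(scheme)
  G <- scheme$bvecs[dw, , drop = FALSE]
  b <- scheme$bvals[dw]
  b * cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
            2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' sqrt(l1^2 + l2^2 + l3^2)`; lies in [0, 1] for nonnegative eigenvalues,
#' 0 for isotropy, 1 in the single-nonzero limit.  Scale-invariant.
#'
#' @param l1,l2,l3 Eigenvalues, `l1 >= l2 >= l3`.  Alternatively pass a
#'   length-3 vector as `l1`.
#' @return Dimensionless FA, or `NA` when all eigenvalues are zero.
#' @examples
#' fa_from_eigenvalues(1.7e-3, 0.2e-3, 0.2e-3)  # 0.8703883
#' @export
fa_from_eigenvalues <- function(l1, l2 = NULL, l3 = NULL) {
  ev <- if (is.null(l2)) as.numeric(l1) else c(l1, l2, l3)
  if (length(ev) != 3) stop("three eigenvalues required", call. = FALSE)
  den <- sum(ev^2)
  if (den == 0) return(NA_real_)
  sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2) / den)
}

#' Mean diffusivity from tensor eigenvalues
#'
#' @inheritParams fa_from_eigenvalues
#' @return Mean of the three eigenvalues, mm^2/s.
#' @export
md_from_eigenvalues <- function(l1, l2 = NULL, l3 = NULL) {
  ev <- if (is.null(l2)) as.numeric(l1) else c(l1, l2, l3)
  if (length(ev) != 3) stop("three eigenvalues required", call. = FALSE)
  mean(ev)
}

#' Voxelwise scalar metric map from a DWI volume
#'
#' Applies [adc_profile()] + [gfa_from_adc_profile()] (GFA) or
#' [fit_tensor()] + [fa_from_eigenvalues()] / [md_from_eigenvalues()]
#' (FA, MD) at every voxel inside `mask`.  Voxels outside the mask, voxels
#' whose b0 signal is nonpositive, and voxels with nonpositive DW signals
#' are flagged invalid rather than set to zero (zero is a meaningful metric
#' value).
#'
#' @param volume A `dwi_volume` (see [build_phantom()]).
#' @param metric One of `"GFA"`, `"FA"`, `"MD"`.
#' @param mask Optional logical array with the volume's spatial dimensions;
#'   `NULL` processes every voxel.
#' @param clamp Passed to [adc_profile()] (GFA only).
#' @return A `scalar_map`: list with 3-D `data`, logical `valid`, `voxdim`
#'   (mm) and `metric`.
#' @export
metric_map <- function(volume, metric = c("GFA", "FA", "MD"), mask = NULL,
                       clamp = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(volume, "dwi_volume"))
  dims <- dim(volume$data)
  sdim <- dims[1:3]
  if (is.null(mask)) mask <- array(TRUE, sdim)
  if (!identical(dim(mask), sdim))
    stop("mask geometry does not match the DWI volume", call. = FALSE)
  scheme <- volume$scheme
  idx <- which(mask)
  nvox <- length(idx)
  data <- array(NA_real_, sdim)
  valid <- array(FALSE, sdim)
  if (nvox) {
    sig <- matrix(volume$data, prod(sdim), dims[4])[idx, , drop = FALSE]
    s0 <- rowMeans(sig[, b0_indices(scheme), drop = FALSE])
    dw <- dw_indices(scheme)
    ok <- is.finite(s0) & s0 > 0 &
      apply(sig[, dw, drop = FALSE] > 0, 1, all)
    vals <- rep(NA_real_, nvox)
    if (any(ok)) {
      ratio <- sig[ok, dw, drop = FALSE] / s0[ok]
      if (metric == "GFA") {
        adc <- -log(ratio) / rep(scheme$bvals[dw], each = sum(ok))
        if (clamp) adc <- pmax(adc, 0)
        vals[ok] <- gfa_rows(adc)
      } else {
        X <- tensor_design(scheme)
        if (qr(X)$rank < 6)
          stop("degenerate gradient scheme: tensor design matrix is rank-deficient",
               call. = FALSE)
        beta <- t(qr.solve(X, t(-log(ratio))))   # sum(ok) x 6
        f <- if (metric == "FA") fa_from_eigenvalues else md_from_eigenvalues
        vals[ok] <- vapply(seq_len(nrow(beta)), function(i) {
          b <- beta[i, ]
          D <- matrix(c(b[1], b[4], b[5], b[4], b[2], b[6], b[5], b[6], b[3]), 3, 3)
          f(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
        }, numeric(1))
      }
    }
    data[idx] <- vals
    valid[idx] <- ok & is.finite(vals)
  }
  scalar_map(data, valid, volume$voxdim, metric)
}

#' @keywords internal
scalar_map <- function(data, valid, voxdim, metric) {
  stopifnot(length(dim(data)) == 3, identical(dim(data), dim(valid)),
            length(voxdim) == 3)
  structure(list(data = data, valid = valid, voxdim = as.numeric(voxdim),
                 metric = metric),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map> %s, %s voxels (%s mm), %d valid\n",
              x$metric, paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxdim, 3), collapse = "x"), sum(x$valid)))
  invisible(x)
}
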