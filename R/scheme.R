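#' Construct a diffusion gradient scheme
#'
#' Builds an acquisition scheme of `n_directions` diffusion-weighted (DW)
#' gradient directions at a single b-value, preceded by one unweighted (b0)
#' volume.  Directions are laid out deterministically on the upper hemisphere
#' with a Fibonacci (golden-angle) spiral, which is quasi-uniform and avoids
#' antipodal duplicates (a gradient and its negation probe the same
#' diffusion direction).
#'
#' At least 6 non-collinear directions are required for the 6 free elements
#' of a symmetric diffusion tensor to be identifiable.
#'
#' @param n_directions Number of DW axes (motion-probing-gradient
#'   directions); must be an integer >= 6.  A clinical 21-axis protocol is
#'   the default elsewhere in the package.
#' @param b Diffusion weighting in s/mm^2 applied to every DW volume.
#' @return A `gradient_scheme` object: a list with `bvals` (length
#'   `n_directions + 1`, first entry 0), `bvecs` (matrix, one row per
#'   volume, unit rows for DW volumes, zero row for b0) and `n_s`, the
#'   number of DW axes.
#' @examples
#' sch <- make_scheme(21, 1000)
#' sch$n_s            # 21
#' length(sch$bvals)  # 22 volumes: one b0 + 21 DW
#' @export
make_scheme <- function(n_directions, b = 1000) {
  if (length(n_directions) != 1L || !is.numeric(n_directions) ||
      n_directions != round(n_directions) || n_directions < 6)
    stop("`n_directions` must be a single integer >= 6 ",
         "(fewer directions leave the tensor fit underdetermined)",
         call. = FALSE)
  if (length(b) != 1L || !is.numeric(b) || !is.finite(b) || b <= 0)
    stop("`b` must be a single positive diffusion weighting in s/mm^2",
         call. = FALSE)
  n_directions <- as.integer(n_directions)
  dirs <- fibonacci_hemisphere(n_directions)
  scheme <- structure(
    list(bvals = c(0, rep(b, n_directions)),
         bvecs = rbind(c(0, 0, 0), dirs),
         n_s   = n_directions),
    class = "gradient_scheme")
  validate_scheme(scheme)
  scheme
}

#' @keywords internal
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n                     # strictly inside (0, 1): no equator/pole doubling
  phi <- pi * (3 - sqrt(5)) * (i - 1)    # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  m <- unname(cbind(r * cos(phi), r * sin(phi), z))
  m / sqrt(rowSums(m^2))
}

validate_scheme <- function(scheme) {
  stopifnot(is.list(scheme),
            all(c("bvals", "bvecs", "n_s") %in% names(scheme)))
  b <- scheme$bvals
  g <- scheme$bvecs
  if (nrow(g) != length(b))
    stop("bvecs/bvals volume counts disagree", call. = FALSE)
  dw <- b > 0
  if (!any(!dw))
    stop("scheme has no b0 volume", call. = FALSE)
  nrm <- sqrt(rowSums(g[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("DW gradient directions must be unit vectors", call. = FALSE)
  if (sum(dw) != scheme$n_s)
    stop("n_s must equal the number of b > 0 volumes", call. = FALSE)
  invisible(scheme)
}

dw_indices <- function(scheme) which(scheme$bvals > 0)
b0_indices <- function(scheme) which(scheme$bvals == 0)

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes: %d b0 + %d DW at b = %g s/mm^2\n",
              length(x$bvals), length(b0_indices(x)), x$n_s,
              max(x$bvals)))
  invisible(x)
}
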