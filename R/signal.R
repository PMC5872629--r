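#' Specify a diffusion tensor compartment
#'
#' A tensor compartment is defined by its three eigenvalues (principal
#' diffusivities, mm^2/s, sorted descending), the orientation of its
#' principal eigenvector, and a volume fraction used when several
#' compartments share a voxel (crossing fibers).
#'
#' @param eigenvalues Numeric length-3, `lambda1 >= lambda2 >= lambda3 >= 0`,
#'   in mm^2/s.
#' @param direction Principal diffusion direction; any nonzero 3-vector,
#'   normalized internally.
#' @param fraction Volume fraction in a multi-compartment voxel.
#' @return A `tensor_spec` object.
#' @examples
#' fiber <- tensor_spec(c(1.7e-3, 0.2e-3, 0.2e-3), direction = c(1, 0, 0))
#' @export
tensor_spec <- function(eigenvalues, direction = c(1, 0, 0), fraction = 1) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) != 3 || any(!is.finite(ev)))
    stop("`eigenvalues` must be three finite diffusivities (mm^2/s)", call. = FALSE)
  if (any(diff(ev) > 1e-15) || ev[3] < 0)
    stop("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 >= 0", call. = FALSE)
  d <- as.numeric(direction)
  if (length(d) != 3 || sum(d^2) == 0)
    stop("`direction` must be a nonzero 3-vector", call. = FALSE)
  if (length(fraction) != 1 || fraction < 0)
    stop("`fraction` must be a single nonnegative number", call. = FALSE)
  structure(list(eigenvalues = ev,
                 direction = d / sqrt(sum(d^2)),
                 fraction = fraction),
            class = "tensor_spec")
}

#' Assemble the 3x3 tensor matrix of a compartment
#'
#' The principal eigenvector is the supplied direction; the remaining two
#' axes complete an orthonormal frame (their in-plane orientation is
#' immaterial when `lambda2 == lambda3`, the usual axially symmetric case).
#'
#' @param spec A [tensor_spec()].
#' @return Symmetric 3x3 matrix in mm^2/s.
#' @export
tensor_matrix <- function(spec) {
  stopifnot(inherits(spec, "tensor_spec"))
  v1 <- spec$direction
  # pick a helper axis not parallel to v1, then Gram-Schmidt
  helper <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- helper - sum(helper * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  R <- cbind(v1, v2, v3)
  R %*% diag(spec$eigenvalues) %*% t(R)
}

#' Forward-model DWI signals for a voxel
#'
#' Evaluates the (multi-)tensor signal equation
#' `S = S0 * sum_k f_k * exp(-b * g' D_k g)` for every volume of a gradient
#' scheme.  b0 volumes return `S0` exactly.
#'
#' @param spec A single [tensor_spec()] or a list of them whose fractions
#'   sum to 1 (crossing-fiber voxel).
#' @param scheme A [make_scheme()] gradient scheme.
#' @param S0 Non-diffusion-weighted signal, must be positive.
#' @return Numeric vector of signals, one per volume of the scheme.
#' @examples
#' sch <- make_scheme(21, 1000)
#' iso <- tensor_spec(rep(1e-3, 3))
#' s <- tensor_signal(iso, sch, S0 = 1000)
#' all.equal(s[-1], rep(1000 * exp(-1), 21))  # ADC = 1e-3 along every axis
#' @export
tensor_signal <- function(spec, scheme, S0) {
  validate_scheme(scheme)
  if (length(S0) != 1 || !is.finite(S0) || S0 <= 0)
    stop("`S0` must be a single positive signal value", call. = FALSE)
  specs <- if (inherits(spec, "tensor_spec")) list(spec) else spec
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "tensor_spec")))
    stop("`spec` must be a tensor_spec or a list of tensor_spec", call. = FALSE)
  fr <- vapply(specs, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-12)
    stop("compartment fractions must sum to 1", call. = FALSE)
  G <- scheme$bvecs
  s <- numeric(length(scheme$bvals))
  for (k in seq_along(specs)) {
    D <- tensor_matrix(specs[[k]])
    adc <- rowSums((G %*% D) * G)   # g' D g per volume (0 for the zero b0 row)
    s <- s + fr[k] * exp(-scheme$bvals * adc)
  }
  S0 * s
}

#' Add Rician noise to magnitude MRI signals
#'
#' Magnitude reconstruction of complex Gaussian noise yields Rician-
#' distributed signals: `sqrt((s + n1)^2 + n2^2)` with `n1, n2` independent
#' zero-mean Gaussians of standard deviation `sigma`.  With `sigma = 0` the
#' input is returned unchanged.  Array inputs keep their dimensions.
#'
#' @param signals Numeric vector or array of noise-free magnitudes.
#' @param sigma Noise standard deviation, in signal units; must be >= 0.
#' @param seed Optional integer seed for reproducibility; the caller's
#'   random-number state is left untouched.
#' @return Noisy signals, same shape as the input.
#' @export
add_rician_noise <- function(signals, sigma, seed = NULL) {
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  if (sigma == 0) return(signals)
  noisy <- with_local_seed(seed, {
    n <- length(signals)
    sqrt((signals + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  })
  if (!is.null(dim(signals))) dim(noisy) <- dim(signals)
  noisy
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL uses (and advances) the global stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
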