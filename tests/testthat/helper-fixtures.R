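# Shared fixtures and independent oracles used across the suite.

wm_lambda <- c(1.7e-3, 0.2e-3, 0.2e-3)

# A hand-built 2-direction scheme (x and y axes) for closed-form signal checks.
# Not a valid fitting scheme; used only with tensor_signal().
xy_scheme <- function(b = 1000) {
  structure(list(bvals = c(0, b, b),
                 bvecs = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 n_s = 2L),
            class = "gradient_scheme")
}

# Independent two-pass std/rms GFA, deliberately naive.
gfa_naive <- function(x) {
  s <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  r <- sqrt(mean(x^2))
  s / r
}

# Exact two-sided Wilcoxon signed-rank p by brute-force enumeration of all
# 2^m sign assignments (feasible for m <= 12).
enum_wilcoxon_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  rk <- rank(abs(d))
  M <- sum(rk)
  w_obs <- min(sum(rk[d > 0]), M - sum(rk[d > 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_plus <- as.vector(signs %*% rk)
  mean(pmin(w_plus, M - w_plus) <= w_obs)
}

# Spearman rho via the classical sum-of-squared-rank-differences formula
# (valid only without ties).
spearman_d2 <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}

# Paired pre/post extraction from a cohort table.
paired_delta <- function(tab, col) {
  pre <- tab[tab$timepoint == "pre", ]
  post <- tab[tab$timepoint == "post", ]
  post <- post[match(pre$subject, post$subject), ]
  list(pre = pre[[col]], post = post[[col]],
       delta = post[[col]] - pre[[col]])
}
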