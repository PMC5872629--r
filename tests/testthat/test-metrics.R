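test_that("adc_profile inverts the signal model and applies the clamping rule", {
  sch <- make_scheme(21, 1000)
  s <- tensor_signal(tensor_spec(rep(1e-3, 3)), sch, 1000)
  p <- adc_profile(s, sch)
  expect_equal(unname(p$values), rep(1e-3, 21), tolerance = 1e-15)
  expect_true(p$defined)
  expect_equal(p$n_s, 21L)

  flat <- rep(1000, 22)                 # S_i = S0 everywhere
  expect_equal(unname(adc_profile(flat, sch)$values), rep(0, 21))

  over <- flat; over[-1] <- 1100        # noise overshoot: S_i > S0
  expect_equal(unname(adc_profile(over, sch)$values), rep(0, 21))
  raw <- adc_profile(over, sch, clamp = FALSE)
  expect_true(all(raw$values < 0))

  dead <- flat; dead[1] <- 0            # all b0 signals nonpositive
  expect_false(adc_profile(dead, sch)$defined)
  expect_true(all(is.na(adc_profile(dead, sch)$values)))
})

test_that("GFA matches hand-computed values and handles degenerate profiles", {
  expect_equal(gfa_from_adc_profile(rep(0.7, 21)), 0, tolerance = 1e-12)
  expect_equal(gfa_from_adc_profile(c(0, 0, 1)), 1, tolerance = 1e-15)
  expect_equal(gfa_from_adc_profile(c(1, 2, 3)), sqrt(3 * 2 / (2 * 14)),
               tolerance = 1e-15)
  expect_true(is.na(gfa_from_adc_profile(rep(0, 21))))
  expect_error(gfa_from_adc_profile(1), "at least two")
})

test_that("GFA is bounded, scale-invariant and agrees with the naive std/rms oracle", {
  set.seed(11)
  for (i in 1:200) {
    x <- runif(21, 0, 3e-3)
    g <- gfa_from_adc_profile(x)
    expect_gte(g, 0)
    expect_lte(g, 1)
    expect_equal(g, gfa_naive(x), tolerance = 1e-12)
    expect_equal(gfa_from_adc_profile(x * runif(1, 0.1, 100)), g,
                 tolerance = 1e-12)
  }
  # single-nonzero profiles attain exactly 1, for any length and magnitude
  for (n in c(3, 21, 50)) {
    x <- numeric(n); x[sample(n, 1)] <- runif(1, 1e-5, 1)
    expect_equal(gfa_from_adc_profile(x), 1, tolerance = 1e-12)
  }
})

test_that("log-linear tensor fit recovers known tensors exactly without noise", {
  sch <- make_scheme(21, 1000)
  ft <- fit_tensor(tensor_signal(tensor_spec(wm_lambda, c(1, 0, 0)), sch, 1000), sch)
  expect_equal(ft$eigenvalues, wm_lambda, tolerance = 1e-12)
  iso <- fit_tensor(tensor_signal(tensor_spec(rep(1e-3, 3)), sch, 1000), sch)
  expect_equal(iso$eigenvalues, rep(1e-3, 3), tolerance = 1e-12)
  expect_equal(ft$tensor, t(ft$tensor), tolerance = 1e-15)
})

test_that("tensor fit matches an independent generic least-squares solve", {
  sch <- make_scheme(21, 1000)
  set.seed(3)
  s <- add_rician_noise(tensor_signal(tensor_spec(wm_lambda, c(0.2, -1, 0.4)),
                                      sch, 1000), 1000 / 30, seed = 5)
  ft <- fit_tensor(s, sch)
  # oracle: lm() on the same design
  dw <- sch$bvals > 0
  G <- sch$bvecs[dw, ]
  X <- sch$bvals[dw] * cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
                             2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3],
                             2 * G[, 2] * G[, 3])
  y <- -log(s[dw] / mean(s[!dw]))
  beta <- unname(coef(lm(y ~ X - 1)))
  D <- matrix(c(beta[1], beta[4], beta[5], beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  expect_equal(ft$tensor, D, tolerance = 1e-9)
})

test_that("noisy tensor fits are nearly unbiased for lambda1 at SNR 30", {
  sch <- make_scheme(21, 1000)
  spec <- tensor_spec(wm_lambda, c(1, 0, 0))
  clean <- tensor_signal(spec, sch, 1000)
  l1 <- vapply(1:300, function(i) {
    fit_tensor(add_rician_noise(clean, 1000 / 30, seed = 4000 + i), sch)$eigenvalues[1]
  }, numeric(1))
  expect_equal(mean(l1), 1.7e-3, tolerance = 0.05)
})

test_that("degenerate schemes are rejected by the tensor fit", {
  bad <- structure(list(bvals = c(0, rep(1000, 6)),
                        bvecs = rbind(c(0, 0, 0),
                                      matrix(rep(c(1, 0, 0), 6), ncol = 3,
                                             byrow = TRUE)),
                        n_s = 6L),
                   class = "gradient_scheme")
  s <- tensor_signal(tensor_spec(rep(1e-3, 3)), bad, 1000)
  expect_error(fit_tensor(s, bad), "rank-deficient")
})

test_that("FA matches its closed form and is scale- and rotation-invariant", {
  expect_equal(fa_from_eigenvalues(1, 1, 1), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_equal(fa_from_eigenvalues(wm_lambda), sqrt(2.25 / 2.97),
               tolerance = 1e-12)
  expect_true(is.na(fa_from_eigenvalues(0, 0, 0)))
  expect_equal(fa_from_eigenvalues(wm_lambda * 7), fa_from_eigenvalues(wm_lambda),
               tolerance = 1e-12)
  expect_equal(md_from_eigenvalues(wm_lambda), mean(wm_lambda))
  # rotation invariance through the full forward-model/fit loop
  sch <- make_scheme(21, 1000)
  set.seed(21)
  fas <- vapply(1:20, function(i) {
    d <- rnorm(3)
    ft <- fit_tensor(tensor_signal(tensor_spec(wm_lambda, d), sch, 1000), sch)
    fa_from_eigenvalues(ft$eigenvalues)
  }, numeric(1))
  expect_equal(fas, rep(sqrt(2.25 / 2.97), 20), tolerance = 1e-9)
})

test_that("metric maps apply the voxelwise operation inside the mask only", {
  sch <- make_scheme(21, 1000)
  blocks <- list(a = list(x = 1:3, y = 1:3, z = 1:2,
                          tensors = list(tensor_spec(rep(1e-3, 3)))))
  ph <- build_phantom(c(5, 5, 3), sch, blocks, sigma = 0)
  mask <- truth_mask(ph$truth)
  gfa <- metric_map(ph$dwi, "GFA", mask)
  expect_true(all(abs(gfa$data[mask]) < 1e-12))   # isotropic: GFA = 0
  expect_true(all(is.na(gfa$data[!mask])))
  expect_identical(gfa$valid, mask)

  fib <- list(a = list(x = 1:3, y = 1:3, z = 1:2,
                       tensors = list(tensor_spec(wm_lambda, c(0, 1, 0)))))
  ph2 <- build_phantom(c(5, 5, 3), sch, fib, sigma = 0)
  fa <- metric_map(ph2$dwi, "FA", truth_mask(ph2$truth))
  expect_equal(unname(fa$data[truth_mask(ph2$truth)]),
               rep(sqrt(2.25 / 2.97), sum(truth_mask(ph2$truth))),
               tolerance = 1e-9)
  md <- metric_map(ph2$dwi, "MD", truth_mask(ph2$truth))
  expect_equal(md$data[1, 1, 1], mean(wm_lambda), tolerance = 1e-12)

  expect_error(metric_map(ph$dwi, "GFA", array(TRUE, c(2, 2, 2))), "geometry")
})

test_that("noiseless maps stay within [0, 1] for FA and GFA", {
  sch <- make_scheme(21, 1000)
  ph <- build_phantom(c(14, 14, 5), sch, phantom_blocks(), sigma = 0)
  mask <- truth_mask(ph$truth)
  for (m in c("FA", "GFA")) {
    mp <- metric_map(ph$dwi, m, mask)
    v <- mp$data[mp$valid]
    expect_true(all(v >= 0 & v <= 1))
  }
})
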