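test_that("signed-rank test handles the degenerate and textbook cases", {
  x <- c(3, 5, 1, 8, 2, 9)
  r <- wilcoxon_signed_rank(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$n_effective, 0L)

  # all six differences positive: W- = 0, exact p = 2/2^6
  r2 <- wilcoxon_signed_rank(rep(0, 6), 1:6)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 2 / 64)
  expect_equal(r2$method, "exact")
})

test_that("exact p equals brute-force sign-pattern enumeration for n <= 12", {
  set.seed(17)
  for (n in c(5, 8, 10, 12)) {
    for (rep in 1:10) {
      pre <- rnorm(n)
      post <- pre + rnorm(n, 0.3)
      mine <- wilcoxon_signed_rank(pre, post)
      expect_equal(mine$method, "exact")
      expect_equal(mine$p_value, enum_wilcoxon_p(pre, post), tolerance = 1e-12)
      # base R's exact signed-rank test as a second, independent reference
      ref <- suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                          exact = TRUE, correct = FALSE))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("normal approximation with continuity correction tracks the exact p at n = 20", {
  set.seed(23)
  for (rep in 1:10) {
    # integer differences drawn from 12 magnitudes: ties are guaranteed at
    # n = 20, so the tie-corrected approximation is always taken
    pre <- sample(100, 20)
    post <- pre + sample(c(-6:-1, 1:12), 20, replace = TRUE)
    a <- wilcoxon_signed_rank(pre, post)
    expect_equal(a$method, "normal-approximation")
    expect_lt(abs(a$p_value - enum_wilcoxon_p(pre, post)), 0.01)
  }
})

test_that("zero differences are discarded before ranking", {
  pre <- c(1, 2, 3, 4, 5, 6, 7)
  post <- c(1, 2, 3, 6, 8, 11, 15)  # three zeros dropped, four distinct positive
  r <- wilcoxon_signed_rank(pre, post)
  expect_equal(r$n_effective, 4L)
  expect_equal(r$p_value, enum_wilcoxon_p(pre, post), tolerance = 1e-12)
})

test_that("Spearman matches the rank-difference formula and reference implementation", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  r <- spearman_rho(x, y)
  expect_equal(r$rho, spearman_d2(x, y), tolerance = 1e-12)   # = 0.8
  expect_equal(r$rho, unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  expect_equal(r$r_squared, r$rho^2, tolerance = 1e-15)

  expect_equal(spearman_rho(1:8, -(1:8))$rho, -1)
  expect_equal(spearman_rho(c(3, 1, 2), c(30, 10, 20))$rho, 1)
  set.seed(31)
  for (rep in 1:20) {
    a <- rnorm(15)
    b <- rnorm(15) + 0.5 * a
    mine <- spearman_rho(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    # invariance under strictly monotone transforms
    expect_equal(spearman_rho(exp(a), b)$rho, mine$rho, tolerance = 1e-12)
    expect_equal(spearman_rho(a, qlogis(pnorm(b)))$rho, mine$rho,
                 tolerance = 1e-12)
  }
})

test_that("Spearman handles ties via midranks and flags zero-variance input", {
  a <- c(1, 1, 2, 3, 3, 4)
  b <- c(2, 1, 3, 3, 5, 6)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(spearman_rho(a, b)$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_true(spearman_rho(rep(1, 5), 1:5)$degenerate)
})

test_that("analyze_cohort mirrors the study's reporting structure", {
  tab <- simulate_cohort(cohort_spec(seed = 42))
  rep <- analyze_cohort(tab)
  expect_s3_class(rep, "cohort_report")
  expect_equal(nrow(rep$roi_table), 4)
  expect_setequal(rep$roi_table$roi,
                  c("ba4_lesioned", "ba4_nonlesioned",
                    "ba6_lesioned", "ba6_nonlesioned"))
  expect_true(all(c("fa_pre_mean", "fa_post_mean", "fa_p", "gfa_pre_mean",
                    "gfa_post_mean", "gfa_p", "rho_fma", "p_fma", "rho_lpt",
                    "r2_lpt", "p_lpt") %in% names(rep$roi_table)))
  expect_equal(rep$roi_table$r2_lpt, rep$roi_table$rho_lpt^2, tolerance = 1e-12)
  expect_equal(rep$motor_summary$measure, c("fma", "wmft_rate", "wmft_lpt"))
  expect_true(all(rep$roi_table$gfa_p >= 0 & rep$roi_table$gfa_p <= 1))
  # missing columns are named in the error
  expect_error(analyze_cohort(tab[, setdiff(names(tab), "wmft_lpt")]),
               "wmft_lpt")
  expect_error(analyze_cohort(tab[, setdiff(names(tab), "fa_ba6_lesioned")]),
               "ba6_lesioned")
})

test_that("null cohorts keep the ROI tests near their nominal type-I level", {
  rois <- default_roi_params()
  rois$fa_post_mean <- rois$fa_pre_mean
  rois$gfa_post_mean <- rois$gfa_pre_mean
  null_spec <- cohort_spec(rois = rois, rho_star = 0,
                           fma_delta_mean = 0, lpt_delta_mean = 0)
  ps <- vapply(1:50, function(i) {
    analyze_cohort(simulate_cohort(null_spec, seed = 5000 + i))$roi_table$gfa_p
  }, numeric(4))
  expect_lt(mean(ps < 0.05), 0.15)   # ~5% expected, allow Monte-Carlo slack
})

test_that("holm adjustment is available but off by default", {
  tab <- simulate_cohort(cohort_spec(seed = 8))
  raw <- analyze_cohort(tab)
  adj <- analyze_cohort(tab, p_adjust = "holm")
  expect_true(all(adj$roi_table$gfa_p >= raw$roi_table$gfa_p - 1e-15))
})
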