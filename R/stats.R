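#' Wilcoxon signed-rank test for paired pre/post samples
#'
#' Classical paired signed-rank test on differences `post - pre`.  Zero
#' differences are discarded (Wilcoxon's rule, as SPSS applies); absolute
#' differences are ranked with midranks for ties; the statistic is
#' `W = min(W+, W-)`.  The two-sided p-value is exact — computed from the
#' full null distribution of `W+` over all sign assignments — whenever the
#' effective n is at most 20 and there are no ties among the absolute
#' differences; otherwise a normal approximation with tie correction and a
#' continuity correction is used.
#'
#' @param pre,post Numeric vectors of paired observations (same length,
#'   n >= 3, no missing values).
#' @return A `signed_rank_test` list: `statistic` (W), `p_value`
#'   (two-sided), `n`, `n_effective` (after dropping zero differences),
#'   `method` (`"exact"` or `"normal-approximation"`) and `degenerate`
#'   (`TRUE` when every difference is zero, in which case `p_value = 1`).
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + c(1, 2, 3, 4, 5, 6))$p_value  # 0.03125
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post))
    stop("`pre` and `post` must be paired vectors of equal length", call. = FALSE)
  if (length(pre) < 3)
    stop("at least 3 pairs are required", call. = FALSE)
  if (anyNA(pre) || anyNA(post))
    stop("missing values in paired sample", call. = FALSE)
  d <- post - pre
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(structure(list(statistic = 0, p_value = 1, n = length(pre),
                          n_effective = 0L, method = "degenerate",
                          degenerate = TRUE),
                     class = "signed_rank_test"))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  w_minus <- sum(rk[d < 0])
  w <- min(w_plus, w_minus)
  ties <- anyDuplicated(abs(d)) > 0
  if (m <= 20 && !ties) {
    # exact null distribution of W+ by convolution over ranks 1..m
    counts <- c(1, numeric(m * (m + 1) / 2))
    for (k in seq_len(m)) {
      shifted <- c(numeric(k), counts[seq_len(length(counts) - k)])
      counts <- counts + shifted
    }
    # symmetric distribution: two-sided p = P(W+ <= w) + P(W+ >= M - w)
    p <- min(1, 2 * sum(counts[seq_len(w + 1)]) / 2^m)
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(rk)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu + 0.5) / sqrt(sig2)     # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal-approximation"
  }
  structure(list(statistic = w, p_value = p, n = length(pre),
                 n_effective = m, method = method, degenerate = FALSE),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, p = %.4g (%s, n_eff = %d)\n",
              x$statistic, x$p_value, x$method, x$n_effective))
  invisible(x)
}

#' Spearman rank correlation with t-based p-value
#'
#' `rho` is the Pearson correlation of the midranks of `x` and `y`; the
#' two-sided p-value comes from `t = rho * sqrt((n-2) / (1-rho^2))` on
#' `n - 2` degrees of freedom.  The squared correlation `R^2 = rho^2` is
#' reported alongside, as clinical studies often print it.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, no missing values).
#' @return A `spearman_cor` list: `rho`, `r_squared`, `p_value`, `n`,
#'   `degenerate` (`TRUE`, with `NA` estimates, when either input has zero
#'   rank variance).
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho  # 0.7
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("at least 3 observations are required", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(list(rho = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_, n = n, degenerate = TRUE),
                     class = "spearman_cor"))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, r_squared = rho^2, p_value = p, n = n,
                 degenerate = FALSE),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman: rho = %.4g (R^2 = %.4g), p = %.4g, n = %d\n",
              x$rho, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Full pre/post cohort analysis
#'
#' Reduces a cohort table to the study's reporting structure: per ROI, the
#' pre and post mean (+/- SD) of FA and GFA with Wilcoxon signed-rank
#' p-values for the pre/post change, and Spearman correlations of the
#' per-subject GFA change against the FMA change and the WMFT-lpt change;
#' plus cohort-level motor summaries (FMA, WMFT mean rate, WMFT-lpt) with
#' their own signed-rank p-values.
#'
#' @param table A `cohort_table` from [simulate_cohort()], or any tibble
#'   with columns `subject`, `timepoint` (`pre`/`post`), `fma`,
#'   `wmft_rate`, `wmft_lpt` and per-ROI `fa_<roi>` / `gfa_<roi>` columns.
#' @param p_adjust Multiple-testing adjustment for the ROI-level p-values,
#'   a [stats::p.adjust()] method; `"none"` (default) matches conventional
#'   single-test reporting, `"holm"` is available.
#' @return A `cohort_report` list with tibbles `roi_table` (one row per
#'   ROI) and `motor_summary` (one row per clinical measure).
#' @export
analyze_cohort <- function(table, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("subject", "timepoint", "fma", "wmft_rate", "wmft_lpt")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rois <- sub("^gfa_", "", grep("^gfa_", names(table), value = TRUE))
  if (!length(rois)) stop("cohort table has no gfa_<roi> columns", call. = FALSE)
  fa_miss <- rois[!paste0("fa_", rois) %in% names(table)]
  if (length(fa_miss))
    stop("missing FA columns for ROI(s): ", paste(fa_miss, collapse = ", "),
         call. = FALSE)

  pre <- table[table$timepoint == "pre", ]
  post <- table[table$timepoint == "post", ]
  ord <- match(pre$subject, post$subject)
  if (anyNA(ord) || nrow(pre) != nrow(post))
    stop("unmatched pre/post subjects in cohort table", call. = FALSE)
  post <- post[ord, ]

  d_fma <- post$fma - pre$fma
  d_lpt <- post$wmft_lpt - pre$wmft_lpt

  roi_rows <- lapply(rois, function(r) {
    fa0 <- pre[[paste0("fa_", r)]];  fa1 <- post[[paste0("fa_", r)]]
    g0 <- pre[[paste0("gfa_", r)]];  g1 <- post[[paste0("gfa_", r)]]
    dg <- g1 - g0
    c_fma <- spearman_rho(dg, d_fma)
    c_lpt <- spearman_rho(dg, d_lpt)
    tibble::tibble(
      roi = r,
      fa_pre_mean = mean(fa0), fa_pre_sd = stats::sd(fa0),
      fa_post_mean = mean(fa1), fa_post_sd = stats::sd(fa1),
      fa_p = wilcoxon_signed_rank(fa0, fa1)$p_value,
      gfa_pre_mean = mean(g0), gfa_pre_sd = stats::sd(g0),
      gfa_post_mean = mean(g1), gfa_post_sd = stats::sd(g1),
      gfa_p = wilcoxon_signed_rank(g0, g1)$p_value,
      rho_fma = c_fma$rho, p_fma = c_fma$p_value,
      rho_lpt = c_lpt$rho, r2_lpt = c_lpt$r_squared, p_lpt = c_lpt$p_value)
  })
  roi_table <- do.call(rbind, roi_rows)
  if (p_adjust != "none") {
    roi_table$fa_p <- stats::p.adjust(roi_table$fa_p, p_adjust)
    roi_table$gfa_p <- stats::p.adjust(roi_table$gfa_p, p_adjust)
  }

  motor <- lapply(c(fma = "fma", wmft_rate = "wmft_rate",
                    wmft_lpt = "wmft_lpt"), function(col) {
    tibble::tibble(measure = col,
                   pre_mean = mean(pre[[col]]), pre_sd = stats::sd(pre[[col]]),
                   post_mean = mean(post[[col]]), post_sd = stats::sd(post[[col]]),
                   p = wilcoxon_signed_rank(pre[[col]], post[[col]])$p_value)
  })
  structure(list(roi_table = roi_table,
                 motor_summary = do.call(rbind, unname(motor)),
                 n_subjects = nrow(pre)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 4, ...) {
  cat(sprintf("<cohort_report> n = %d subjects\n\nMotor function:\n", x$n_subjects))
  print(as.data.frame(x$motor_summary), digits = digits, row.names = FALSE)
  cat("\nROI metrics (pre/post means, signed-rank p, dGFA correlations):\n")
  print(as.data.frame(x$roi_table), digits = digits, row.names = FALSE)
  invisible(x)
}
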