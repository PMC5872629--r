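#' Specify a synthetic pre/post rehabilitation cohort
#'
#' Defines the generative model for a paired-design cohort: per-ROI FA and
#' GFA means/SDs before and after the intervention, motor-score
#' distributions (Fugl-Meyer assessment and Wolf Motor Function Test log
#' performance time), and a planted Spearman correlation `rho_star` between
#' the per-subject GFA change in the lesioned primary-motor ROI and the
#' WMFT-lpt change.  Defaults reproduce the published group-level values of
#' a 36-patient rTMS + occupational-therapy study arm.
#'
#' Per-subject change scores are modelled directly: `post = pre + delta`
#' with `delta ~ N(post_mean - pre_mean, delta_sd)`, the paired-design
#' analogue of drawing both timepoints with a within-subject correlation.
#' `delta_sd` defaults to the pre-intervention SD of each measure.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param rois Data frame with columns `roi`, `fa_pre_mean`, `fa_pre_sd`,
#'   `fa_post_mean`, `fa_post_sd`, `fa_delta_sd`, and the same six for
#'   `gfa`.  Default: the four motor-area ROIs at their published values.
#' @param rho_star Planted Spearman correlation between dGFA (lesioned BA4)
#'   and dWMFT-lpt, in [-1, 1].
#' @param fma_pre_mean,fma_pre_sd,fma_delta_mean,fma_delta_sd FMA total
#'   score distribution (points, 0-66).
#' @param lpt_pre_mean,lpt_pre_sd,lpt_delta_mean,lpt_delta_sd WMFT log
#'   performance time distribution (log-seconds, capped at `ln(120)`).
#' @param seed Default seed used by [simulate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 36,
                        rois = default_roi_params(),
                        rho_star = -0.363,
                        fma_pre_mean = 45.4, fma_pre_sd = 12.3,
                        fma_delta_mean = 5.5, fma_delta_sd = 6,
                        lpt_pre_mean = 2.8, lpt_pre_sd = 1.2,
                        lpt_delta_mean = -0.4, lpt_delta_sd = 0.5,
                        seed = 1L) {
  if (n_subjects < 3) stop("`n_subjects` must be >= 3", call. = FALSE)
  if (!is.finite(rho_star) || abs(rho_star) > 1)
    stop("`rho_star` must lie in [-1, 1]", call. = FALSE)
  rois <- tibble::as_tibble(rois)
  need <- c("roi", paste0(rep(c("fa_", "gfa_"), each = 5),
                          c("pre_mean", "pre_sd", "post_mean", "post_sd",
                            "delta_sd")))
  miss <- setdiff(need, names(rois))
  if (length(miss))
    stop("`rois` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sds <- unlist(rois[grep("_sd$", names(rois))])
  if (any(!is.finite(sds) | sds <= 0))
    stop("all SDs must be positive", call. = FALSE)
  if (!"ba4_lesioned" %in% rois$roi)
    stop("`rois` must include the 'ba4_lesioned' ROI (correlation anchor)",
         call. = FALSE)
  if (any(c(fma_pre_sd, fma_delta_sd, lpt_pre_sd, lpt_delta_sd) <= 0))
    stop("all SDs must be positive", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), rois = rois,
                 rho_star = rho_star,
                 fma_pre_mean = fma_pre_mean, fma_pre_sd = fma_pre_sd,
                 fma_delta_mean = fma_delta_mean, fma_delta_sd = fma_delta_sd,
                 lpt_pre_mean = lpt_pre_mean, lpt_pre_sd = lpt_pre_sd,
                 lpt_delta_mean = lpt_delta_mean, lpt_delta_sd = lpt_delta_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Published per-ROI FA/GFA group parameters
#'
#' Pre/post means and SDs of FA and GFA in the white matter under the
#' lesioned and nonlesioned BA4 and BA6, as reported for the 36-patient
#' study arm the defaults emulate.  Change-score SDs default to the
#' pre-intervention SD.
#'
#' @return A tibble with one row per ROI.
#' @export
default_roi_params <- function() {
  p <- tibble::tribble(
    ~roi,              ~fa_pre_mean, ~fa_pre_sd, ~fa_post_mean, ~fa_post_sd,
                       ~gfa_pre_mean, ~gfa_pre_sd, ~gfa_post_mean, ~gfa_post_sd,
    "ba4_lesioned",    0.194, 0.023, 0.195, 0.025, 0.181, 0.006,  0.186, 0.005,
    "ba4_nonlesioned", 0.207, 0.018, 0.211, 0.013, 0.193, 0.012,  0.200, 0.014,
    "ba6_lesioned",    0.179, 0.006, 0.181, 0.004, 0.165, 0.0002, 0.168, 0.001,
    "ba6_nonlesioned", 0.189, 0.002, 0.190, 0.003, 0.172, 0.007,  0.175, 0.005
  )
  p$fa_delta_sd <- p$fa_pre_sd
  p$gfa_delta_sd <- p$gfa_pre_sd
  p
}

#' Simulate a pre/post cohort with planted effects
#'
#' Draws per-subject ROI summaries and clinical scores under a
#' [cohort_spec()].  The change in GFA of the lesioned BA4 ROI and the
#' change in WMFT log performance time are coupled through a Gaussian
#' copula whose Pearson parameter `r = 2 * sin(pi * rho_star / 6)` yields
#' the planted Spearman correlation in expectation.  GFA and FA values are
#' clipped to [0, 1]; FMA is rounded and clipped to 0-66; log performance
#' times respect the 120 s task cap.  WMFT task times are back-generated by
#' setting all 15 tasks to `exp(lpt)`, so the log-of-mean-time transform
#' reproduces the drawn lpt exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the spec's seed.  The draw is
#'   deterministic given the seed and does not disturb the caller's RNG.
#' @return A `cohort_table`: tibble with one row per subject x timepoint
#'   and columns `subject`, `timepoint` (`"pre"`/`"post"`), `fma`,
#'   `task_01` ... `task_15` (s), `wmft_rate` (per min), `wmft_lpt`
#'   (log-s), and `fa_<roi>` / `gfa_<roi>` per ROI.
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_local_seed(seed, {
    # Gaussian copula scores for the planted Spearman correlation
    r <- 2 * sin(pi * spec$rho_star / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)

    clip01 <- function(x) pmin(pmax(x, 0), 1)
    rois <- spec$rois
    gfa_pre <- gfa_post <- fa_pre <- fa_post <-
      matrix(NA_real_, n, nrow(rois), dimnames = list(NULL, rois$roi))
    for (i in seq_len(nrow(rois))) {
      p <- rois[i, ]
      gp <- stats::rnorm(n, p$gfa_pre_mean, p$gfa_pre_sd)
      dz <- if (p$roi == "ba4_lesioned") z1 else stats::rnorm(n)
      gd <- (p$gfa_post_mean - p$gfa_pre_mean) + p$gfa_delta_sd * dz
      gfa_pre[, i] <- clip01(gp)
      gfa_post[, i] <- clip01(gp + gd)
      fp <- stats::rnorm(n, p$fa_pre_mean, p$fa_pre_sd)
      fd <- (p$fa_post_mean - p$fa_pre_mean) + p$fa_delta_sd * stats::rnorm(n)
      fa_pre[, i] <- clip01(fp)
      fa_post[, i] <- clip01(fp + fd)
    }

    fma_pre <- pmin(pmax(round(stats::rnorm(n, spec$fma_pre_mean,
                                            spec$fma_pre_sd)), 0), 66)
    fma_post <- pmin(pmax(round(fma_pre +
      stats::rnorm(n, spec$fma_delta_mean, spec$fma_delta_sd)), 0), 66)

    # lpt drawn from a normal truncated at ln(120) so the task-time cap
    # is respected by construction; the post delta carries copula score z2
    cap <- log(120)
    u <- stats::runif(n) * stats::pnorm(cap, spec$lpt_pre_mean, spec$lpt_pre_sd)
    lpt_pre <- stats::qnorm(u, spec$lpt_pre_mean, spec$lpt_pre_sd)
    lpt_post <- pmin(lpt_pre + spec$lpt_delta_mean + spec$lpt_delta_sd * z2, cap)

    subj <- sprintf("S%02d", seq_len(n))
    make_rows <- function(tp, fma, lpt, fa, gfa) {
      tasks <- matrix(rep(exp(lpt), 15), n, 15)
      colnames(tasks) <- sprintf("task_%02d", 1:15)
      out <- tibble::tibble(subject = subj, timepoint = tp, fma = fma)
      out <- cbind(out, tibble::as_tibble(tasks))
      out$wmft_rate <- apply(tasks, 1, wmft_mean_rate)
      out$wmft_lpt <- apply(tasks, 1, wmft_lpt)
      colnames(fa) <- paste0("fa_", colnames(fa))
      colnames(gfa) <- paste0("gfa_", colnames(gfa))
      tibble::as_tibble(cbind(out, fa, gfa))
    }
    tab <- rbind(make_rows("pre", fma_pre, lpt_pre, fa_pre, gfa_pre),
                 make_rows("post", fma_post, lpt_post, fa_post, gfa_post))
    class(tab) <- c("cohort_table", class(tab))
    tab
  })
}
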