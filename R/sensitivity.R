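# Sensitivity analyses: MR-PRESSO (global / outlier / distortion),
# leave-one-out domination screening, and the Steiger directionality test.

# Leave-one-out zero-intercept WLS slopes with weights w = 1/se_out^2, and
# the weighted residual of each SNP against the fit that excludes it.
# Vectorised: x, y, w are length-k vectors or n x k matrices.
.loo_residuals <- function(x, y, w) {
  if (is.matrix(x)) {
    wm <- matrix(w, nrow(x), ncol(x), byrow = TRUE)
    sxy <- rowSums(wm * x * y)
    sxx <- rowSums(wm * x * x)
    beta_loo <- (sxy - wm * x * y) / (sxx - wm * x * x)
    res <- wm * (y - beta_loo * x)^2
  } else {
    sxy <- sum(w * x * y)
    sxx <- sum(w * x * x)
    beta_loo <- (sxy - w * x * y) / (sxx - w * x * x)
    res <- w * (y - beta_loo * x)^2
  }
  list(beta_loo = beta_loo, res = res)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' The observed residual sum of squares weighs each SNP's outcome effect
#' against the value predicted by the inverse-variance fit excluding that
#' SNP. The null distribution is built from \code{n_sim} parametric draws
#' of both summary statistics under the fitted no-pleiotropy model; the
#' global p-value is \code{(1 + #(sim RSS >= observed)) / (n_sim + 1)}.
#' Per-SNP outlier p-values compare each observed residual with its own
#' simulated distribution and are Bonferroni-adjusted before the
#' \code{outlier_alpha} cut. The distortion test compares the shift in the
#' IVW estimate caused by removing the detected outliers against removals
#' of random SNP sets of the same size.
#'
#' @param h A \code{harmonized_set} with at least 4 instruments.
#' @param n_sim Number of parametric simulations (>= 1000).
#' @param outlier_alpha Per-SNP significance level after Bonferroni
#'   adjustment.
#' @param seed Integer seed; identical inputs and seed give identical
#'   results.
#' @param n_distortion Random outlier sets drawn for the distortion null.
#' @return An object of class \code{mr_presso}: \code{global_rss},
#'   \code{global_pval}, \code{outlier_pvals} (Bonferroni-adjusted),
#'   \code{outliers} (integer indices), \code{distortion_pval},
#'   \code{beta_all}, \code{beta_corrected}, \code{n_sim}, \code{seed}.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1L,
                      n_distortion = 1000) {
  k <- nrow(h)
  if (k < 4) .stopf("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 1000) .stopf("n_sim must be >= 1000")
  x <- h$beta_exp; y <- h$beta_out
  se_x <- h$se_exp; se_y <- h$se_out
  w <- 1 / se_y^2

  obs <- .loo_residuals(x, y, w)
  rss_obs <- sum(obs$res)
  beta_all <- sum(w * x * y) / sum(w * x^2)

  .with_seed(seed, {
    xs <- matrix(stats::rnorm(n_sim * k, rep(x, each = n_sim),
                              rep(se_x, each = n_sim)), n_sim, k)
    ys <- matrix(stats::rnorm(n_sim * k, rep(obs$beta_loo * x, each = n_sim),
                              rep(se_y, each = n_sim)), n_sim, k)
    sim <- .loo_residuals(xs, ys, w)
    rss_sim <- rowSums(sim$res)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    raw <- (1 + colSums(sim$res >= matrix(obs$res, n_sim, k, byrow = TRUE))) /
      (n_sim + 1)
    adj <- pmin(1, raw * k)
    outliers <- which(adj < outlier_alpha)

    beta_corrected <- beta_all
    distortion_pval <- NA_real_
    if (length(outliers) > 0 && length(outliers) < k - 1) {
      kept <- setdiff(seq_len(k), outliers)
      beta_corrected <- sum(w[kept] * x[kept] * y[kept]) /
        sum(w[kept] * x[kept]^2)
      d_obs <- beta_all - beta_corrected
      d_null <- vapply(seq_len(n_distortion), function(b) {
        drop <- sample.int(k, length(outliers))
        kb <- setdiff(seq_len(k), drop)
        beta_all - sum(w[kb] * x[kb] * y[kb]) / sum(w[kb] * x[kb]^2)
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) /
        (n_distortion + 1)
    }

    out <- list(global_rss = rss_obs, global_pval = global_pval,
                outlier_pvals = adj, outliers = outliers,
                distortion_pval = distortion_pval,
                beta_all = beta_all, beta_corrected = beta_corrected,
                n_sim = n_sim, seed = seed)
    class(out) <- "mr_presso"
    out
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.4g (%d sims)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outliers)) {
    cat("outliers:", paste(x$outliers, collapse = ", "),
        sprintf("| distortion p = %.3g\n", x$distortion_pval))
    cat(sprintf("IVW beta %.4g -> %.4g after outlier removal\n",
                x$beta_all, x$beta_corrected))
  } else {
    cat("no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out domination screen
#'
#' Recomputes the auto-model IVW estimate excluding each instrument in
#' turn. The association is flagged as dominated by single SNPs when the
#' all-SNP result is nominally significant but excluding some single SNP
#' either lifts the p-value above \code{nominal_alpha} or flips the sign of
#' the estimate.
#'
#' @param h A \code{harmonized_set} with at least 2 instruments.
#' @param nominal_alpha Nominal significance level.
#' @return An object of class \code{mr_loo}: \code{table} (one row per
#'   SNP: \code{snp}, \code{beta_without}, \code{pval_without}),
#'   \code{dominated}, \code{dominating_snps}, \code{beta_all},
#'   \code{pval_all}.
#' @export
leave_one_out <- function(h, nominal_alpha = 0.05) {
  k <- nrow(h)
  if (k < 2) .stopf("leave-one-out requires at least 2 instruments")
  full <- mr_ivw(h, model = "auto")
  rows <- lapply(seq_len(k), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], model = "auto")
    data.frame(snp = h$snp[j], beta_without = fit$estimate$beta,
               pval_without = fit$estimate$pval, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  dominating <- character(0)
  dominated <- FALSE
  if (full$estimate$pval < nominal_alpha) {
    hit <- tab$pval_without >= nominal_alpha |
      sign(tab$beta_without) != sign(full$estimate$beta)
    dominated <- any(hit)
    dominating <- tab$snp[hit]
  }
  out <- list(table = tab, dominated = dominated,
              dominating_snps = dominating,
              beta_all = full$estimate$beta, pval_all = full$estimate$pval)
  class(out) <- "mr_loo"
  out
}

#' @export
print.mr_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out: all-SNP IVW beta = %.4g (p = %.3g)\n",
              x$beta_all, x$pval_all))
  if (x$dominated) {
    cat("dominated by:", paste(x$dominating_snps, collapse = ", "), "\n")
  } else {
    cat("no single SNP dominates the result\n")
  }
  invisible(x)
}

#' Steiger test of causal direction
#'
#' Sums the per-instrument variance explained on the exposure and the
#' outcome (each via the regression-t identity, see
#' \code{\link{per_snp_r2}}) and tests their difference with a z-test on
#' Fisher-transformed correlations \eqn{\sqrt{R^2}} using the respective
#' sample sizes. The assumed exposure-to-outcome direction is supported
#' when the instruments explain more variance in the exposure.
#'
#' @param h A \code{harmonized_set}.
#' @param n_exp,n_out Sample sizes; taken from the \code{n_exp} /
#'   \code{n_out} columns when NULL.
#' @return An object of class \code{mr_steiger}: \code{r2_exposure},
#'   \code{r2_outcome}, \code{correct_direction}, \code{direction},
#'   \code{z}, \code{pval}.
#' @export
mr_steiger <- function(h, n_exp = NULL, n_out = NULL) {
  if (is.null(n_exp)) n_exp <- stats::median(h$n_exp)
  if (is.null(n_out)) n_out <- stats::median(h$n_out)
  if (is.na(n_exp) || is.na(n_out)) {
    .stopf("Steiger test needs sample sizes for both traits")
  }
  r2e <- min(sum(per_snp_r2(h$beta_exp, h$se_exp, n_exp)), 1 - 1e-12)
  r2o <- min(sum(per_snp_r2(h$beta_out, h$se_out, n_out)), 1 - 1e-12)
  z <- (atanh(sqrt(r2e)) - atanh(sqrt(r2o))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  pval <- 2 * stats::pnorm(-abs(z))
  direction <- if (r2e > r2o) {
    "exposure_to_outcome"
  } else if (r2e < r2o) {
    "outcome_to_exposure"
  } else {
    "ambiguous"
  }
  out <- list(r2_exposure = r2e, r2_outcome = r2o,
              correct_direction = r2e > r2o, direction = direction,
              z = z, pval = pval)
  class(out) <- "mr_steiger"
  out
}

#' @export
print.mr_steiger <- function(x, ...) {
  cat(sprintf("Steiger: R2(exposure) = %.4g, R2(outcome) = %.4g -> %s (z = %.3g, p = %.3g)\n",
              x$r2_exposure, x$r2_outcome, x$direction, x$z, x$pval))
  invisible(x)
}
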