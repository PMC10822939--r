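# Causal-effect estimators on harmonized instrument sets: per-SNP Wald
# ratios, fixed/random-effects IVW with Cochran's Q model selection,
# MR-Egger regression, and the bootstrap weighted median.

#' Per-SNP Wald ratio
#'
#' \code{ratio = beta_out / beta_exp} with first-order delta-method
#' standard error \code{se_out / |beta_exp|} (exposure-side uncertainty
#' ignored, the convention of standard two-sample MR tooling). A
#' second-order standard error incorporating \code{se_exp} is available
#' behind a flag.
#'
#' @param beta_exp,se_exp SNP-exposure effect and standard error.
#' @param beta_out,se_out SNP-outcome effect and standard error.
#' @param second_order Use the second-order delta-method standard error.
#' @return A list with numeric vectors \code{ratio} and \code{ratio_se}.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (any(beta_exp == 0)) .stopf("undefined ratio: beta_exp == 0")
  ratio <- beta_out / beta_exp
  if (second_order) {
    ratio_se <- sqrt(se_out^2 / beta_exp^2 +
                       beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    ratio_se <- se_out / abs(beta_exp)
  }
  list(ratio = ratio, ratio_se = ratio_se)
}

# Build the one-row estimate table shared by every method. A NULL df means
# a standard-normal reference; otherwise a t reference on df degrees of
# freedom.
.mr_estimate <- function(method, beta, se, n_snps, df = NULL, note = "") {
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  z <- beta / se
  pval <- if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
  pval <- min(max(pval, .Machine$double.xmin), 1)
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - crit * se, ci_high = beta + crit * se,
             or_ = exp(beta), or_low = exp(beta - crit * se),
             or_high = exp(beta + crit * se),
             pval = pval, n_snps = n_snps, note = note,
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j (r_j - \hat\beta)^2 / se_j^2}, referred to a chi-square
#' distribution on \code{k - 1} degrees of freedom.
#'
#' @param ratios Per-SNP Wald ratios.
#' @param ratio_ses Their standard errors.
#' @param pooled_beta The pooled (fixed-effects IVW) estimate.
#' @return A list with \code{q}, \code{df}, \code{pval}.
#' @export
cochran_q <- function(ratios, ratio_ses, pooled_beta) {
  k <- length(ratios)
  if (k < 2) .stopf("Cochran's Q requires at least 2 SNPs")
  q <- sum(((ratios - pooled_beta) / ratio_ses)^2)
  df <- k - 1
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effects IVW pools the per-SNP Wald ratios with weights
#' \eqn{w_j = 1 / se_j^2}; the random-effects variant inflates the standard
#' error multiplicatively by \eqn{\sqrt{\max(1, Q / df)}}. With
#' \code{model = "auto"} the random-effects model is used when Cochran's Q
#' is significant at p < 0.05, the fixed-effects model otherwise. A single
#' instrument reduces to the Wald ratio with Q undefined.
#'
#' @param h A \code{harmonized_set} (see \code{\link{harmonize}}).
#' @param model One of \code{"auto"}, \code{"fixed"}, \code{"random"}.
#' @return A list of class \code{mr_ivw}: \code{estimate} (the selected
#'   model's one-row estimate table), \code{fixed}, \code{random},
#'   \code{heterogeneity} (\code{q}, \code{df}, \code{pval}).
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  k <- nrow(h)
  if (k == 0) .stopf("no instruments")
  wr <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  w <- 1 / wr$ratio_se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))

  if (k == 1) {
    est <- .mr_estimate("wald", beta, se_fixed, 1L,
                        note = "single instrument; Q undefined")
    out <- list(estimate = est, fixed = est, random = est,
                heterogeneity = list(q = NA_real_, df = 0L, pval = NA_real_))
    class(out) <- "mr_ivw"
    return(out)
  }

  het <- cochran_q(wr$ratio, wr$ratio_se, beta)
  se_random <- se_fixed * sqrt(max(1, het$q / het$df))
  fixed <- .mr_estimate("ivw_fixed", beta, se_fixed, k)
  random <- .mr_estimate("ivw_random", beta, se_random, k)
  chosen <- switch(model,
    fixed = fixed,
    random = random,
    auto = if (!is.na(het$pval) && het$pval < 0.05) random else fixed)
  chosen$note <- sprintf("selected by %s rule (Q p = %.3g)", model, het$pval)
  out <- list(estimate = chosen, fixed = fixed, random = random,
              heterogeneity = het)
  class(out) <- "mr_ivw"
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with weights \eqn{1 / se_{out}^2} and a free intercept, after
#' orienting every SNP so its exposure effect is non-negative. The slope is
#' the pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Both are referred to a t distribution on
#' \code{k - 2} degrees of freedom.
#'
#' @param h A \code{harmonized_set} with at least 3 instruments.
#' @return A list of class \code{mr_egger}: \code{slope}, \code{slope_se},
#'   \code{intercept}, \code{intercept_se}, \code{intercept_pval},
#'   \code{df}, and \code{estimate} (one-row estimate table for the slope).
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) .stopf("insufficient instruments for Egger")
  sgn <- ifelse(h$beta_exp < 0, -1, 1)
  x <- h$beta_exp * sgn
  y <- h$beta_out * sgn
  fit <- stats::lm(y ~ x, weights = 1 / h$se_out^2)
  cf <- summary(fit)$coefficients
  est <- .mr_estimate("egger", cf["x", 1], cf["x", 2], k, df = k - 2)
  out <- list(slope = cf["x", 1], slope_se = cf["x", 2],
              slope_pval = est$pval,
              intercept = cf["(Intercept)", 1],
              intercept_se = cf["(Intercept)", 2],
              intercept_pval = cf["(Intercept)", 4],
              df = k - 2L, estimate = est)
  class(out) <- "mr_egger"
  out
}

# Bowden-style weighted median of ratios: linear interpolation of the
# standardized cumulative weight function at 0.5.
.weighted_median <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  below <- max(which(p < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) * (0.5 - p[below]) / (p[below + 1] - p[below])
}

#' Weighted-median causal estimate
#'
#' Weighted median of the per-SNP Wald ratios with inverse-variance
#' weights; consistent when at least half the instrument weight comes from
#' valid instruments. The standard error comes from a seeded parametric
#' bootstrap: ratios are re-drawn as \code{N(ratio_j, ratio_se_j)} with the
#' weights held fixed, and the median recomputed.
#'
#' @param h A \code{harmonized_set} with at least 3 instruments.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row estimate table (method \code{weighted_median}).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  k <- nrow(h)
  if (k < 3) .stopf("weighted median requires at least 3 instruments")
  if (n_boot < 100) .stopf("n_boot must be >= 100")
  wr <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  w <- 1 / wr$ratio_se^2
  beta <- .weighted_median(wr$ratio, w)
  boots <- .with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * k, mean = rep(wr$ratio, each = n_boot),
                                 sd = rep(wr$ratio_se, each = n_boot)),
                    nrow = n_boot, ncol = k)
    apply(draws, 1L, .weighted_median, weights = w)
  })
  se <- stats::sd(boots)
  .mr_estimate("weighted_median", beta, se, k,
               note = sprintf("bootstrap se, %d resamples", n_boot))
}
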