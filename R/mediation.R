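# Product-of-coefficients mediation for exposure -> mediator -> outcome
# triangles built from three two-sample MR legs.

#' Product-of-coefficients mediated effect
#'
#' \eqn{\beta_i = \beta_1 \beta_2 / \beta}, where \eqn{\beta_1} is the
#' exposure-to-mediator effect, \eqn{\beta_2} the mediator-to-outcome
#' effect, and \eqn{\beta} the total exposure-to-outcome effect (all on the
#' log-odds scale). The mediated path is coherent with the total effect
#' only when \eqn{\beta_1 \beta_2} and \eqn{\beta} share a sign; the
#' \code{consistent} flag codifies that check.
#'
#' @param beta1 Exposure-to-mediator effect.
#' @param beta2 Mediator-to-outcome effect.
#' @param beta_total Total exposure-to-outcome effect (non-zero).
#' @param p1,p2 Optional leg p-values; when both are given,
#'   \code{qualifies} records whether both legs are significant at
#'   \code{alpha}.
#' @param alpha Nominal level for \code{qualifies}.
#' @return An object of class \code{mr_mediation}: \code{beta1},
#'   \code{beta2}, \code{beta_total}, \code{beta_i}, \code{consistent},
#'   \code{qualifies}.
#' @examples
#' mediation_effect(log(1.035), log(0.488), log(1.266))
#' @export
mediation_effect <- function(beta1, beta2, beta_total,
                             p1 = NA_real_, p2 = NA_real_, alpha = 0.05) {
  .check_scalar_number(beta1, "beta1")
  .check_scalar_number(beta2, "beta2")
  .check_scalar_number(beta_total, "beta_total")
  if (beta_total == 0) .stopf("total effect zero")
  beta_i <- beta1 * beta2 / beta_total
  qualifies <- if (is.na(p1) || is.na(p2)) NA else (p1 < alpha && p2 < alpha)
  out <- list(beta1 = beta1, beta2 = beta2, beta_total = beta_total,
              beta_i = beta_i,
              consistent = sign(beta1 * beta2) == sign(beta_total),
              qualifies = qualifies)
  class(out) <- "mr_mediation"
  out
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Mediated effect beta_i = beta1 * beta2 / beta = %.4g\n", x$beta_i))
  cat(sprintf("  beta1 = %.4g, beta2 = %.4g, beta_total = %.4g\n",
              x$beta1, x$beta2, x$beta_total))
  cat(sprintf("  sign-consistent with total effect: %s\n", x$consistent))
  if (!is.na(x$qualifies)) {
    cat(sprintf("  both legs nominally significant: %s\n", x$qualifies))
  }
  invisible(x)
}

#' Find candidate mediators present in both legs
#'
#' A mediator qualifies for the product-of-coefficients decomposition when
#' it is significantly associated in both the exposure-to-mediator and
#' the mediator-to-outcome results tables.
#'
#' @param leg1 Results table of the exposure-to-mediator leg.
#' @param leg2 Results table of the mediator-to-outcome leg.
#' @param alpha Significance level applied to both legs.
#' @param id1,id2 Names of the mediator-id columns in each table.
#' @param p1,p2 Names of the p-value columns in each table.
#' @return Character vector of mediator ids significant in both legs.
#' @export
find_mediation_candidates <- function(leg1, leg2, alpha = 0.05,
                                      id1 = "outcome", id2 = "exposure",
                                      p1 = "pval_ivw", p2 = "pval_ivw") {
  for (spec in list(c(id1, "leg1"), c(p1, "leg1"))) {
    if (!spec[1] %in% names(leg1)) .stopf("column '%s' missing from leg1", spec[1])
  }
  for (spec in list(c(id2, "leg2"), c(p2, "leg2"))) {
    if (!spec[1] %in% names(leg2)) .stopf("column '%s' missing from leg2", spec[1])
  }
  sig1 <- leg1[[id1]][!is.na(leg1[[p1]]) & leg1[[p1]] < alpha]
  sig2 <- leg2[[id2]][!is.na(leg2[[p2]]) & leg2[[p2]] < alpha]
  sort(intersect(sig1, sig2))
}
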