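# The central model-fitting interface: fit all requested estimators to one
# harmonized exposure-outcome instrument set and return a classed object.

#' Fit two-sample Mendelian randomization estimators
#'
#' Runs the requested estimators on a harmonized instrument set and
#' collects their estimates, Cochran's Q heterogeneity, and the MR-Egger
#' intercept test in a single model object. IVW fixed- and random-effects
#' results are always both computed; the \code{estimate} selected by
#' \code{model} ("auto" follows the Q p < 0.05 rule) is flagged in the
#' table. Methods whose instrument-count preconditions fail (Egger and the
#' weighted median need 3 SNPs) are skipped with a note.
#'
#' @param h A \code{harmonized_set} from \code{\link{harmonize}} (or any
#'   data.frame with columns \code{beta_exp}, \code{se_exp},
#'   \code{beta_out}, \code{se_out}).
#' @param methods Estimators to run, a subset of \code{"ivw"},
#'   \code{"egger"}, \code{"weighted_median"}.
#' @param model IVW model selection: \code{"auto"}, \code{"fixed"},
#'   \code{"random"}.
#' @param n_boot Bootstrap resamples for the weighted-median standard
#'   error.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class \code{mr_fit} with components
#'   \code{estimates} (one row per method), \code{heterogeneity},
#'   \code{egger} (or NULL), \code{ivw}, \code{data}, \code{n_snps}.
#' @examples
#' sim <- simulate_pair(sim_config(n_snps = 30, theta = 0.2, seed = 3))
#' fit <- mr_fit(harmonize(sim$exposure, sim$outcome))
#' fit
#' coef(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "weighted_median"),
                   model = "auto", n_boot = 1000, seed = 1L) {
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median"),
                       several.ok = TRUE)
  k <- nrow(h)
  if (k == 0) .stopf("no instruments")
  rows <- list()
  ivw <- NULL
  egger <- NULL
  notes <- character(0)

  if ("ivw" %in% methods) {
    ivw <- mr_ivw(h, model = model)
    sel <- ivw$estimate
    sel$method <- paste0(sel$method, "_selected")
    rows <- c(rows, list(ivw$fixed, ivw$random, sel))
  }
  if ("egger" %in% methods) {
    if (k >= 3) {
      egger <- mr_egger(h)
      rows <- c(rows, list(egger$estimate))
    } else {
      notes <- c(notes, "egger skipped: fewer than 3 instruments")
    }
  }
  if ("weighted_median" %in% methods) {
    if (k >= 3) {
      rows <- c(rows, list(mr_weighted_median(h, n_boot = n_boot, seed = seed)))
    } else {
      notes <- c(notes, "weighted_median skipped: fewer than 3 instruments")
    }
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  out <- list(estimates = estimates,
              heterogeneity = if (!is.null(ivw)) ivw$heterogeneity else NULL,
              egger = egger, ivw = ivw, data = h, n_snps = k,
              notes = notes, call = match.call())
  class(out) <- "mr_fit"
  out
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %d instrument(s)\n", x$n_snps))
  est <- x$estimates
  est$pval <- format.pval(est$pval, digits = 3)
  num <- vapply(est, is.numeric, TRUE)
  est[num] <- lapply(est[num], signif, digits = digits)
  print(est[, c("method", "beta", "se", "ci_low", "ci_high", "or_", "pval")],
        row.names = FALSE)
  if (!is.null(x$heterogeneity) && !is.na(x$heterogeneity$q)) {
    cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g)\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$pval))
  }
  if (!is.null(x$egger)) {
    cat(sprintf("Egger intercept = %.4g (se %.3g, p = %.3g)\n",
                x$egger$intercept, x$egger$intercept_se, x$egger$intercept_pval))
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  est <- x$fit$estimates
  cat("\nOdds-ratio scale:\n")
  or <- data.frame(method = est$method,
                   or = signif(est$or_, 4),
                   or_low = signif(est$or_low, 4),
                   or_high = signif(est$or_high, 4))
  print(or, row.names = FALSE)
  invisible(x)
}

#' Extract causal-effect estimates from an mr_fit
#'
#' @param object An \code{mr_fit}.
#' @param ... Unused.
#' @return Named numeric vector of per-method beta estimates.
#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  half <- (est$ci_high - est$ci_low) / 2 *
    stats::qnorm((1 + level) / 2) / stats::qnorm(0.975)
  m <- cbind(est$beta - half, est$beta + half)
  dimnames(m) <- list(est$method,
                      paste0(format(c((1 - level) / 2, (1 + level) / 2) * 100), " %"))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Scatter plot of a Mendelian randomization fit
#'
#' SNP-outcome against SNP-exposure effects (oriented to non-negative
#' exposure effects) with one standard-error bars and the fitted IVW and
#' Egger lines.
#'
#' @param x An \code{mr_fit}.
#' @param ... Passed to \code{plot}.
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  sgn <- ifelse(h$beta_exp < 0, -1, 1)
  bx <- h$beta_exp * sgn
  by <- h$beta_out * sgn
  graphics::plot(bx, by, pch = 19, cex = 0.6,
                 xlab = "SNP-exposure effect", ylab = "SNP-outcome effect", ...)
  graphics::segments(bx, by - h$se_out, bx, by + h$se_out, col = "grey60")
  graphics::segments(bx - h$se_exp, by, bx + h$se_exp, by, col = "grey60")
  if (!is.null(x$ivw)) {
    graphics::abline(0, x$ivw$estimate$beta, col = "steelblue", lwd = 2)
  }
  if (!is.null(x$egger)) {
    graphics::abline(x$egger$intercept, x$egger$slope,
                     col = "firebrick", lwd = 2, lty = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, lty = c(1, 2),
                   col = c("steelblue", "firebrick"),
                   legend = c("IVW", "MR-Egger"))
  invisible(x)
}
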