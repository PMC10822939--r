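# Shared fixtures and independent oracles for the estimator tests.

# Build a harmonized set directly from effect vectors.
make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   n_exp = 20000, n_out = 50000) {
  k <- length(beta_exp)
  h <- data.frame(
    snp = sprintf("rs%03d", seq_len(k)),
    effect_allele = rep("A", k), other_allele = rep("G", k),
    beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    eaf_exp = rep(0.3, k), n_exp = n_exp,
    beta_out = beta_out, se_out = se_out,
    pval_out = 2 * pnorm(-abs(beta_out / se_out)),
    eaf_out = rep(0.3, k), n_out = n_out,
    stringsAsFactors = FALSE)
  class(h) <- c("harmonized_set", "data.frame")
  h
}

# Harmonized set specified at the Wald-ratio level: beta_exp = 1 so the
# ratios and their ses equal the outcome-side values.
ratio_h <- function(ratios, ratio_ses) {
  make_h(rep(1, length(ratios)), rep(1e-6, length(ratios)), ratios, ratio_ses)
}

random_h <- function(k, seed) {
  set.seed(seed)
  make_h(beta_exp = runif(k, 0.03, 0.2) * sample(c(-1, 1), k, TRUE),
         se_exp = runif(k, 0.005, 0.02),
         beta_out = rnorm(k, 0, 0.05),
         se_out = runif(k, 0.01, 0.05))
}

# Independent oracles (different code paths from the implementation):
# zero-intercept WLS via lm's QR solver.
oracle_ivw_beta <- function(h) {
  unname(coef(lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / se_out^2)))
}

# Egger WLS via explicit normal equations.
oracle_egger <- function(h) {
  sgn <- ifelse(h$beta_exp < 0, -1, 1)
  X <- cbind(1, h$beta_exp * sgn)
  y <- h$beta_out * sgn
  W <- diag(1 / h$se_out^2)
  XtWX <- t(X) %*% W %*% X
  b <- solve(XtWX, t(X) %*% W %*% y)
  res <- y - X %*% b
  sigma2 <- sum((1 / h$se_out^2) * res^2) / (nrow(X) - 2)
  se <- sqrt(diag(sigma2 * solve(XtWX)))
  list(intercept = b[1], slope = b[2], intercept_se = se[1], slope_se = se[2])
}

# Cumulative-weight interpolation of the weighted median via approx().
oracle_wmedian <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]; w <- weights[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  approx(p, r, xout = 0.5)$y
}

sim_harmonized <- function(n_snps, theta, seed, n_exp = 50000, n_out = 50000,
                           ...) {
  sim <- simulate_pair(sim_config(n_snps = n_snps, theta = theta, seed = seed,
                                  n_exp = n_exp, n_out = n_out, ...))
  harmonize(sim$exposure, sim$outcome)
}
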