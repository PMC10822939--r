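# Summary-level GWAS simulator with known causal truth.
#
# Generating model (per SNP j, independent instruments):
#   gamma_hat_j = gamma_j + e_xj,            e_xj ~ N(0, se_xj^2)
#   Gamma_hat_j = theta * gamma_j + alpha_j + e_yj,   e_yj ~ N(0, se_yj^2)
# with standard errors tied to allele frequency and sample size,
#   se ~= 1 / sqrt(2 * maf * (1 - maf) * n),
# so instrument strength (and the F statistic) responds to n as in a real
# GWAS. alpha_j are pleiotropic direct effects: balanced (sd pleio_tau),
# directional (mean pleio_mu), optionally correlated with gamma_j
# (InSIDE violation), with a configurable fraction of gross outliers.

#' Configuration for the summary-statistics simulator
#'
#' @param n_snps Number of candidate instruments.
#' @param n_exp,n_out Sample sizes of the exposure and outcome studies.
#' @param theta True causal effect on the beta (log-odds) scale.
#' @param gamma_mean,gamma_sd Mean and sd of the true instrument strengths
#'   \eqn{\gamma_j}, drawn from a normal truncated to positive values so the
#'   effect allele is consistently trait-increasing.
#' @param pleio_tau Standard deviation of balanced pleiotropic direct
#'   effects \eqn{\alpha_j} (0 disables pleiotropy).
#' @param pleio_mu Mean of directional pleiotropy.
#' @param inside_rho Coupling of \eqn{\alpha_j} to centred \eqn{\gamma_j};
#'   non-zero values violate the InSIDE assumption.
#' @param outlier_frac Fraction of SNPs given gross direct effects of
#'   magnitude at least 10 times the typical pleiotropy scale.
#' @param maf_range Range of the uniform minor-allele-frequency draw,
#'   within (0.01, 0.5).
#' @param ld_blocks Optional list of \code{c(size, r2)} pairs describing
#'   within-block LD among the first SNPs (metadata for clump testing; the
#'   summary statistics themselves are simulated as independent).
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_snps = 100, n_exp = 18340, n_out = 50000,
                       theta = 0, gamma_mean = 0.1, gamma_sd = 0.05,
                       pleio_tau = 0, pleio_mu = 0, inside_rho = 0,
                       outlier_frac = 0, maf_range = c(0.05, 0.5),
                       ld_blocks = NULL, seed = 1L) {
  if (n_snps < 1) .stopf("n_snps must be >= 1")
  if (n_exp < 100 || n_out < 100) .stopf("sample sizes must be >= 100")
  if (outlier_frac < 0 || outlier_frac >= 1) .stopf("outlier_frac must lie in [0, 1)")
  if (pleio_tau < 0) .stopf("pleio_tau must be >= 0")
  if (gamma_sd < 0 || gamma_mean <= 0) .stopf("gamma strengths must be positive on average")
  if (length(maf_range) != 2L || maf_range[1] <= 0.01 - 1e-12 ||
      maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    .stopf("maf_range must lie within (0.01, 0.5]")
  }
  structure(list(n_snps = as.integer(n_snps), n_exp = as.integer(n_exp),
                 n_out = as.integer(n_out), theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleio_tau = pleio_tau, pleio_mu = pleio_mu,
                 inside_rho = inside_rho, outlier_frac = outlier_frac,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# normal truncated to (0, Inf) by inverse-CDF sampling
.rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate an exposure/outcome pair of GWAS summary tables
#'
#' Draws per-SNP instrument strengths, pleiotropic direct effects and
#' sampling noise under the linear summary-statistics model, and returns
#' both study tables together with the generating truth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with elements \code{exposure} and \code{outcome}
#'   (summary-statistics data.frames sharing SNP ids and allele coding) and
#'   \code{truth} (class \code{sim_truth}: \code{theta}, \code{gamma},
#'   \code{alpha}, \code{outlier_indices}, \code{maf}, \code{seed}).
#' @examples
#' sim <- simulate_pair(sim_config(n_snps = 20, theta = 0.2, seed = 7))
#' head(sim$exposure)
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    p <- config$n_snps
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exp)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_out)
    gamma <- .rtnorm_pos(p, config$gamma_mean, config$gamma_sd)

    alpha <- config$pleio_mu + stats::rnorm(p, 0, config$pleio_tau)
    if (config$inside_rho != 0) {
      alpha <- alpha + config$inside_rho * (gamma - mean(gamma))
    }
    n_out_snp <- floor(config$outlier_frac * p)
    outlier_idx <- integer(0)
    if (n_out_snp > 0) {
      outlier_idx <- sort(sample.int(p, n_out_snp))
      scale <- if (config$pleio_tau > 0) {
        10 * config$pleio_tau
      } else if (config$theta != 0) {
        10 * abs(config$theta * mean(gamma))
      } else {
        10 * mean(se_y / gamma)
      }
      alpha[outlier_idx] <- sample(c(-1, 1), n_out_snp, replace = TRUE) * scale
    }

    beta_x <- gamma + stats::rnorm(p, 0, se_x)
    beta_y <- config$theta * gamma + alpha + stats::rnorm(p, 0, se_y)

    # non-palindromic allele pairs so default harmonization keeps every SNP
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), p, replace = TRUE)
    snp <- sprintf("rs%05d", seq_len(p))

    exposure <- data.frame(
      snp = snp, effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
      beta = beta_x, se = se_x,
      pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
      eaf = maf, n = config$n_exp, trait = "sim_exposure",
      stringsAsFactors = FALSE)
    outcome <- data.frame(
      snp = snp, effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
      beta = beta_y, se = se_y,
      pval = 2 * stats::pnorm(-abs(beta_y / se_y)),
      eaf = maf, n = config$n_out, trait = "sim_outcome",
      stringsAsFactors = FALSE)

    truth <- structure(list(theta = config$theta, gamma = gamma, alpha = alpha,
                            outlier_indices = outlier_idx, maf = maf,
                            seed = config$seed),
                       class = "sim_truth")
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate a constant-correlation LD block
#'
#' Every off-diagonal entry within the block equals \code{r2}; positions are
#' spaced 1 kb apart so the clumping distance window can be exercised.
#'
#' @param n_snps Number of SNPs in the block.
#' @param r2 Within-block squared correlation in [0, 1].
#' @param snp_ids Optional SNP ids (default \code{blk1..blkN}).
#' @param spacing_bp Base-pair spacing between consecutive SNPs.
#' @return An \code{\link{ld_matrix}} with positions attached.
#' @export
simulate_ld_block <- function(n_snps, r2, snp_ids = NULL, spacing_bp = 1000) {
  if (r2 < 0 || r2 > 1) .stopf("r2 must lie in [0, 1]")
  if (is.null(snp_ids)) snp_ids <- paste0("blk", seq_len(n_snps))
  m <- matrix(r2, n_snps, n_snps, dimnames = list(snp_ids, snp_ids))
  diag(m) <- 1
  pos <- stats::setNames(seq_len(n_snps) * spacing_bp, snp_ids)
  ld_matrix(m, positions = pos)
}

#' Build a rank-labelled taxonomy table
#'
#' Emulates a microbiome GWAS trait panel: taxa labelled with one of the
#' five ranks phylum/class/order/family/genus, a configurable number of
#' them unnamed (\code{name == "unknown"}, placed at genus or family level
#' as in reference panels). With the default 211 taxa the rank composition
#' is the reference split 131 genera / 35 families / 20 orders / 16 classes
#' / 9 phyla; other sizes are allocated proportionally.
#'
#' @param n_taxa Total number of taxa.
#' @param n_unknown Number of unnamed taxa (must not exceed \code{n_taxa}).
#' @param seed Integer seed controlling which taxa are unnamed.
#' @return A data.frame with columns \code{taxon_id}, \code{rank},
#'   \code{name}.
#' @export
make_taxonomy_fixture <- function(n_taxa = 211, n_unknown = 15, seed = 1L) {
  if (n_unknown > n_taxa) .stopf("n_unknown must not exceed n_taxa")
  ref <- c(genus = 131, family = 35, order = 20, class = 16, phylum = 9)
  if (n_taxa == sum(ref)) {
    counts <- ref
  } else {
    counts <- floor(ref / sum(ref) * n_taxa)
    rem <- n_taxa - sum(counts)
    if (rem > 0) {
      frac <- ref / sum(ref) * n_taxa - counts
      bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[bump] <- counts[bump] + 1
    }
  }
  rank <- rep(names(counts), counts)
  name <- sprintf("%s.Taxon%03d", rank, seq_len(n_taxa))
  .with_seed(seed, {
    if (n_unknown > 0) {
      eligible <- which(rank %in% c("genus", "family"))
      if (length(eligible) < n_unknown) eligible <- seq_len(n_taxa)
      unk <- sample(eligible, n_unknown)
      name[unk] <- "unknown"
    }
  })
  data.frame(taxon_id = sprintf("tax%03d", seq_len(n_taxa)),
             rank = rank, name = name, stringsAsFactors = FALSE)
}

#' Simulate an exposure–mediator–outcome triangle
#'
#' Generates three independent two-sample systems with effects wired so
#' that the product-of-coefficients decomposition has known truth:
#' exposure to mediator with effect \code{a}, mediator to outcome with
#' effect \code{b}, and exposure to outcome with total effect
#' \code{direct + a * b}.
#'
#' @param a,b True effects of the two mediated legs.
#' @param direct Direct (unmediated) exposure-to-outcome effect.
#' @param n_snps,n_exp,n_out Per-leg simulator settings (see
#'   \code{\link{sim_config}}).
#' @param seed Integer seed; the three legs use \code{seed}, \code{seed+1},
#'   \code{seed+2}.
#' @return A list with elements \code{leg1}, \code{leg2}, \code{total}
#'   (each a \code{\link{simulate_pair}} result) and \code{truth}
#'   (\code{a}, \code{b}, \code{direct}, \code{total}).
#' @export
simulate_triangle <- function(a, b, direct = 0, n_snps = 100,
                              n_exp = 50000, n_out = 50000, seed = 1L) {
  total <- direct + a * b
  mk <- function(theta, s) {
    simulate_pair(sim_config(n_snps = n_snps, n_exp = n_exp, n_out = n_out,
                             theta = theta, seed = s))
  }
  list(leg1 = mk(a, seed),
       leg2 = mk(b, seed + 1L),
       total = mk(total, seed + 2L),
       truth = list(a = a, b = b, direct = direct, total = total))
}
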