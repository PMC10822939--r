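# Study pipeline: exposure x outcome grids through the full QC ->
# harmonize -> estimate -> sensitivity -> classify chain, with rank-wise
# Bonferroni thresholds and a tabular report.

#' Bonferroni-corrected significance threshold
#'
#' @param m Number of tests at the rank (>= 1).
#' @param alpha Family-wise level.
#' @return \code{alpha / m}.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (any(m < 1)) .stopf("m must be >= 1")
  alpha / m
}

#' Per-rank Bonferroni thresholds from a taxonomy table
#'
#' Counts the taxa at each rank in the supplied table and returns
#' \code{alpha / m} per rank, so panels of any composition get the correct
#' thresholds.
#'
#' @param taxonomy Data.frame with a \code{rank} column.
#' @param alpha Family-wise level.
#' @return Data.frame with columns \code{rank}, \code{m},
#'   \code{threshold}.
#' @export
rank_thresholds <- function(taxonomy, alpha = 0.05) {
  counts <- table(taxonomy$rank)
  data.frame(rank = names(counts), m = as.integer(counts),
             threshold = bonferroni_threshold(as.integer(counts), alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a causal association
#'
#' Nested classes: \emph{nominal} requires IVW p below
#' \code{nominal_alpha}; \emph{stable} additionally requires a clean
#' sensitivity profile (Egger intercept p > 0.05; MR-PRESSO global p >
#' 0.05, or a sign-concordant outlier-corrected estimate with distortion p
#' >= 0.05; not dominated by a single SNP in leave-one-out; Steiger
#' direction supporting exposure-to-outcome); \emph{strong} additionally
#' requires IVW p below the rank-wise Bonferroni threshold. Missing
#' sensitivity results cap the classification at nominal with a warning.
#'
#' @param pval_ivw IVW p-value.
#' @param rank_threshold Bonferroni threshold for the exposure's rank.
#' @param egger_intercept_pval MR-Egger intercept p-value.
#' @param presso_clean Logical: MR-PRESSO profile clean as defined above.
#' @param loo_dominated Logical: leave-one-out domination flag.
#' @param steiger_correct Logical: Steiger direction correct.
#' @param nominal_alpha Nominal level.
#' @return One of \code{"none"}, \code{"nominal"}, \code{"stable"},
#'   \code{"strong"}.
#' @export
classify_association <- function(pval_ivw, rank_threshold,
                                 egger_intercept_pval = NA,
                                 presso_clean = NA, loo_dominated = NA,
                                 steiger_correct = NA,
                                 nominal_alpha = 0.05) {
  if (is.na(pval_ivw) || pval_ivw >= nominal_alpha) return("none")
  sens <- c(egger = egger_intercept_pval, presso = presso_clean,
            loo = loo_dominated, steiger = steiger_correct)
  if (any(is.na(sens))) {
    warning("classify_association: missing sensitivity results; capped at nominal")
    return("nominal")
  }
  stable <- egger_intercept_pval > 0.05 && isTRUE(as.logical(presso_clean)) &&
    !isTRUE(as.logical(loo_dominated)) && isTRUE(as.logical(steiger_correct))
  if (!stable) return("nominal")
  if (!is.na(rank_threshold) && pval_ivw < rank_threshold) return("strong")
  "stable"
}

# MR-PRESSO cleanliness rule used by classify: no global pleiotropy, or a
# corrected estimate that is sign-concordant with the uncorrected one and
# not significantly distorted.
.presso_clean <- function(presso) {
  if (is.null(presso)) return(NA)
  if (presso$global_pval > 0.05) return(TRUE)
  if (length(presso$outliers) == 0) return(FALSE)
  !is.na(presso$distortion_pval) && presso$distortion_pval >= 0.05 &&
    sign(presso$beta_corrected) == sign(presso$beta_all)
}

# One exposure-outcome pair through the full chain.
.run_pair <- function(exposure, outcome, qc, ld, nominal_alpha,
                      rank, rank_threshold, n_boot, n_sim, pair_seed) {
  label <- function(df, default) {
    if ("trait" %in% names(df) && !is.na(df$trait[1])) df$trait[1] else default
  }
  base <- data.frame(
    exposure = label(exposure, "exposure"), outcome = label(outcome, "outcome"),
    rank = rank, n_snps = 0L,
    beta_ivw = NA_real_, se_ivw = NA_real_, or_ivw = NA_real_,
    or_low = NA_real_, or_high = NA_real_, pval_ivw = NA_real_,
    ivw_model = NA_character_,
    beta_ivw_fixed = NA_real_, pval_ivw_fixed = NA_real_,
    beta_ivw_random = NA_real_, pval_ivw_random = NA_real_,
    q = NA_real_, q_pval = NA_real_,
    beta_egger = NA_real_, pval_egger = NA_real_,
    egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
    beta_wmedian = NA_real_, pval_wmedian = NA_real_,
    presso_global_pval = NA_real_, presso_n_outliers = NA_integer_,
    presso_distortion_pval = NA_real_,
    loo_dominated = NA, steiger_correct = NA,
    classification = "none", reason = "", stringsAsFactors = FALSE)

  sel <- select_by_p(exposure, qc$p_threshold)
  if (nrow(sel) > 1 && !is.null(ld)) {
    sel <- ld_clump(sel, ld, qc$clump_r2, qc$clump_window_kb)
  }
  if (nrow(sel) > 0 && "n" %in% names(sel) && !anyNA(sel$n)) {
    f <- f_statistic(per_snp_r2(sel$beta, sel$se, sel$n), sel$n, k = 1)
    sel <- sel[f > qc$f_min, , drop = FALSE]
  }
  if (nrow(sel) > 0) sel <- suppressWarnings(maf_filter(sel, qc$maf_min))
  h <- harmonize(sel, outcome, drop_palindromic = qc$drop_palindromic)
  k <- nrow(h)
  base$n_snps <- k
  if (k == 0) {
    base$reason <- "no_instruments"
    return(base)
  }

  fit <- mr_fit(h, model = "auto", n_boot = n_boot, seed = pair_seed)
  est <- fit$estimates
  pick <- function(m) est[est$method == m, , drop = FALSE]
  sel_row <- est[grepl("_selected$", est$method), , drop = FALSE]
  base$beta_ivw <- sel_row$beta; base$se_ivw <- sel_row$se
  base$or_ivw <- sel_row$or_; base$or_low <- sel_row$or_low
  base$or_high <- sel_row$or_high; base$pval_ivw <- sel_row$pval
  base$ivw_model <- sub("_selected$", "", sel_row$method)
  fx <- pick("ivw_fixed"); rd <- pick("ivw_random")
  if (nrow(fx)) { base$beta_ivw_fixed <- fx$beta; base$pval_ivw_fixed <- fx$pval }
  if (nrow(rd)) { base$beta_ivw_random <- rd$beta; base$pval_ivw_random <- rd$pval }
  if (!is.null(fit$heterogeneity)) {
    base$q <- fit$heterogeneity$q; base$q_pval <- fit$heterogeneity$pval
  }
  if (!is.null(fit$egger)) {
    base$beta_egger <- fit$egger$slope
    base$pval_egger <- fit$egger$slope_pval
    base$egger_intercept <- fit$egger$intercept
    base$egger_intercept_pval <- fit$egger$intercept_pval
  }
  wm <- pick("weighted_median")
  if (nrow(wm)) { base$beta_wmedian <- wm$beta; base$pval_wmedian <- wm$pval }

  presso <- NULL
  if (k >= 4) {
    presso <- mr_presso(h, n_sim = n_sim, seed = pair_seed + 1L)
    base$presso_global_pval <- presso$global_pval
    base$presso_n_outliers <- length(presso$outliers)
    base$presso_distortion_pval <- presso$distortion_pval
  }
  loo <- if (k >= 2) leave_one_out(h, nominal_alpha) else NULL
  if (!is.null(loo)) base$loo_dominated <- loo$dominated
  steiger <- if (!anyNA(c(h$n_exp, h$n_out))) mr_steiger(h) else NULL
  if (!is.null(steiger)) base$steiger_correct <- steiger$correct_direction

  base$classification <- withCallingHandlers(
    classify_association(base$pval_ivw, rank_threshold,
                         base$egger_intercept_pval, .presso_clean(presso),
                         base$loo_dominated, base$steiger_correct,
                         nominal_alpha),
    warning = function(w) invokeRestart("muffleWarning"))
  if (base$classification == "nominal" &&
      (is.null(presso) || is.null(loo) || is.null(steiger) ||
       is.na(base$egger_intercept_pval))) {
    base$reason <- "sensitivity_incomplete"
  }
  base
}

#' Run a grid of two-sample MR analyses
#'
#' Applies the full chain — p-value selection, LD clumping, F and MAF
#' filters, harmonization, estimators, sensitivity tests, classification —
#' to every exposure-outcome combination and returns one report row per
#' pair. Pairs with no surviving instruments are emitted with
#' classification \code{none} and reason \code{no_instruments}. The run is
#' a pure function of the inputs, configuration and seed.
#'
#' @param exposures Named list of exposure summary-statistics data.frames.
#' @param outcomes Named list of outcome summary-statistics data.frames.
#' @param qc A \code{\link{selection_config}}.
#' @param ld Optional \code{\link{ld_matrix}} for clumping.
#' @param ranks Optional character vector (recycled or named by exposure)
#'   giving each exposure's taxonomic rank; defaults to \code{"disease"}.
#' @param taxonomy Optional taxonomy table from which per-rank Bonferroni
#'   thresholds are computed via \code{\link{rank_thresholds}}; when
#'   absent, each rank's m is the number of exposures carrying it in this
#'   grid.
#' @param nominal_alpha Nominal significance level.
#' @param n_boot Weighted-median bootstrap resamples.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Integer seed; per-pair seeds are derived deterministically.
#' @return A data.frame with one row per exposure-outcome pair (see
#'   \code{\link{write_report}} for the column set).
#' @export
run_grid <- function(exposures, outcomes, qc = selection_config(), ld = NULL,
                     ranks = NULL, taxonomy = NULL, nominal_alpha = 0.05,
                     n_boot = 1000, n_sim = 1000, seed = 1L) {
  if (!is.list(exposures) || is.data.frame(exposures)) exposures <- list(exposures)
  if (!is.list(outcomes) || is.data.frame(outcomes)) outcomes <- list(outcomes)
  ne <- length(exposures); no <- length(outcomes)
  if (is.null(ranks)) ranks <- rep("disease", ne)
  ranks <- rep_len(ranks, ne)
  thr <- if (!is.null(taxonomy)) {
    rank_thresholds(taxonomy, nominal_alpha)
  } else {
    rank_thresholds(data.frame(rank = ranks), nominal_alpha)
  }
  rows <- vector("list", ne * no)
  for (i in seq_len(ne)) {
    rt <- thr$threshold[match(ranks[i], thr$rank)]
    for (j in seq_len(no)) {
      idx <- (i - 1L) * no + j
      rows[[idx]] <- .run_pair(exposures[[i]], outcomes[[j]], qc, ld,
                               nominal_alpha, ranks[i],
                               if (is.na(rt)) nominal_alpha else rt,
                               n_boot, n_sim,
                               pair_seed = seed + 2L * idx)
      if (!is.null(names(exposures))) rows[[idx]]$exposure <- names(exposures)[i]
      if (!is.null(names(outcomes))) rows[[idx]]$outcome <- names(outcomes)[j]
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report
}

#' Write the study report
#'
#' One row per exposure-outcome pair with the odds ratio and 95% interval
#' per method, heterogeneity and pleiotropy p-values, MR-PRESSO,
#' leave-one-out and Steiger outcomes, and the classification — the fields
#' conventionally reported per association in two-sample MR studies.
#'
#' @param records Report data.frame from \code{\link{run_grid}}.
#' @param path Output path (tab-separated).
#' @export
write_report <- function(records, path) {
  write_results(records, path)
}
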