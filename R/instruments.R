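# Instrument selection, quality filters and effect-allele harmonization.

#' Instrument-selection configuration
#'
#' Defaults follow the conventional microbiome-exposure setting: a relaxed
#' genome-wide threshold of 1e-5, LD clumping at r2 < 0.001 within a
#' 10,000 kb window, F > 10, MAF >= 0.01, and unconditional removal of
#' palindromic variants. Disease exposures conventionally use
#' \code{p_threshold = 5e-8}.
#'
#' @param p_threshold Strict upper p-value bound for instrument inclusion.
#' @param clump_r2 LD-clumping r2 threshold.
#' @param clump_window_kb Clumping distance window in kilobases.
#' @param f_min Minimum instrument-strength F statistic (strict: F must
#'   exceed this value).
#' @param maf_min Minimum minor-allele frequency (variants with MAF
#'   strictly below are excluded).
#' @param drop_palindromic Drop A/T and C/G variants during harmonization.
#' @return A validated list of class \code{selection_config}.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                             clump_window_kb = 10000, f_min = 10,
                             maf_min = 0.01, drop_palindromic = TRUE) {
  if (p_threshold <= 0 || p_threshold >= 1) .stopf("p_threshold must lie in (0, 1)")
  if (clump_r2 < 0 || clump_r2 > 1) .stopf("clump_r2 must lie in [0, 1]")
  if (f_min <= 0) .stopf("f_min must be positive")
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 maf_min = maf_min, drop_palindromic = isTRUE(drop_palindromic)),
            class = "selection_config")
}

#' Select instruments by association p-value
#'
#' Retains records with \code{pval} strictly below the threshold.
#'
#' @param records Summary-statistics data.frame.
#' @param p_threshold Strict upper bound.
#' @return The retained subset.
#' @export
select_by_p <- function(records, p_threshold = 1e-5) {
  records[records$pval < p_threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties broken by SNP id), keeps
#' the best SNP, removes every remaining SNP correlated with it at
#' \code{r2 >= clump_r2} within the distance window, and recurses on the
#' remainder. Without positional information only the r2 rule applies;
#' with positions, SNPs more than \code{window_kb} kilobases apart are
#' never clumped against each other. SNPs absent from the LD matrix are
#' treated as independent (r2 = 0) with a warning.
#'
#' @param records Summary-statistics data.frame.
#' @param ld An \code{\link{ld_matrix}}, or NULL (all SNPs independent).
#' @param clump_r2 r2 threshold (retained pairs have r2 strictly below it).
#' @param window_kb Distance window in kilobases; pairs with
#'   \code{|pos_a - pos_b| <= window_kb * 1000} count as within the window.
#' @return The retained subset.
#' @export
ld_clump <- function(records, ld = NULL, clump_r2 = 0.001, window_kb = 10000) {
  if (nrow(records) <= 1L) return(records)
  if (is.null(ld)) {
    warning("ld_clump: no LD matrix supplied; treating all SNPs as independent")
    return(records)
  }
  ids <- records$snp
  known <- ids %in% rownames(ld)
  if (any(!known)) {
    warning(sprintf("ld_clump: %d SNP(s) absent from the LD matrix, treated as r2 = 0",
                    sum(!known)))
  }
  pos <- attr(ld, "positions")
  ord <- order(records$pval, records$snp)
  active <- ord
  keep <- integer(0)
  while (length(active)) {
    top <- active[1L]
    keep <- c(keep, top)
    active <- active[-1L]
    if (!length(active)) break
    r2 <- rep(0, length(active))
    if (known[top]) {
      hit <- known[active]
      r2[hit] <- ld[ids[top], ids[active[hit]]]
    }
    within <- rep(TRUE, length(active))
    if (!is.null(pos)) {
      pa <- pos[ids[top]]
      pb <- pos[ids[active]]
      ok <- !is.na(pa) & !is.na(pb)
      within[ok] <- abs(pa - pb[ok]) <= window_kb * 1000
    }
    active <- active[!(r2 >= clump_r2 & within)]
  }
  records[sort(keep), , drop = FALSE]
}

#' Instrument-strength F statistic
#'
#' \eqn{F = R^2 (n - k - 1) / (k (1 - R^2))} for \eqn{R^2} variance in the
#' exposure explained by \eqn{k} instruments in a study of \eqn{n} samples.
#'
#' @param r2 Variance explained, in [0, 1).
#' @param n Sample size (must exceed \code{k + 1}).
#' @param k Number of instruments (default 1 for per-SNP strength).
#' @return The F statistic (vectorised over \code{r2}).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0) || any(r2 >= 1)) .stopf("r2 must lie in [0, 1)")
  if (any(n <= k + 1)) .stopf("n must exceed k + 1")
  if (any(k < 1)) .stopf("k must be >= 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Per-SNP variance explained
#'
#' Uses the regression-t identity \eqn{R^2 = t^2 / (t^2 + n - 2)} with
#' \eqn{t = \beta / se}, requiring no allele frequency.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param n Sample size (> 2).
#' @return Variance explained, in [0, 1); vectorised.
#' @export
per_snp_r2 <- function(beta, se, n) {
  if (any(se <= 0)) .stopf("se must be positive")
  if (any(n <= 2)) .stopf("n must exceed 2")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Remove palindromic variants
#'
#' Drops SNPs whose allele pair is A/T or C/G, whose strand cannot be
#' resolved from alleles alone.
#'
#' @param records Summary-statistics data.frame.
#' @return The retained subset, with a \code{dropped} attribute listing
#'   removed SNP ids.
#' @export
drop_palindromic <- function(records) {
  pal <- .is_palindromic(records$effect_allele, records$other_allele)
  out <- records[!pal, , drop = FALSE]
  attr(out, "dropped") <- data.frame(snp = records$snp[pal],
                                     reason = rep("palindromic", sum(pal)),
                                     stringsAsFactors = FALSE)
  out
}

#' Minor-allele-frequency filter
#'
#' Excludes variants whose minor-allele frequency \code{min(eaf, 1 - eaf)}
#' is strictly below \code{maf_min}. Records without an allele frequency
#' are retained with a warning.
#'
#' @param records Summary-statistics data.frame.
#' @param maf_min MAF lower bound (boundary values are retained).
#' @return The retained subset.
#' @export
maf_filter <- function(records, maf_min = 0.01) {
  if (!"eaf" %in% names(records)) {
    warning("maf_filter: no eaf column; all records retained")
    return(records)
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  missing <- is.na(maf)
  if (any(missing)) {
    warning(sprintf("maf_filter: %d record(s) lack eaf and were retained", sum(missing)))
  }
  records[missing | maf >= maf_min, , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every exposure instrument with the matching outcome record on a
#' shared effect allele. Same-orientation pairs are kept unchanged; pairs
#' with swapped alleles have the outcome beta negated and allele frequency
#' complemented; pairs that only match after complementing the outcome
#' strand are rescued (with the swap rule applied on the flipped strand);
#' anything else is dropped with reason \code{allele_mismatch}. SNPs absent
#' from the outcome are dropped with reason \code{missing_in_outcome};
#' palindromic variants, for which strand flips are indistinguishable from
#' allele swaps, are dropped when \code{drop_palindromic} is TRUE.
#' Exposure-side values are never modified.
#'
#' @param exposure,outcome Summary-statistics data.frames.
#' @param drop_palindromic Remove A/T and C/G variants.
#' @return A data.frame of class \code{harmonized_set} with columns
#'   \code{snp}, \code{effect_allele}, \code{other_allele},
#'   \code{beta_exp}, \code{se_exp}, \code{pval_exp}, \code{eaf_exp},
#'   \code{n_exp}, \code{beta_out}, \code{se_out}, \code{pval_out},
#'   \code{eaf_out}, \code{n_out}, plus a \code{dropped} attribute
#'   (\code{snp}, \code{reason}).
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  om <- outcome[!duplicated(outcome$snp), , drop = FALSE]
  idx <- match(exposure$snp, om$snp)

  p <- nrow(exposure)
  keep <- logical(p)
  negate <- logical(p)
  reason <- character(p)

  e1 <- exposure$effect_allele; e2 <- exposure$other_allele
  o1 <- om$effect_allele[idx];  o2 <- om$other_allele[idx]
  pal <- .is_palindromic(e1, e2)

  for (i in seq_len(p)) {
    if (is.na(idx[i])) { reason[i] <- "missing_in_outcome"; next }
    if (pal[i] && drop_palindromic) { reason[i] <- "palindromic"; next }
    a1 <- o1[i]; a2 <- o2[i]
    if (a1 == e1[i] && a2 == e2[i]) {
      keep[i] <- TRUE
    } else if (a1 == e2[i] && a2 == e1[i]) {
      keep[i] <- TRUE; negate[i] <- TRUE
    } else if (!pal[i] &&
               .complement[a1] == e1[i] && .complement[a2] == e2[i]) {
      keep[i] <- TRUE
    } else if (!pal[i] &&
               .complement[a1] == e2[i] && .complement[a2] == e1[i]) {
      keep[i] <- TRUE; negate[i] <- TRUE
    } else {
      reason[i] <- "allele_mismatch"
    }
  }

  getcol <- function(df, col, rows) {
    if (col %in% names(df)) df[[col]][rows] else rep(NA_real_, length(rows))
  }
  krows <- which(keep)
  orows <- idx[krows]
  beta_out <- om$beta[orows]
  eaf_out <- getcol(om, "eaf", orows)
  neg <- negate[krows]
  beta_out[neg] <- -beta_out[neg]
  eaf_out[neg] <- 1 - eaf_out[neg]

  h <- data.frame(
    snp = exposure$snp[krows],
    effect_allele = e1[krows], other_allele = e2[krows],
    beta_exp = exposure$beta[krows], se_exp = exposure$se[krows],
    pval_exp = exposure$pval[krows],
    eaf_exp = getcol(exposure, "eaf", krows),
    n_exp = getcol(exposure, "n", krows),
    beta_out = beta_out, se_out = om$se[orows],
    pval_out = om$pval[orows], eaf_out = eaf_out,
    n_out = getcol(om, "n", orows),
    stringsAsFactors = FALSE)
  rownames(h) <- NULL
  attr(h, "dropped") <- data.frame(snp = exposure$snp[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE)
  class(h) <- c("harmonized_set", "data.frame")
  h
}

#' Split a harmonized set back into exposure and outcome tables
#'
#' @param h A \code{harmonized_set}.
#' @return A list with \code{exposure} and \code{outcome}
#'   summary-statistics data.frames on the shared effect-allele convention.
#' @export
harmonized_pair <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  list(
    exposure = data.frame(snp = h$snp, effect_allele = h$effect_allele,
                          other_allele = h$other_allele, beta = h$beta_exp,
                          se = h$se_exp, pval = h$pval_exp, eaf = h$eaf_exp,
                          n = h$n_exp, stringsAsFactors = FALSE),
    outcome = data.frame(snp = h$snp, effect_allele = h$effect_allele,
                         other_allele = h$other_allele, beta = h$beta_out,
                         se = h$se_out, pval = h$pval_out, eaf = h$eaf_out,
                         n = h$n_out, stringsAsFactors = FALSE))
}

#' Remove unnamed taxa from a taxonomy table
#'
#' Drops rows whose \code{name} is \code{"unknown"}; applied to a 211-taxon
#' panel with 15 unnamed taxa this leaves 196 analysable traits.
#'
#' @param taxonomy Data.frame with a \code{name} column.
#' @return The named subset.
#' @export
filter_named_taxa <- function(taxonomy) {
  taxonomy[taxonomy$name != "unknown", , drop = FALSE]
}
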