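# Reading, validating and writing GWAS summary-statistic tables.
#
# A summary-statistics table is a plain data.frame with canonical columns
#   snp, effect_allele, other_allele, beta, se, pval, eaf (optional),
#   n (optional), trait
# where beta is the per-allele effect (log-odds for binary traits).

.sumstat_aliases <- list(
  snp           = c("snp", "rsid", "variant_id", "snp_id", "id", "markername"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele  = c("other_allele", "oa", "a2", "allele2", "non_effect_allele"),
  beta          = c("beta", "b", "effect"),
  se            = c("se", "standard_error", "stderr"),
  pval          = c("pval", "p", "p_value", "pvalue"),
  eaf           = c("eaf", "effect_allele_frequency", "freq", "af"),
  n             = c("n", "samplesize", "n_total")
)

.canonicalise_names <- function(nms) {
  low <- tolower(nms)
  for (canon in names(.sumstat_aliases)) {
    hit <- low %in% .sumstat_aliases[[canon]]
    if (any(hit)) nms[which(hit)[1L]] <- canon
  }
  nms
}

# Row-level validation shared by read_sumstats() and the simulator.
# Returns a logical keep-vector; assumes canonical column names.
.valid_sumstat_rows <- function(df) {
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(df$snp) & nzchar(df$snp) &
    df$effect_allele %in% bases & df$other_allele %in% bases &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pval) & df$pval > 0 & df$pval <= 1
  if ("eaf" %in% names(df)) {
    ok <- ok & (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1))
  }
  if ("n" %in% names(df)) {
    ok <- ok & (is.na(df$n) | df$n >= 2)
  }
  ok
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table of per-SNP association statistics, maps
#' common column-name dialects onto the canonical names (\code{snp},
#' \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se},
#' \code{pval}, optionally \code{eaf} and \code{n}), uppercases alleles,
#' drops rows violating the record invariants (positive standard error,
#' p-value in (0,1], single-base non-identical alleles, allele frequency
#' strictly inside (0,1), sample size at least 2) with a logged count, and
#' resolves duplicate SNP ids by keeping the row with the smallest p-value.
#'
#' @param path Path to a tab-separated file with a header row. The string
#'   \code{"NA"} denotes missing values.
#' @param trait_label Label recorded in the \code{trait} column of the
#'   returned table.
#' @return A data.frame with canonical columns and one row per retained SNP.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\teffect_allele\tother_allele\tbeta\tse\tpval",
#'              "rs1\tA\tG\t0.1\t0.02\t1e-6"), tf)
#' read_sumstats(tf, "example trait")
#' @export
read_sumstats <- function(path, trait_label = NA_character_) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (file.size(path) == 0) .stopf("empty summary-statistics file: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          check.names = FALSE)
  names(df) <- .canonicalise_names(names(df))
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    .stopf("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) .stopf("no data rows in %s", path)

  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in intersect(c("beta", "se", "pval", "eaf", "n"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }

  ok <- .valid_sumstat_rows(df)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf("read_sumstats: dropped %d row(s) violating record invariants", n_bad))
  }
  df <- df[ok, , drop = FALSE]

  # duplicate snp ids: keep the most significant row
  df <- df[order(df$pval, df$snp), , drop = FALSE]
  dup <- duplicated(df$snp)
  if (any(dup)) {
    message(sprintf("read_sumstats: resolved %d duplicate snp id(s), keeping smallest p", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$snp), , drop = FALSE]
  rownames(df) <- NULL
  df$trait <- trait_label
  df
}

#' Read a linkage-disequilibrium matrix
#'
#' Accepts either a square tab-separated matrix whose header row and first
#' column carry SNP ids, or a long-format table with columns
#' \code{snp_a}, \code{snp_b}, \code{r2} (unlisted pairs default to 0).
#'
#' @param path Path to the LD file.
#' @param positions Optional named numeric vector of base-pair coordinates
#'   (names are SNP ids) enabling the distance window during clumping.
#' @return An \code{ld_matrix}: a symmetric matrix of squared correlations
#'   with unit diagonal, SNP ids as dimnames, and an optional
#'   \code{positions} attribute.
#' @export
read_ld <- function(path, positions = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  head_names <- tolower(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]])
  if (length(head_names) == 3L && all(c("snp_a", "snp_b", "r2") %in% head_names)) {
    long <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    names(long) <- tolower(names(long))
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(long))) {
      m[long$snp_a[i], long$snp_b[i]] <- long$r2[i]
      m[long$snp_b[i], long$snp_a[i]] <- long$r2[i]
    }
  } else {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             row.names = 1L, check.names = FALSE)
    m <- as.matrix(raw)
  }
  ld_matrix(m, positions = positions)
}

#' Construct and validate an LD matrix
#'
#' @param r2 Square numeric matrix of squared pairwise correlations with SNP
#'   ids as dimnames.
#' @param positions Optional named numeric vector of base-pair positions.
#' @return The validated matrix with class \code{ld_matrix}.
#' @export
ld_matrix <- function(r2, positions = NULL) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) .stopf("LD matrix must be square")
  if (is.null(rownames(r2)) && is.null(colnames(r2))) {
    rownames(r2) <- colnames(r2) <- paste0("snp", seq_len(nrow(r2)))
  } else if (is.null(rownames(r2))) {
    rownames(r2) <- colnames(r2)
  } else if (is.null(colnames(r2))) {
    colnames(r2) <- rownames(r2)
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    .stopf("LD r2 entries must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) .stopf("LD matrix is not symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) .stopf("LD matrix diagonal must equal 1")
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  if (!is.null(positions)) {
    if (is.null(names(positions)) || !all(rownames(r2) %in% names(positions))) {
      .stopf("'positions' must be named and cover every SNP in the matrix")
    }
    attr(r2, "positions") <- positions
  }
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Write a results table
#'
#' Tab-separated with a header, floats rendered with enough significant
#' digits to round-trip through \code{read.delim} within relative 1e-6.
#'
#' @param records A data.frame of results (may have zero rows).
#' @param path Output path; the directory must exist.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) .stopf("'records' must be a data.frame")
  if (!dir.exists(dirname(path))) .stopf("unwritable path: %s", path)
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 12, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
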