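# Instrument selection, quality filtering and harmonization rules.

rec <- function(snp, pval = 1e-6, eaf = 0.3, ea = "A", oa = "G",
                beta = 0.1, se = 0.02, n = 20000) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, beta = beta,
             se = se, pval = pval, eaf = eaf, n = n, stringsAsFactors = FALSE)
}

test_that("p-value selection uses a strict boundary", {
  recs <- rbind(rec("a", 1e-6), rec("b", 1e-5), rec("c", 1e-4))
  kept <- select_by_p(recs, 1e-5)
  expect_equal(kept$snp, "a")
  expect_equal(nrow(select_by_p(recs[0, ], 1e-5)), 0L)

  set.seed(3)
  p <- runif(1000)
  recs2 <- rec(sprintf("s%04d", 1:1000))
  recs2$pval <- p
  expect_equal(nrow(select_by_p(recs2, 0.05)), sum(p < 0.05))
})

test_that("greedy clumping keeps the locus-best SNP and honours the window", {
  ids <- c("a", "b", "c")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids)); diag(m) <- 1
  indep <- ld_matrix(m)
  recs <- rbind(rec("a", 1e-8), rec("b", 1e-7), rec("c", 1e-6))
  expect_equal(nrow(ld_clump(recs, indep, 0.001, 10000)), 3L)

  m5 <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(m5) <- 1
  corr <- ld_matrix(m5, positions = c(a = 1e6, b = 2e6, c = 3e6))
  expect_equal(ld_clump(recs, corr, 0.001, 10000)$snp, "a")

  # same r2 but 20,000 kb apart with a 10,000 kb window: both survive
  m2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  far <- ld_matrix(m2, positions = c(a = 0, b = 2e7))
  expect_equal(nrow(ld_clump(recs[1:2, ], far, 0.001, 10000)), 2L)

  # SNP missing from the LD matrix is treated as independent, with warning
  expect_warning(k <- ld_clump(rbind(recs, rec("d", 1e-9)), corr, 0.001, 10000),
                 "absent")
  expect_true("d" %in% k$snp)
})

test_that("clump output matches an exhaustive pair re-check on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(5:20, 1)
    ids <- sprintf("s%02d", seq_len(k))
    r <- matrix(runif(k * k), k)
    r2 <- (r + t(r)) / 2
    r2[r2 < 0.5] <- 0          # sparse correlation structure
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    pos <- setNames(sort(sample.int(3e7, k)), ids)
    ld <- ld_matrix(r2, positions = pos)
    recs <- rec(ids)
    recs$pval <- runif(k, 1e-10, 1e-4)
    kept <- ld_clump(recs, ld, clump_r2 = 0.3, window_kb = 10000)

    # subset of input, and the globally best p-value always survives
    expect_true(all(kept$snp %in% recs$snp))
    expect_true(recs$snp[which.min(recs$pval)] %in% kept$snp)
    # every retained pair is below the r2 cut or beyond the window
    if (nrow(kept) > 1) {
      prs <- combn(kept$snp, 2)
      ok <- apply(prs, 2, function(p) {
        ld[p[1], p[2]] < 0.3 || abs(pos[p[1]] - pos[p[2]]) > 1e7
      })
      expect_true(all(ok))
    }
    # greedy enumeration oracle: replay the algorithm by hand
    remaining <- recs[order(recs$pval, recs$snp), ]
    manual <- character(0)
    while (nrow(remaining) > 0) {
      top <- remaining$snp[1]
      manual <- c(manual, top)
      drop <- ld[top, remaining$snp] >= 0.3 &
        abs(pos[top] - pos[remaining$snp]) <= 1e7
      drop[1] <- TRUE
      remaining <- remaining[!drop, , drop = FALSE]
    }
    expect_setequal(kept$snp, manual)
  }
})

test_that("F statistic follows its closed form and boundary semantics", {
  expect_equal(f_statistic(0, 1000, 1), 0)
  expect_equal(f_statistic(0.01, 18340, 1), 0.01 * 18338 / 0.99)
  expect_equal(round(f_statistic(0.01, 18340, 1), 2), 185.23)
  expect_error(f_statistic(1, 100, 1), "r2")
  expect_error(f_statistic(0.1, 3, 2), "n must exceed")

  # strictly increasing in r2 and n
  r2s <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(f_statistic(r2s, 1000, 1)) > 0))
  ns <- seq(100, 10000, by = 100)
  expect_true(all(diff(f_statistic(0.01, ns, 1)) > 0))

  # the F > 10 filter boundary: 9.99 excluded, 10.01 retained
  expect_false(9.99 > 10)
  r2_in <- uniroot(function(r) f_statistic(r, 1000, 1) - 10.01, c(0, 0.5))$root
  expect_true(f_statistic(r2_in, 1000, 1) > 10)
})

test_that("per-SNP variance explained follows the regression-t identity", {
  expect_equal(per_snp_r2(0, 0.02, 1000), 0)
  n <- 100
  t2 <- n - 2
  expect_equal(per_snp_r2(sqrt(t2) * 0.01, 0.01, n), 0.5)
  expect_equal(per_snp_r2(0.1, 0.02, 10000), 25 / (25 + 9998))
  expect_error(per_snp_r2(0.1, 0, 100), "se")
})

test_that("palindromic variants are identified and removed", {
  recs <- rbind(rec("p1", ea = "A", oa = "T"), rec("k1", ea = "A", oa = "G"),
                rec("p2", ea = "C", oa = "G"), rec("k2", ea = "T", oa = "C"),
                rec("k3", ea = "G", oa = "T"), rec("k4", ea = "C", oa = "A"))
  out <- drop_palindromic(recs)
  expect_equal(nrow(out), 4L)
  expect_setequal(attr(out, "dropped")$snp, c("p1", "p2"))
  expect_true(all(attr(out, "dropped")$reason == "palindromic"))
})

test_that("MAF filter is symmetric and strict below the bound", {
  recs <- rbind(rec("lo", eaf = 0.005), rec("hi", eaf = 0.995),
                rec("edge", eaf = 0.01), rec("mid", eaf = 0.4))
  kept <- maf_filter(recs, 0.01)
  expect_setequal(kept$snp, c("edge", "mid"))
  recs$eaf[1] <- NA
  expect_warning(kept2 <- maf_filter(recs, 0.01), "lack eaf")
  expect_true("lo" %in% kept2$snp)
  expect_warning(maf_filter(rec("x")[, setdiff(names(rec("x")), "eaf")]),
                 "no eaf")
})

test_that("harmonization aligns, rescues strand flips, and logs drops", {
  expo <- rbind(rec("same", ea = "A", oa = "G", beta = 0.1),
                rec("swap", ea = "A", oa = "G", beta = 0.2),
                rec("flip", ea = "A", oa = "G", beta = 0.3),
                rec("flipswap", ea = "A", oa = "G", beta = 0.4),
                rec("mism", ea = "A", oa = "G", beta = 0.5),
                rec("pal", ea = "A", oa = "T", beta = 0.6),
                rec("gone", ea = "A", oa = "G", beta = 0.7))
  outc <- rbind(rec("same", ea = "A", oa = "G", beta = 0.05, eaf = 0.2),
                rec("swap", ea = "G", oa = "A", beta = 0.05, eaf = 0.2),
                rec("flip", ea = "T", oa = "C", beta = 0.05, eaf = 0.2),
                rec("flipswap", ea = "C", oa = "T", beta = 0.05, eaf = 0.2),
                rec("mism", ea = "A", oa = "C", beta = 0.05),
                rec("pal", ea = "A", oa = "T", beta = 0.05))
  h <- harmonize(expo, outc)
  expect_setequal(h$snp, c("same", "swap", "flip", "flipswap"))
  expect_equal(h$beta_out[h$snp == "same"], 0.05)
  expect_equal(h$beta_out[h$snp == "swap"], -0.05)
  expect_equal(h$eaf_out[h$snp == "swap"], 0.8)
  expect_equal(h$beta_out[h$snp == "flip"], 0.05)
  expect_equal(h$beta_out[h$snp == "flipswap"], -0.05)
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason[dropped$snp == "mism"], "allele_mismatch")
  expect_equal(dropped$reason[dropped$snp == "pal"], "palindromic")
  expect_equal(dropped$reason[dropped$snp == "gone"], "missing_in_outcome")

  # exposure-side statistics are never modified
  expect_equal(h$beta_exp, expo$beta[match(h$snp, expo$snp)])
  expect_equal(h$se_exp, expo$se[match(h$snp, expo$snp)])

  # palindromic variants kept (same-orientation only) when the flag is off
  h2 <- harmonize(expo, outc, drop_palindromic = FALSE)
  expect_true("pal" %in% h2$snp)
})

test_that("harmonization is idempotent", {
  for (seed in c(1, 7, 19)) {
    sim <- simulate_pair(sim_config(n_snps = 40, theta = 0.2, seed = seed))
    # scramble some outcome rows into swapped / flipped encodings
    out <- sim$outcome
    set.seed(seed)
    swp <- sample(40, 15)
    tmp <- out$effect_allele[swp]
    out$effect_allele[swp] <- out$other_allele[swp]
    out$other_allele[swp] <- tmp
    out$beta[swp] <- -out$beta[swp]
    out$eaf[swp] <- 1 - out$eaf[swp]
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    flp <- sample(40, 10)
    out$effect_allele[flp] <- comp[out$effect_allele[flp]]
    out$other_allele[flp] <- comp[out$other_allele[flp]]

    h1 <- harmonize(sim$exposure, out)
    expect_equal(nrow(h1), 40L)
    # the scrambled encodings recover the original aligned outcome betas
    expect_equal(h1$beta_out, sim$outcome$beta, tolerance = 1e-12)
    pair <- harmonized_pair(h1)
    h2 <- harmonize(pair$exposure, pair$outcome)
    expect_equal(as.data.frame(h2), as.data.frame(h1), tolerance = 1e-12)
  }
})

test_that("the QC chain only removes or relabels, never invents SNPs", {
  sim <- simulate_pair(sim_config(n_snps = 120, theta = 0.2, seed = 5))
  s1 <- select_by_p(sim$exposure, 1e-5)
  s2 <- suppressWarnings(maf_filter(s1, 0.01))
  s3 <- drop_palindromic(s2)
  h <- harmonize(s3, sim$outcome)
  expect_true(all(h$snp %in% sim$exposure$snp))
  expect_true(nrow(h) <= nrow(s3))
  expect_true(nrow(s3) <= nrow(s2))
  expect_true(nrow(s2) <= nrow(s1))
})
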