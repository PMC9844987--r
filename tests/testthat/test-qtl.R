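test_that("fractions divide decomposed by parent TPM with zero-parent flag", {
  dp <- rbind(a = c(5, 0, 3))
  par <- rbind(a = c(20, 0, 12))
  colnames(dp) <- colnames(par) <- paste0("s", 1:3)
  f <- compute_fractions(dp, par)
  expect_equal(unname(f[1, ]), c(0.25, 0, 0.25))
  expect_equal(attr(f, "n_zero_parent"), 1)
  expect_error(compute_fractions(dp, par[, 1:2]), "mismatched")
})

test_that("fractions of one parent sum to at most 1 per sample", {
  pan <- simulate_panel(sim_config(n_samples = 12, n_promoters = 15,
                                   seed = 23, mean_log_expression = 1.5,
                                   log10_range = 1))
  proms <- build_promoters(pan$ctss, pan$meta)
  dps <- decompose_promoters(proms, pan$ctss, pan$meta)
  sums <- rowsum(dps$fraction, dps$clusters$parent_id)
  expect_true(all(sums <= 1 + 1e-9))
})

test_that("expression PCs are orthogonal, equivariant and capture rank", {
  set.seed(8)
  # rank-1 matrix: PC1 explains everything
  u <- rnorm(30); v <- rnorm(10)
  tpm <- outer(u, v)
  rownames(tpm) <- sprintf("f%02d", 1:30)
  pr <- stats::prcomp(t(tpm), center = TRUE)
  expect_gt(pr$sdev[1]^2 / sum(pr$sdev^2), 1 - 1e-10)

  tpm2 <- matrix(rnorm(300), 30, 10,
                 dimnames = list(sprintf("f%02d", 1:30), letters[1:10]))
  pcs <- expression_pcs(tpm2, k = 5)
  expect_equal(dim(pcs), c(10L, 5L))
  g <- crossprod(pcs)
  expect_lt(max(abs(g[lower.tri(g)])), 1e-8)
  # permuting samples permutes scores
  perm <- sample(10)
  pcs_p <- expression_pcs(tpm2[, perm], k = 5)
  expect_equal(abs(pcs_p), abs(pcs[perm, ]), tolerance = 1e-8)
  expect_error(expression_pcs(tpm2, k = 10), "smaller")
})

test_that("cis OLS recovers exact and adjusted effects", {
  geno <- genotype_matrix(
    data.frame(snp_id = "s1", chrom = "c", pos = 100L, ref = "A",
               alt = "G"),
    rbind(c(0, 1, 2)))
  resp <- rbind(f1 = c(0, 2, 4))
  summ <- data.frame(feature_id = "f1", chrom = "c", summit = 90L)
  r <- map_cis_qtl(resp, summ, geno, min_maf = 0.1)
  expect_equal(r$beta, 2)
  expect_equal(r$p, 0)
  expect_equal(r$q, r$p)         # single test
  expect_equal(r$distance, 10L)

  # covariate adjustment removes a planted confounder
  set.seed(44)
  n <- 108
  conf <- rnorm(n)
  d <- rbinom(n, 2, 0.3)
  y <- 3 * conf + rnorm(n, sd = 0.1)
  geno2 <- genotype_matrix(
    data.frame(snp_id = "s1", chrom = "c", pos = 100L, ref = "A",
               alt = "G"), rbind(d))
  resp2 <- rbind(f1 = y)
  r2 <- map_cis_qtl(resp2, summ, geno2, covariates = cbind(conf = conf))
  expect_lt(abs(r2$beta), 0.05)

  # missing dosages are dropped per test
  d3 <- d; d3[1:5] <- NA
  geno3 <- genotype_matrix(geno2$info, rbind(d3))
  r3 <- map_cis_qtl(resp2, summ, geno3, covariates = cbind(conf = conf))
  expect_false(anyNA(r3$beta))

  # rank-deficient designs are rejected with the offending column named
  expect_error(
    map_cis_qtl(resp2, summ, geno2,
                covariates = cbind(a = d, b = conf)),
    "collinear")

  # SNPs outside the window or below the MAF threshold are not tested
  geno4 <- genotype_matrix(
    data.frame(snp_id = c("near", "far", "rare"), chrom = "c",
               pos = c(100L, 90000L, 110L), ref = "A", alt = "G"),
    rbind(d, d, rbinom(n, 2, 0.02)))
  r4 <- map_cis_qtl(resp2, summ, geno4, window = 25000, min_maf = 0.1)
  expect_equal(r4$snp_id, "near")
})

test_that("null simulations give calibrated p-values", {
  set.seed(9)
  n <- 108; m <- 1000
  resp <- matrix(rnorm(m * n), m, n,
                 dimnames = list(sprintf("f%04d", 1:m), NULL))
  geno <- genotype_matrix(
    data.frame(snp_id = sprintf("s%04d", 1:m), chrom = "c",
               pos = rep(100L, m), ref = "A", alt = "G"),
    simulate_genotypes(n, 0.3, m))
  summ <- data.frame(feature_id = rownames(resp), chrom = "c",
                     summit = 90L)
  # one cis SNP per feature: restrict each feature to its own SNP by
  # fitting directly
  p <- vapply(seq_len(m), function(i)
    promvar:::fit_dosage_ols(resp[i, ], geno$dosage[i, ])["p"],
    numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("BH q-values match the step-up rule and are monotone", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # family size larger than the supplied subset
  expect_equal(bh_fdr(c(0.01, 0.02), m = 4), c(0.04, 0.04))
  # monotonicity under p perturbation
  set.seed(12)
  p0 <- runif(50)
  q0 <- bh_fdr(p0)
  p1 <- p0; i <- sample(50, 1); p1[i] <- min(1, p0[i] + 0.2)
  expect_true(all(bh_fdr(p1) >= q0 - 1e-12))
})

test_that("lead SNP selection applies the documented tie-breaks", {
  res <- data.frame(
    feature_id = "f", kind = "promoter",
    snp_id = c("a", "b", "c", "d"),
    chrom = "c", pos = 1:4, distance = c(10, 5, -3, 8),
    beta = c(1, 0.1, 0.3, 0.3), se = 1, t = 1,
    p = c(0.01, 0.001, 0.001, 0.001), q = 1,
    stringsAsFactors = FALSE)
  # min p wins; among ties larger |beta|; then smaller |distance|
  expect_equal(lead_snp(res)$snp_id, "c")
  res$beta <- c(1, 0.3, 0.3, 0.3)
  expect_equal(lead_snp(res)$snp_id, "c")   # |distance| 3 < 5 < 8
  res2 <- res[1, , drop = FALSE]
  expect_equal(lead_snp(res2)$snp_id, "a")
})

test_that("relative effect size is the maximal relative group change", {
  d <- rep(0:2, each = 4)
  expect_equal(relative_effect_size(rep(10, 12), d), 0)
  expect_equal(relative_effect_size(rep(c(10, 12, 14), each = 4), d), 0.4)
  # undersized dosage-2 group is excluded from the max
  d2 <- c(rep(0, 5), rep(1, 5), rep(2, 2))
  tpm <- c(rep(10, 5), rep(12, 5), rep(100, 2))
  expect_equal(relative_effect_size(tpm, d2), 0.2)
  # undefined when the reference group is too small
  expect_true(is.na(relative_effect_size(1:6, c(0, 0, 1, 1, 2, 2))))
})

test_that("stabilizing frQTLs need two significant opposite-sign effects", {
  base <- data.frame(parent_id = "p1", snp_id = "s1",
                     feature_id = c("dp1", "dp2"),
                     stringsAsFactors = FALSE)
  res <- cbind(base, beta = c(0.2, -0.2), q = c(0.01, 0.01))
  expect_equal(detect_stabilizing_frqtl(res), "p1")
  res2 <- cbind(base, beta = c(0.2, 0.3), q = c(0.01, 0.01))
  expect_equal(detect_stabilizing_frqtl(res2), character(0))
  res3 <- cbind(base, beta = c(0.2, -0.2), q = c(0.01, 0.20))
  expect_equal(detect_stabilizing_frqtl(res3), character(0))
  # effects on different SNPs do not combine
  res4 <- cbind(base, beta = c(0.2, -0.2), q = c(0.01, 0.01))
  res4$snp_id <- c("s1", "s2")
  expect_equal(detect_stabilizing_frqtl(res4), character(0))
})

test_that("covariate construction one-hot encodes and drops single levels", {
  meta <- library_meta(paste0("s", 1:6), rep(1e6, 6),
                       batch = c("a", "a", "b", "b", "c", "c"),
                       population = rep("x", 6))
  expect_warning(Z <- make_covariates(meta), "single level")
  expect_equal(ncol(Z), 2L)  # batch b and c indicators
  expect_true(all(Z %in% c(0, 1)))
  pcs <- matrix(rnorm(12), 6, 2)
  Z2 <- suppressWarnings(make_covariates(meta, pcs = pcs))
  expect_equal(ncol(Z2), 4L)
})
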