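# the V0/V1 filtering cascade

mini_vt <- function(gt, dp = NULL, gq = NULL, ad_ref = NULL, ad_alt = NULL,
                    alt = "G", qd = 20, mq = 60, mqrs = 0, class = NULL) {
  n <- nrow(gt)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A",
                      alt = rep_len(alt, n), qd = rep_len(qd, n),
                      mq = rep_len(mq, n), mqranksum = rep_len(mqrs, n),
                      stringsAsFactors = FALSE)
  if (!is.null(class)) sites$class <- rep_len(class, n)
  variant_table(sites, gt, dp, gq, ad_ref, ad_alt)
}

test_that("sites split into SNPs, invariants and discarded", {
  gt <- matrix(0L, 4, 2)
  vt <- mini_vt(gt, alt = c("T", ".", "AT", "<NON_REF>"))
  sp <- split_sites(vt)
  expect_equal(unname(sp$counts), c(1L, 2L, 1L))
  expect_equal(sp$snps$sites$pos, 1L)
  expect_equal(sp$discarded$sites$alt, "AT")
})

test_that("hard filter fails on strict inequalities only; missing passes", {
  gt <- matrix(0L, 5, 2)
  vt <- mini_vt(gt, qd = c(1.9, 2.0, 20, 20, NA),
                mq = c(60, 60, 39.9, 40.0, NA),
                mqrs = c(0, 0, 0, -12.5, NA))
  out <- hard_site_filter(vt)
  expect_equal(out$sites$hard_fail, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$sites$annotation_missing,
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("HDplot statistics match hand arithmetic", {
  ## 10 samples: 2 hets with AD 15/5, rest hom-ref
  gt <- matrix(0L, 1, 10)
  gt[1, 1:2] <- 1L
  ad_ref <- matrix(20L, 1, 10); ad_alt <- matrix(0L, 1, 10)
  ad_ref[1, 1:2] <- 15L; ad_alt[1, 1:2] <- 5L
  vt <- mini_vt(gt, dp = ad_ref + ad_alt, gq = matrix(50L, 1, 10),
                ad_ref = ad_ref, ad_alt = ad_alt)
  hd <- hdplot(vt)
  expect_equal(hd$H, 0.2)
  expect_equal(hd$A, 30); expect_equal(hd$B, 10)
  expect_equal(hd$ratio, 0.75)
  expect_equal(hd$D, 20 / sqrt(40), tolerance = 1e-12)  # 3.1623
  ## A = B = 20: D = 0, symmetric pass
  ad_ref[1, 1:2] <- 10L; ad_alt[1, 1:2] <- 10L
  vt2 <- mini_vt(gt, dp = ad_ref + ad_alt, gq = matrix(50L, 1, 10),
                 ad_ref = ad_ref, ad_alt = ad_alt)
  hd2 <- hdplot(vt2)
  expect_equal(hd2$D, 0)
  expect_equal(hd2$ratio, 0.5)
  expect_false(hdplot_filter(vt2)$sites$hd_fail)
  ## 7 hets of 10 genotyped: H = 0.7 > 0.6 flagged
  gt3 <- matrix(0L, 1, 10); gt3[1, 1:7] <- 1L
  ar <- matrix(10L, 1, 10); aa <- matrix(0L, 1, 10); aa[1, 1:7] <- 10L
  vt3 <- mini_vt(gt3, dp = ar + aa, gq = matrix(50L, 1, 10),
                 ad_ref = ar, ad_alt = aa)
  expect_true(hdplot_filter(vt3)$sites$hd_fail)
})

test_that("genotype filter masks DP/GQ failures and applies locus rules", {
  ## 10 samples; one locus per rule
  n <- 10
  mk <- function(dp_row, gq_row, het_cols = 7:9, alt_col = 10) {
    gt <- matrix(0L, 1, n); gt[1, het_cols] <- 1L; gt[1, alt_col] <- 2L
    ad_alt <- matrix(0L, 1, n)
    ad_alt[1, het_cols] <- dp_row[het_cols] %/% 2L
    ad_alt[1, alt_col] <- dp_row[alt_col]
    ad_ref <- matrix(dp_row, 1, n) - ad_alt
    mini_vt(gt, dp = matrix(dp_row, 1, n), gq = matrix(gq_row, 1, n),
            ad_ref = ad_ref, ad_alt = ad_alt)
  }
  ## DP 5 genotype is masked but the locus survives
  vt <- mk(c(5L, rep(20L, 9)), rep(50L, n))
  g <- genotype_filter(vt)
  expect_true(is.na(g$vt$gt[1, 1]))
  expect_equal(g$counts[["retained"]], 1L)
  ## GQ 19 masked, GQ 20 kept
  vt2 <- mk(rep(20L, n), c(19L, 20L, rep(50L, 8)))
  g2 <- genotype_filter(vt2)
  expect_true(is.na(g2$vt$gt[1, 1]))
  expect_false(is.na(g2$vt$gt[1, 2]))
  ## exactly n/2 samples with DP 7 (strictly > 6) retains the locus
  vt3 <- mk(c(rep(7L, 5), rep(6L, 5)), rep(50L, n))
  expect_equal(genotype_filter(vt3)$counts[["retained"]], 1L)
  vt4 <- mk(c(rep(7L, 4), rep(6L, 6)), rep(50L, n))
  expect_equal(genotype_filter(vt4)$counts[["fail_half_depth"]], 1L)
  ## minor allele needs 3 supporting reads
  gt <- matrix(0L, 2, n)
  gt[, n] <- 2L
  dp <- matrix(20L, 2, n); dp[1, n] <- 2L; dp[2, n] <- 3L
  gq <- matrix(50L, 2, n); gq[, n] <- 10L
  ad_alt <- matrix(0L, 2, n); ad_alt[1, n] <- 2L; ad_alt[2, n] <- 3L
  vt5 <- mini_vt(gt, dp = dp, gq = gq, ad_ref = dp - ad_alt,
                 ad_alt = ad_alt)
  g5 <- genotype_filter(vt5)
  expect_equal(g5$vt$sites$pos, 2L)
  expect_equal(g5$counts[["fail_minor_reads"]], 1L)
  ## non-biallelic sites are dropped
  vt6 <- mk(rep(20L, n), rep(50L, n))
  vt6$sites$alt <- "G,T"
  expect_equal(genotype_filter(vt6)$counts[["non_biallelic"]], 1L)
})

test_that("sample missingness removes strictly above 80 percent", {
  gt <- matrix(0L, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  gt[1:41, 2] <- NA_integer_   # 0.82
  gt[1:40, 3] <- NA_integer_   # 0.80 exactly
  sm <- sample_missingness_filter(variant_table(
    data.frame(chrom = "chr1", pos = 1:50, ref = "A", alt = "G"), gt))
  expect_equal(sm$removed$sample, "b")
  expect_equal(sm$vt$samples, c("a", "c"))
  gt_all <- matrix(NA_integer_, 10, 2)
  expect_error(sample_missingness_filter(variant_table(
    data.frame(chrom = "chr1", pos = 1:10, ref = "A", alt = "G"), gt_all)),
    "all samples")
})

test_that("invariant filter needs depth strictly above six in half the samples", {
  mkinv <- function(dp_row) {
    n <- length(dp_row)
    gt <- matrix(ifelse(dp_row > 0, 0L, NA_integer_), 1, n)
    mini_vt(gt, dp = matrix(dp_row, 1, n), alt = ".", qd = NA, mq = NA,
            mqrs = NA)
  }
  expect_equal(invariant_filter(mkinv(rep(10L, 10)))$counts[["retained"]], 1L)
  expect_equal(invariant_filter(mkinv(rep(6L, 10)))$counts[["retained"]], 0L)
  expect_equal(invariant_filter(mkinv(c(rep(7L, 5),
                                        rep(0L, 5))))$counts[["retained"]],
               1L)
})

test_that("merge and V1 bookkeeping", {
  sim <- simulate_population_vcf(n_pops = 2, n_per_pop = 5, n_loci = 30,
                                 n_invariant = 10, seed = 51)
  sp <- split_sites(sim$vt)
  v0 <- merge_v0(sp$snps, sp$invariants)
  expect_equal(nrow(v0$sites), 40L)
  expect_false(is.unsorted(v0$sites$pos))
  ## sample mismatch rejected
  inv_bad <- vt_subset(sp$invariants, j = 1:5)
  expect_error(merge_v0(sp$snps, inv_bad), "sample sets differ")
  ## V1 removals
  v1 <- build_v1(v0, v0$samples[1])
  expect_equal(length(v1$samples), 9L)
  expect_error(build_v1(v0, "nonexistent"), "unknown sample")
  expect_identical(build_v1(v0, character(0)), v0)
})

test_that("tightening thresholds never increases retained sites", {
  sim <- simulate_population_vcf(n_pops = 2, n_per_pop = 10, n_loci = 300,
                                 depth_mean = 10, depth_disp = 2,
                                 seed = 52)
  sp <- split_sites(sim$vt)
  r1 <- genotype_filter(sp$snps, filter_config())$counts[["retained"]]
  r2 <- genotype_filter(sp$snps,
                        filter_config(dp_min = 10L))$counts[["retained"]]
  r3 <- genotype_filter(sp$snps,
                        filter_config(minor_reads_min = 10L))$counts[["retained"]]
  expect_lte(r2, r1)
  expect_lte(r3, r1)
})

test_that("the 50-site cascade reproduces the enumerated outcome", {
  fx <- make_cascade_fixture()
  res <- filter_cascade(fx$vt)
  ex <- fx$expected
  expect_equal(res$removed_samples$sample, ex$removed_samples)
  expect_equal(res$v0$sites$pos, ex$v0_pos)
  expect_equal(res$v0$samples, ex$v0_samples)
  ## per-stage reasons
  snps <- hdplot_filter(hard_site_filter(split_sites(fx$vt)$snps))
  expect_equal(snps$sites$pos[snps$sites$hard_fail], ex$hard_fail)
  expect_equal(snps$sites$pos[snps$sites$hd_fail], ex$hd_fail)
  ## masked genotypes persist into V0
  for (m in ex$masked) {
    i <- which(res$v0$sites$pos == as.integer(m[1]))
    expect_true(is.na(res$v0$gt[i, m[2]]))
  }
  ## conservation: every input site is retained or dropped with a reason
  n_dropped <- length(c(ex$hard_fail, ex$hd_fail, ex$non_biallelic,
                        ex$discarded, ex$half_depth_fail,
                        ex$minor_reads_fail, ex$invariant_dropped))
  expect_equal(length(ex$v0_pos) + n_dropped, 50L)
})

test_that("the cascade result is identical after a VCF round trip", {
  fx <- make_cascade_fixture()
  f <- tempfile(fileext = ".vcf")
  write_vcf(fx$vt, f)
  res <- filter_cascade(read_vcf(f))
  expect_equal(res$v0$sites$pos, fx$expected$v0_pos)
  expect_equal(res$removed_samples$sample, fx$expected$removed_samples)
})
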