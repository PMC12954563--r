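# Hand-built 50-site filter-cascade fixture with a fully enumerated
# expected outcome. 12 samples: s01-s10 well-covered, s11 exactly at the
# 80% missingness bound (kept), s12 missing everywhere (removed).
#
# Site plan (pos = site number on chr1), expected fate in brackets:
#   1  baseline good site                        [retained]
#   2  QD = 1.9                                  [hard filter]
#   3  QD = 2.0 boundary                         [retained]
#   4  MQ = 39.9                                 [hard filter]
#   5  MQ = 40.0 boundary                        [retained]
#   6  MQRankSum = -12.6                         [hard filter]
#   7  MQRankSum = -12.5 boundary                [retained]
#   8  all annotations missing                   [retained]
#   9  H = 7/10 = 0.7                            [HDplot H]
#  10  H = 6/10 = 0.6 boundary                   [retained]
#  11  het ratio 0.9                             [HDplot ratio]
#  12  D = 192/sqrt(320) = 10.73                 [HDplot D]
#  13  ratio 0.8 boundary, D = 7.59              [retained]
#  14  ratio 0.2 boundary, D = -7.59             [retained]
#  15  triallelic ALT "G,T"                      [non-biallelic]
#  16  indel ALT "AT"                            [discarded at split]
#  17  invariant, DP 10 in s01-s10               [retained]
#  18  invariant, DP 6 everywhere                [invariant filter: need >6]
#  19  invariant, DP 7 in s01-s06, 0 elsewhere   [retained: 6 of 11 >= 5.5]
#  20  invariant, DP 5 everywhere                [invariant filter]
#  21  s06 DP = 5                                [retained, s06 masked]
#  22  s06 GQ = 19                               [retained, s06 masked]
#  23  s06 GQ = 20 boundary                      [retained, s06 called]
#  24  DP 7 in s01-s06, DP 6 in s07-s11          [retained: 6 of 12 >= 6]
#  25  DP 7 in s01-s05, DP 6 in s06-s11          [half-depth: 5 of 12 < 6]
#  26  minor allele reads 2 (s10 AD 0,2 DP 2)    [minor reads]
#  27  minor allele reads 3 (s10 AD 0,3 DP 3)    [retained, s10 masked]
#  28-49  baseline good sites                    [retained]
#  50  invariant, DP 10 in s01-s10               [retained]
#
# s11 is called only at sites 13, 14, 21, 22, 23, 24, 27: missing at 28 of
# the 35 retained SNP sites = exactly 0.80, kept under the strict rule.
make_cascade_fixture <- function() {
  n <- 50L; ns <- 12L
  samples <- sprintf("s%02d", 1:12)
  gt <- matrix(NA_integer_, n, ns, dimnames = list(NULL, samples))
  dp <- gq <- ad_ref <- ad_alt <- gt

  baseline <- function(i) {
    gt[i, 1:6] <<- 0L; gt[i, 7:9] <<- 1L; gt[i, 10] <<- 2L; gt[i, 11] <<- 0L
    dp[i, 1:11] <<- 20L; dp[i, 12] <<- 0L
    gq[i, 1:11] <<- 50L; gq[i, 12] <<- 0L
    ad_ref[i, 1:6] <<- 20L; ad_alt[i, 1:6] <<- 0L
    ad_ref[i, 7:9] <<- 10L; ad_alt[i, 7:9] <<- 10L
    ad_ref[i, 10] <<- 0L; ad_alt[i, 10] <<- 20L
    ad_ref[i, 11] <<- 20L; ad_alt[i, 11] <<- 0L
    ad_ref[i, 12] <<- 0L; ad_alt[i, 12] <<- 0L
  }
  snp_sites <- setdiff(1:50, c(16, 17, 18, 19, 20, 50))
  for (i in snp_sites) baseline(i)

  qd <- rep(20, n); mq <- rep(60, n); mqrs <- rep(0, n)
  qd[2] <- 1.9; qd[3] <- 2.0
  mq[4] <- 39.9; mq[5] <- 40.0
  mqrs[6] <- -12.6; mqrs[7] <- -12.5
  qd[8] <- mq[8] <- mqrs[8] <- NA

  set_het <- function(i, j, r, a) {
    gt[i, j] <<- 1L; ad_ref[i, j] <<- r; ad_alt[i, j] <<- a
    dp[i, j] <<- r + a; gq[i, j] <<- 50L
  }
  ## 9: seven hets of ten called
  gt[9, 1:7] <- 1L; ad_ref[9, 1:7] <- 10L; ad_alt[9, 1:7] <- 10L
  gt[9, 8:10] <- 0L; ad_ref[9, 8:10] <- 20L; ad_alt[9, 8:10] <- 0L
  ## 10: six hets of ten called
  gt[10, 1:6] <- 1L; ad_ref[10, 1:6] <- 10L; ad_alt[10, 1:6] <- 10L
  gt[10, 7:10] <- 0L; ad_ref[10, 7:10] <- 20L; ad_alt[10, 7:10] <- 0L
  ## 11: three hets with AD 18/2 -> ratio 54/60 = 0.9
  for (j in 7:9) set_het(11, j, 18L, 2L)
  ## 12: four hets DP 80, AD 64/16 -> D = 192/sqrt(320) = 10.73
  for (j in 7:10) set_het(12, j, 64L, 16L)
  ## 13: two hets AD 64/16 -> ratio 0.8, D = 7.59
  for (j in 7:8) set_het(13, j, 64L, 16L)
  gt[13, 9] <- 0L; ad_ref[13, 9] <- 20L; ad_alt[13, 9] <- 0L
  ## 14: two hets AD 16/64 -> ratio 0.2, D = -7.59
  for (j in 7:8) set_het(14, j, 16L, 64L)
  gt[14, 9] <- 0L; ad_ref[14, 9] <- 20L; ad_alt[14, 9] <- 0L
  ## 21: s06 DP 5 -> masked
  dp[21, 6] <- 5L; ad_ref[21, 6] <- 5L
  ## 22/23: s06 GQ 19 (masked) / 20 (kept)
  gq[22, 6] <- 19L; gq[23, 6] <- 20L
  ## 24/25: half-depth boundary; hets get AD 3/3 at DP 6
  for (i in 24:25) {
    k <- if (i == 24) 6L else 5L
    dp[i, 1:k] <- 7L; dp[i, (k + 1):11] <- 6L
    ad_ref[i, 1:6] <- dp[i, 1:6]; ad_alt[i, 1:6] <- 0L
    for (j in 7:9) { ad_ref[i, j] <- 3L; ad_alt[i, j] <- 3L }
    ad_ref[i, 10] <- 0L; ad_alt[i, 10] <- dp[i, 10]
    ad_ref[i, 11] <- dp[i, 11]; ad_alt[i, 11] <- 0L
  }
  ## 26/27: minor-allele read support 2 / 3, no heterozygotes
  for (i in 26:27) {
    gt[i, 7:9] <- 0L; ad_ref[i, 7:9] <- 20L; ad_alt[i, 7:9] <- 0L
    d10 <- if (i == 26) 2L else 3L
    gt[i, 10] <- 2L; dp[i, 10] <- d10; gq[i, 10] <- 10L
    ad_ref[i, 10] <- 0L; ad_alt[i, 10] <- d10
  }
  ## s11 called only at these SNP sites
  s11_called <- c(13, 14, 21, 22, 23, 24, 27)
  s11_off <- setdiff(snp_sites, s11_called)
  gt[s11_off, 11] <- NA_integer_; dp[s11_off, 11] <- 0L
  gq[s11_off, 11] <- 0L; ad_ref[s11_off, 11] <- 0L; ad_alt[s11_off, 11] <- 0L

  ## invariants
  inv_sites <- c(17, 18, 19, 20, 50)
  dp[17, 1:10] <- 10L; dp[17, 11:12] <- 0L
  dp[18, ] <- 6L
  dp[19, 1:6] <- 7L; dp[19, 7:12] <- 0L
  dp[20, ] <- 5L
  dp[50, 1:10] <- 10L; dp[50, 11:12] <- 0L
  for (i in inv_sites) gt[i, ] <- ifelse(dp[i, ] > 0L, 0L, NA_integer_)

  alt <- rep("G", n); ref <- rep("A", n)
  alt[inv_sites] <- "."
  alt[15] <- "G,T"
  alt[16] <- "AT"
  sites <- data.frame(chrom = "chr1", pos = 1:50, ref = ref, alt = alt,
                      qd = qd, mq = mq, mqranksum = mqrs,
                      stringsAsFactors = FALSE)
  vt <- variant_table(sites, gt, dp, gq, ad_ref, ad_alt, samples = samples)

  list(vt = vt,
       expected = list(
         hard_fail = c(2, 4, 6),
         hd_fail = c(9, 11, 12),
         non_biallelic = 15,
         discarded = 16,
         half_depth_fail = 25,
         minor_reads_fail = 26,
         invariant_dropped = c(18, 20),
         removed_samples = "s12",
         v0_pos = sort(setdiff(1:50, c(2, 4, 6, 9, 11, 12, 15, 16, 18,
                                       20, 25, 26))),
         v0_samples = sprintf("s%02d", 1:11),
         masked = list(c(21, "s06"), c(22, "s06"), c(27, "s10"))))
}
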