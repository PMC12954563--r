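# diversity and differentiation statistics

test_that("locus stats match hand counts", {
  gt <- rbind(c(0L, 1L, 2L),    # p_alt = 0.5, MAF 0.5, Ho 1/3
              c(0L, 0L, 0L),    # monomorphic
              c(1L, 1L, 1L))    # all het
  ls <- locus_stats(gt)
  expect_equal(ls$maf, c(0.5, 0, 0.5))
  expect_equal(ls$ho, c(1 / 3, 0, 1))
  ## zero-call locus undefined
  ls0 <- locus_stats(matrix(NA_integer_, 1, 3))
  expect_true(is.na(ls0$maf))
})

test_that("Hs matches the Nei-Chesser formula by hand", {
  ## one population, two hets: p = 0.5, Ho = 1, n = 2
  ## Hs = 2 * (1 - 0.5 - 1/4) = 0.5
  gt <- matrix(c(1L, 1L), 1, 2)
  hs <- expected_heterozygosity(gt, c("p1", "p1"))
  expect_equal(hs$hs, 0.5)
  ## monomorphic locus: 0
  expect_equal(expected_heterozygosity(matrix(0L, 1, 4),
                                       rep("p1", 4))$hs, 0)
  ## approaches 1 - sum(p^2) for large n
  sim <- simulate_population_vcf(n_pops = 1, n_per_pop = 400,
                                 n_loci = 200, fst = 0, seed = 61)
  hs_pkg <- expected_heterozygosity(sim$vt$gt, sim$labels$population)$hs
  p <- rowMeans(sim$vt$gt, na.rm = TRUE) / 2
  naive <- mean(2 * p * (1 - p))
  expect_lt(abs(hs_pkg - naive) / naive, 0.01)
})

test_that("theta is 1 for fixed differences and 0 for shared frequencies", {
  gt <- matrix(c(rep(0L, 10), rep(2L, 10)), 5, 20, byrow = TRUE)
  pops <- rep(c("a", "b"), each = 10)
  expect_equal(wc_fst(gt, pops)$theta, 1)
  ## same-frequency populations: theta near 0
  sim <- simulate_population_vcf(n_pops = 2, n_per_pop = 100,
                                 n_loci = 2000, fst = 0, seed = 62)
  expect_lt(abs(wc_fst(sim$vt$gt, sim$labels$population)$theta), 0.01)
  ## single population errors
  expect_error(wc_fst(gt, rep("a", 20)), "two populations")
})

test_that("theta is invariant to label permutation and allele relabelling", {
  sim <- simulate_population_vcf(n_pops = 3, n_per_pop = 20, n_loci = 200,
                                 fst = 0.1, seed = 63)
  gt <- sim$vt$gt; pops <- sim$labels$population
  t0 <- wc_fst(gt, pops)$theta
  relab <- c(a = "z", b = "y", c = "x")
  pops2 <- setNames(relab[match(pops, unique(pops))], NULL)
  expect_equal(wc_fst(gt, pops2)$theta, t0)
  expect_equal(wc_fst(2L - gt, pops)$theta, t0)
  ## Hs / Ho / MAF also invariant to ref/alt swap
  expect_equal(expected_heterozygosity(2L - gt, pops)$hs,
               expected_heterozygosity(gt, pops)$hs)
  expect_equal(locus_stats(2L - gt)$maf, locus_stats(gt)$maf)
})

test_that("theta recovers the Balding-Nichols F with a covering bootstrap CI", {
  sim <- simulate_population_vcf(n_pops = 10, n_per_pop = 25,
                                 n_loci = 2000, fst = 0.10, seed = 64)
  fst <- wc_fst(sim$vt$gt, sim$labels$population)
  expect_lt(abs(fst$theta - 0.10), 0.02)
  ci <- bootstrap_ci(fst, n_boot = 1000, seed = 65)
  expect_true(ci["lower"] <= fst$theta && fst$theta <= ci["upper"])
  expect_identical(ci, bootstrap_ci(fst, n_boot = 1000, seed = 65))
})

test_that("pi matches hand enumeration with invariant sites and missingness", {
  ## site {0/0, 1/1}: 4 copies, 2 ref + 2 alt: D = 4, C = 6
  gt1 <- matrix(c(0L, 2L), 1, 2)
  expect_equal(pi_pixy(gt1)$pi, 4 / 6, tolerance = 1e-12)
  ## plus two fully-called invariant sites: 4 / (6+6+6)
  vt <- variant_table(data.frame(chrom = "chr1", pos = 1:3, ref = "A",
                                 alt = c("G", ".", "."),
                                 class = c("snp", "invariant", "invariant")),
                      rbind(c(0L, 2L), c(0L, 0L), c(0L, 0L)))
  expect_equal(pi_pixy(vt)$pi, 4 / 18, tolerance = 1e-12)
  ## a single called het: D = 1, C = 1
  expect_equal(pi_pixy(matrix(c(1L, NA), 1, 2))$pi, 1)
})

test_that("pi equals all-pairs brute force and windows re-aggregate exactly", {
  set.seed(66)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), 100 * 10, replace = TRUE,
                      prob = c(0.4, 0.2, 0.2, 0.2)), 100, 10)
  expect_equal(pi_pixy(gt)$pi, naive_pi(gt), tolerance = 1e-12)
  vt <- variant_table(data.frame(chrom = "chr1",
                                 pos = sort(sample(1:5000, 100)),
                                 ref = "A", alt = "G"), gt)
  res <- pi_pixy(vt, window_size = 500)
  expect_equal(sum(res$windows$num) / sum(res$windows$denom), res$pi,
               tolerance = 1e-15)
  ## the mean of window ratios is NOT the estimator; the summed form is
  expect_equal(res$num / res$denom, res$pi)
})

test_that("ascertainment toward common alleles inflates MAF/Ho and deflates FST", {
  sim <- simulate_population_vcf(n_pops = 6, n_per_pop = 25,
                                 n_loci = 4000, fst = 0.1,
                                 maf_range = c(0.02, 0.5), seed = 67)
  gt <- sim$vt$gt
  ## "known" class ascertained at intermediate frequency in every
  ## population, the way array discovery panels select SNPs; this is what
  ## depletes differentiated loci and biases FST downward
  perpop_maf <- vapply(unique(sim$labels$population), function(pl) {
    p <- rowMeans(gt[, sim$labels$population == pl, drop = FALSE],
                  na.rm = TRUE) / 2
    pmin(p, 1 - p)
  }, numeric(nrow(gt)))
  known_pool <- which(apply(perpop_maf, 1, min) >= 0.2)
  set.seed(68)
  random_cls <- sample(setdiff(seq_len(nrow(gt)), known_pool[1:500]), 500)
  idx <- c(known_pool[1:500], random_cls)
  cls <- rep(c("known", "random"), each = 500)
  res <- ascertainment_comparison(gt[idx, ], cls,
                                  sim$labels$population)
  expect_lt(res$p_maf, 0.05)
  expect_lt(res$p_ho, 0.05)
  expect_gt(res$stats$median_maf[res$stats$class == "known"],
            res$stats$median_maf[res$stats$class == "random"])
  expect_gt(res$fst_underestimation, 0)
})
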