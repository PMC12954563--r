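# Island-model genotype simulator with sequencing noise. Population allele
# frequencies follow the Balding-Nichols model: at each locus, population
# frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral frequency p,
# so Weir-Cockerham theta estimates F. Read-level noise (negative-binomial
# depth, binomial allele depths, likelihood-based genotype calls and GQ)
# makes the output exercise the same failure modes the filters target,
# including paralog-collapsed loci built by summing reads of two latent loci.

## maximum-likelihood biallelic genotype call + GQ from allele depths under
## a symmetric per-read error rate; vectorised over equal-length vectors
call_genotypes <- function(ad_ref, ad_alt, err = 0.01) {
  dp <- ad_ref + ad_alt
  ll <- cbind(ad_alt * log(err) + ad_ref * log1p(-err),   # hom ref
              dp * log(0.5),                              # het
              ad_ref * log(err) + ad_alt * log1p(-err))   # hom alt
  call <- max.col(ll, ties.method = "first") - 1L
  best <- ll[cbind(seq_len(nrow(ll)), call + 1L)]
  ll[cbind(seq_len(nrow(ll)), call + 1L)] <- -Inf
  second <- apply(ll, 1, max)
  gq <- pmin(99L, as.integer(round(10 / log(10) * (best - second))))
  gq[dp == 0L] <- 0L
  call[dp == 0L] <- NA_integer_
  list(gt = call, gq = gq)
}

#' Simulate a population genotype dataset with known truth
#'
#' Generates SNP genotypes for `n_pops` island populations of `n_per_pop`
#' diploids each under the Balding-Nichols model at differentiation `fst`,
#' pushes them through a sequencing-noise model (negative-binomial depth,
#' binomial allele depths with per-read error, ML genotype calls with GQ),
#' and optionally adds: paralog-collapsed loci (reads of a second latent
#' locus summed in, the signature HDplot detects), random missingness,
#' invariant sites (DP only), and technical replicate samples re-emitted
#' with genotype-error flips. Deterministic given `seed`.
#'
#' @param n_pops,n_per_pop populations and diploids per population.
#' @param n_loci number of SNP loci.
#' @param fst target differentiation F in `[0, 1)`.
#' @param maf_range ancestral minor-allele frequency range (uniform draw).
#' @param depth_mean,depth_disp negative-binomial depth model (mean,
#'   dispersion size; defaults 40, 5).
#' @param err per-read base error used for allele depths and calling.
#' @param missingness extra fraction of genotype calls masked at random.
#' @param paralog_fraction fraction of loci collapsed with a latent
#'   duplicate locus (duplicate allele frequency uniform on 0.2-0.8).
#' @param n_invariant number of invariant (monomorphic reference) sites.
#' @param n_replicates number of samples re-emitted as technical replicates
#'   (named `<sample>_rep`).
#' @param genotype_error per-locus probability that a replicate call is
#'   flipped to a different genotype.
#' @param seed RNG seed.
#' @return list of class `pop_sim`: `vt` (a [variant_table()] holding SNP
#'   then invariant sites; replicate columns last), `labels` (data.frame
#'   sample, population), `replicate_map` (data.frame sample, replicate),
#'   `truth` (data.frame per SNP locus: ancestral frequency, paralog flag)
#'   and `pop_freqs` (loci x populations matrix).
#' @export
simulate_population_vcf <- function(n_pops = 10L, n_per_pop = 25L,
                                    n_loci = 2000L, fst = 0.1,
                                    maf_range = c(0.05, 0.5),
                                    depth_mean = 40, depth_disp = 5,
                                    err = 0.01, missingness = 0,
                                    paralog_fraction = 0,
                                    n_invariant = 0L, n_replicates = 0L,
                                    genotype_error = 0.01, seed = 1L) {
  stopifnot(n_loci >= 1, fst >= 0, fst < 1, missingness >= 0,
            missingness <= 1, paralog_fraction >= 0, paralog_fraction <= 1)
  N <- n_pops * n_per_pop
  with_seed(seed, {
    p_anc <- runif(n_loci, maf_range[1], maf_range[2])
    pop_freqs <- if (fst == 0) {
      matrix(p_anc, n_loci, n_pops)
    } else {
      matrix(rbeta(n_loci * n_pops,
                   rep(p_anc, n_pops) * (1 - fst) / fst,
                   rep(1 - p_anc, n_pops) * (1 - fst) / fst),
             n_loci, n_pops)
    }
    pop_of <- rep(seq_len(n_pops), each = n_per_pop)
    true_gt <- matrix(rbinom(n_loci * N, 2L,
                             pop_freqs[, pop_of]), n_loci, N)
    ## paralog-collapsed loci: a latent duplicate locus at intermediate
    ## frequency contributes reads to the same site
    n_par <- round(paralog_fraction * n_loci)
    is_par <- rep(FALSE, n_loci)
    gt2 <- NULL
    if (n_par > 0) {
      is_par[resample(seq_len(n_loci), n_par)] <- TRUE
      p2 <- runif(n_par, 0.2, 0.8)
      gt2 <- matrix(rbinom(n_par * N, 2L, rep(p2, N)), n_par, N)
    }
    ## depth and allele depths
    dp <- matrix(rnbinom(n_loci * N, mu = depth_mean, size = depth_disp),
                 n_loci, N)
    alt_rate <- function(g) c(err, 0.5, 1 - err)[g + 1L]
    ad_alt <- matrix(rbinom(n_loci * N, dp, alt_rate(true_gt)), n_loci, N)
    if (n_par > 0) {
      dp1 <- matrix(rbinom(n_par * N, dp[is_par, ], 0.5), n_par, N)
      dp2 <- dp[is_par, , drop = FALSE] - dp1
      ad_alt[is_par, ] <- rbinom(n_par * N, dp1, alt_rate(true_gt[is_par, ])) +
        rbinom(n_par * N, dp2, alt_rate(gt2))
    }
    ad_ref <- dp - ad_alt
    cl <- call_genotypes(as.vector(ad_ref), as.vector(ad_alt), err)
    gt <- matrix(cl$gt, n_loci, N)
    gq <- matrix(cl$gq, n_loci, N)
    if (missingness > 0) {
      drop <- matrix(runif(n_loci * N) < missingness, n_loci, N)
      gt[drop] <- NA_integer_
    }
    samples <- sprintf("pop%02d_ind%03d", pop_of, seq_len(N))
    ## technical replicates: re-emit called genotypes with error flips
    rep_map <- data.frame(sample = character(0), replicate = character(0))
    if (n_replicates > 0) {
      stopifnot(n_replicates <= N)
      ridx <- seq_len(n_replicates)
      rgt <- gt[, ridx, drop = FALSE]
      flip <- matrix(runif(n_loci * n_replicates) < genotype_error,
                     n_loci, n_replicates) & !is.na(rgt)
      shift <- matrix(resample(1:2, n_loci * n_replicates, replace = TRUE),
                      n_loci, n_replicates)
      rgt[flip] <- (rgt[flip] + shift[flip]) %% 3L
      rep_names <- paste0(samples[ridx], "_rep")
      gt <- cbind(gt, rgt)
      dp <- cbind(dp, dp[, ridx, drop = FALSE])
      gq <- cbind(gq, gq[, ridx, drop = FALSE])
      ad_ref <- cbind(ad_ref, ad_ref[, ridx, drop = FALSE])
      ad_alt <- cbind(ad_alt, ad_alt[, ridx, drop = FALSE])
      samples <- c(samples, rep_names)
      rep_map <- data.frame(sample = samples[ridx], replicate = rep_names,
                            stringsAsFactors = FALSE)
    }
    n_tot <- length(samples)
    ## invariant sites: reference-monomorphic, DP only
    if (n_invariant > 0) {
      inv_dp <- matrix(rnbinom(n_invariant * n_tot, mu = depth_mean,
                               size = depth_disp), n_invariant, n_tot)
      inv_gt <- matrix(0L, n_invariant, n_tot)
      inv_gt[inv_dp == 0L] <- NA_integer_
      gt <- rbind(gt, inv_gt)
      dp <- rbind(dp, inv_dp)
      gq <- rbind(gq, matrix(NA_integer_, n_invariant, n_tot))
      ad_ref <- rbind(ad_ref, matrix(NA_integer_, n_invariant, n_tot))
      ad_alt <- rbind(ad_alt, matrix(NA_integer_, n_invariant, n_tot))
    }
    n_sites <- n_loci + n_invariant
    pos <- sort(resample(seq_len(n_sites * 50L), n_sites))
    refs <- resample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    alt_of <- c(A = "G", C = "T", G = "A", T = "C")
    sites <- data.frame(
      chrom = "chr1", pos = pos, ref = refs,
      alt = c(unname(alt_of[refs[seq_len(n_loci)]]),
              rep(".", n_invariant)),
      qd = c(round(runif(n_loci, 15, 35), 2), rep(NA_real_, n_invariant)),
      mq = c(rep(60, n_loci), rep(NA_real_, n_invariant)),
      mqranksum = c(round(rnorm(n_loci, 0, 1), 3),
                    rep(NA_real_, n_invariant)),
      class = c(rep("snp", n_loci), rep("invariant", n_invariant)),
      stringsAsFactors = FALSE)
    vt <- variant_table(sites, gt, dp, gq, ad_ref, ad_alt, samples = samples)
    structure(list(
      vt = vt,
      labels = data.frame(sample = samples,
                          population = c(sprintf("pop%02d", pop_of),
                                         sprintf("pop%02d",
                                                 pop_of[seq_len(nrow(rep_map))]))[
                                                   seq_len(n_tot)],
                          stringsAsFactors = FALSE),
      replicate_map = rep_map,
      truth = data.frame(locus = seq_len(n_loci), pos = pos[seq_len(n_loci)],
                         p_anc = p_anc, is_paralog = is_par),
      pop_freqs = pop_freqs), class = "pop_sim")
  })
}
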