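# Diversity and differentiation statistics on biallelic dosage matrices
# (loci x samples; 0/1/2, NA missing):
#   - per-locus MAF / observed heterozygosity
#   - Nei & Chesser unbiased expected heterozygosity (Hs), averaged over
#     populations then loci
#   - Weir & Cockerham (1984) theta from per-locus variance components
#     a (among populations), b (among individuals within populations),
#     c (within individuals), combined as ratio of sums over loci, with a
#     seeded percentile bootstrap over loci
#   - missing-data-aware nucleotide diversity: summed pairwise differences
#     over summed comparable pairs, invariant sites included
#   - the ascertainment-bias contrast between probe classes

check_pops <- function(gt, pops) {
  stopifnot(ncol(gt) == length(pops))
  factor(pops)
}

#' Per-locus minor allele frequency and observed heterozygosity
#'
#' @param gt dosage matrix loci x samples (0/1/2, NA missing).
#' @param class optional per-locus probe class (e.g. `"random"` /
#'   `"known"`), attached to the output.
#' @return data.frame `maf`, `ho`, `n_called`, `class`. Loci with zero
#'   calls have NA statistics.
#' @export
locus_stats <- function(gt, class = NULL) {
  n_called <- rowSums(!is.na(gt))
  p_alt <- rowSums(gt, na.rm = TRUE) / (2 * n_called)
  ho <- rowSums(gt == 1L, na.rm = TRUE) / n_called
  data.frame(maf = ifelse(n_called > 0, pmin(p_alt, 1 - p_alt), NA_real_),
             ho = ifelse(n_called > 0, ho, NA_real_),
             n_called = n_called,
             class = if (is.null(class)) NA_character_ else class,
             stringsAsFactors = FALSE)
}

#' Expected heterozygosity (Nei & Chesser unbiased Hs)
#'
#' Per locus and population, with n-tilde called diploids, alternate
#' frequency p and observed heterozygote fraction Ho:
#' `Hs = n/(n-1) * (1 - p^2 - q^2 - Ho/(2n))`. The species-level value is
#' the mean over populations per locus, then the mean over loci
#' (populations with fewer than 2 called diploids at a locus are skipped;
#' loci with no valid population are skipped).
#'
#' @param gt dosage matrix loci x samples.
#' @param pops population label per sample.
#' @return list `hs` (species-level scalar), `per_locus` (numeric vector),
#'   `per_pop` (mean over loci per population).
#' @export
expected_heterozygosity <- function(gt, pops) {
  pops <- check_pops(gt, pops)
  lv <- levels(pops)
  hs_mat <- matrix(NA_real_, nrow(gt), length(lv),
                   dimnames = list(NULL, lv))
  for (k in seq_along(lv)) {
    sub <- gt[, pops == lv[k], drop = FALSE]
    n <- rowSums(!is.na(sub))
    p <- rowSums(sub, na.rm = TRUE) / (2 * n)
    ho <- rowSums(sub == 1L, na.rm = TRUE) / n
    hs <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
    hs[n < 2] <- NA_real_
    hs_mat[, k] <- hs
  }
  per_locus <- rowMeans(hs_mat, na.rm = TRUE)
  per_locus[rowSums(!is.na(hs_mat)) == 0] <- NA_real_
  list(hs = mean(per_locus, na.rm = TRUE),
       per_locus = per_locus,
       per_pop = colMeans(hs_mat, na.rm = TRUE))
}

## Weir & Cockerham (1984) per-locus variance components for a biallelic
## locus; returns c(a, b, c) or NAs when undefined
wc_components <- function(gt_row, pops) {
  called <- !is.na(gt_row)
  tab <- tapply(called, pops, sum)
  n_i <- as.numeric(tab[!is.na(tab) & tab > 0])
  keep_lv <- names(tab)[!is.na(tab) & tab > 0]
  r <- length(n_i)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  p_i <- vapply(keep_lv, function(l)
    mean(gt_row[pops == l], na.rm = TRUE) / 2, numeric(1))
  h_i <- vapply(keep_lv, function(l)
    mean(gt_row[pops == l] == 1L, na.rm = TRUE), numeric(1))
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir & Cockerham's FST (theta)
#'
#' Per-locus variance components combined as a ratio of sums over loci:
#' `theta = sum(a) / sum(a + b + c)`. Loci where the components are
#' undefined (fewer than two populations with data, or a zero denominator)
#' are skipped from both sums.
#'
#' @param gt dosage matrix loci x samples.
#' @param pops population label per sample (at least two populations).
#' @return list of class `wc_fst`: `theta`, `a`, `abc` (per-locus
#'   vectors), `per_locus` theta, `n_loci_used`.
#' @export
wc_fst <- function(gt, pops) {
  pops <- check_pops(gt, pops)
  if (nlevels(droplevels(pops)) < 2)
    stop("theta needs at least two populations; use ",
         "expected_heterozygosity() for a single population")
  comp <- t(vapply(seq_len(nrow(gt)), function(i)
    wc_components(gt[i, ], pops), numeric(3)))
  a <- comp[, 1]; abc <- rowSums(comp)
  ok <- !is.na(abc) & abc != 0         # monomorphic loci carry no signal
  if (!any(ok)) stop("no informative loci for theta")
  structure(list(theta = sum(a[ok]) / sum(abc[ok]),
                 a = a, abc = abc,
                 per_locus = ifelse(abc != 0, a / abc, NA_real_),
                 n_loci_used = sum(ok)), class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.4f (%d loci)\n", x$theta,
              x$n_loci_used))
  invisible(x)
}

#' Bootstrap confidence interval for theta
#'
#' Resamples loci with replacement `n_boot` times, recomputes the
#' ratio-of-sums theta from the stored per-locus components, and returns
#' the percentile interval. Seeded and deterministic.
#'
#' @param fst a [wc_fst()] result.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(fst, n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fst, "wc_fst"))
  ok <- which(!is.na(fst$abc) & fst$abc != 0)
  a <- fst$a[ok]; abc <- fst$abc[ok]
  L <- length(ok)
  with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      sum(a[idx]) / sum(abc[idx])
    }, numeric(1))
    ci <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, names = FALSE)
    c(lower = ci[1], upper = ci[2])
  })
}

#' Nucleotide diversity with invariant sites (pixy-style)
#'
#' Missing-data-aware pi: per site, with `n` called allele copies of which
#' `n_alt` carry the alternate, the number of differing pairs is
#' `D = n_ref * n_alt` and the number of comparable pairs `C = n(n-1)/2`;
#' `pi = sum(D) / sum(C)` over sites. Invariant sites contribute `C` with
#' `D = 0`, which is what makes the estimate robust to missingness and to
#' filtering. Sites with fewer than 2 called copies are excluded from both
#' sums. Window values aggregate by summing numerators and denominators;
#' their aggregate reproduces the global value exactly (never a mean of
#' ratios).
#'
#' @param vt a `variant_table` containing variant AND invariant sites, or
#'   a dosage matrix (then all sites are treated as SNPs on one sequence).
#' @param window_size optional window length in bp for windowed output.
#' @param pops optional population labels for per-population pi.
#' @return list `pi` (global), `num`, `denom`, `windows` (data.frame with
#'   chrom, start, end, num, denom, pi; NA pi where no comparable pairs),
#'   `per_pop` when `pops` given.
#' @export
pi_pixy <- function(vt, window_size = NULL, pops = NULL) {
  if (is.matrix(vt)) {
    vt <- variant_table(data.frame(chrom = "chr1", pos = seq_len(nrow(vt)),
                                   ref = "A", alt = "G",
                                   stringsAsFactors = FALSE), vt)
  }
  site_terms <- function(gt) {
    n <- 2 * rowSums(!is.na(gt))
    n_alt <- rowSums(gt, na.rm = TRUE)
    list(num = (n - n_alt) * n_alt, denom = n * (n - 1) / 2, n = n)
  }
  global <- function(gt) {
    t <- site_terms(gt)
    use <- t$n >= 2
    list(num = sum(t$num[use]), denom = sum(t$denom[use]),
         pi = sum(t$num[use]) / sum(t$denom[use]), terms = t, use = use)
  }
  g <- global(vt$gt)
  windows <- NULL
  if (!is.null(window_size)) {
    win <- floor((vt$sites$pos - 1) / window_size)
    key <- paste(vt$sites$chrom, win)
    agg <- function(x) tapply(x, key, sum)
    num_w <- agg(ifelse(g$use, g$terms$num, 0))
    den_w <- agg(ifelse(g$use, g$terms$denom, 0))
    ord <- order(names(num_w))
    chrom_w <- tapply(vt$sites$chrom, key, `[`, 1)
    win_w <- tapply(win, key, `[`, 1)
    windows <- data.frame(chrom = as.character(chrom_w[ord]),
                          start = as.integer(win_w[ord]) * window_size,
                          end = (as.integer(win_w[ord]) + 1L) * window_size,
                          num = as.numeric(num_w[ord]),
                          denom = as.numeric(den_w[ord]))
    windows$pi <- ifelse(windows$denom > 0, windows$num / windows$denom,
                         NA_real_)
    rownames(windows) <- NULL
  }
  per_pop <- NULL
  if (!is.null(pops)) {
    pops <- check_pops(vt$gt, pops)
    per_pop <- vapply(levels(pops), function(l)
      global(vt$gt[, pops == l, drop = FALSE])$pi, numeric(1))
  }
  list(pi = g$pi, num = g$num, denom = g$denom, windows = windows,
       per_pop = per_pop)
}

#' Ascertainment-bias comparison between probe classes
#'
#' Contrasts MAF and observed heterozygosity between SNP classes (e.g.
#' known/array targets vs randomly discovered sites) with one-sided
#' Wilcoxon rank-sum tests (alternative: the known class is larger), and
#' reports per-class theta plus the relative FST underestimation
#' `(theta_random - theta_known) / theta_random` expected when markers
#' were pre-ascertained at intermediate frequencies.
#'
#' @param gt dosage matrix loci x samples.
#' @param class per-locus class, `"random"` or `"known"`.
#' @param pops population labels (needed for the per-class theta).
#' @return list `stats` (per-class medians), `p_maf`, `p_ho` (one-sided),
#'   `theta_by_class`, `fst_underestimation`.
#' @export
ascertainment_comparison <- function(gt, class, pops) {
  stopifnot(length(class) == nrow(gt))
  ls <- locus_stats(gt, class)
  cls <- unique(class)
  small <- vapply(cls, function(cl) sum(class == cl) < 2, logical(1))
  if (any(small)) {
    warning("class(es) with < 2 loci excluded: ",
            paste(cls[small], collapse = ", "))
    keepc <- !(class %in% cls[small])
    gt <- gt[keepc, , drop = FALSE]
    class <- class[keepc]
    ls <- ls[keepc, , drop = FALSE]
  }
  stopifnot(all(c("random", "known") %in% class))
  kn <- class == "known"; rd <- class == "random"
  p_maf <- wilcox.test(ls$maf[kn], ls$maf[rd],
                       alternative = "greater", exact = FALSE)$p.value
  p_ho <- wilcox.test(ls$ho[kn], ls$ho[rd],
                      alternative = "greater", exact = FALSE)$p.value
  th_r <- wc_fst(gt[rd, , drop = FALSE], pops)$theta
  th_k <- wc_fst(gt[kn, , drop = FALSE], pops)$theta
  list(stats = data.frame(class = c("random", "known"),
                          median_maf = c(median(ls$maf[rd], na.rm = TRUE),
                                         median(ls$maf[kn], na.rm = TRUE)),
                          median_ho = c(median(ls$ho[rd], na.rm = TRUE),
                                        median(ls$ho[kn], na.rm = TRUE))),
       p_maf = p_maf, p_ho = p_ho,
       theta_by_class = c(random = th_r, known = th_k),
       fst_underestimation = (th_r - th_k) / th_r)
}
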