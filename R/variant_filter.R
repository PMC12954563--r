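# The V0/V1 filtering cascade for joint-genotyped variant+invariant calls:
# SNP/invariant split, GATK-style hard site filters, HDplot paralog
# flagging, genotype-level DP/GQ masking with locus retention rules, sample
# missingness, invariant-site depth rules, merge into V0 and curated
# removals into V1. Sites are flagged (not deleted) until the merge so the
# audit trail is complete.

#' Filtering thresholds
#'
#' Defaults follow standard practice for lenient population-level
#' filtering: hard site filter fails on `QD < 2 || MQ < 40 ||
#' MQRankSum < -12.5` (missing annotations pass); HDplot flags
#' `H > 0.6`, allele ratio outside `[0.2, 0.8]`, or `|D| > 10`; genotypes
#' need `DP >= 6` and `GQ >= 20`; a locus needs depth strictly above 6 in
#' at least half the samples and at least 3 reads supporting its minor
#' allele; samples with more than 80 percent missing data are removed.
#'
#' @param ... override any default by name.
#' @return a named list of thresholds.
#' @export
filter_config <- function(...) {
  cfg <- list(qd_min = 2.0, mq_min = 40.0, mqranksum_min = -12.5,
              dp_min = 6L, gq_min = 20L, half_sample_dp = 6L,
              minor_reads_min = 3L, sample_missing_max = 0.80,
              hmax = 0.6, raf_min = 0.2, raf_max = 0.8,
              d_min = -10, d_max = 10)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Split sites into SNPs, invariants and discarded classes
#'
#' SNP: at least one single-base alternate allele. Invariant: no observed
#' alternate (`.`/empty, or symbolic `<NON_REF>` only). Everything else
#' (indels, MNPs, mixed) is discarded with counts.
#'
#' @param vt a [variant_table()].
#' @return list `snps`, `invariants`, `discarded` (variant tables) and
#'   `counts`.
#' @export
split_sites <- function(vt) {
  cls <- site_class(vt$sites$ref, vt$sites$alt)
  list(snps = vt_subset(vt, cls == "snp"),
       invariants = vt_subset(vt, cls == "invariant"),
       discarded = vt_subset(vt, cls == "other"),
       counts = c(snp = sum(cls == "snp"),
                  invariant = sum(cls == "invariant"),
                  discarded = sum(cls == "other")))
}

#' Hard site filter on QD / MQ / MQRankSum
#'
#' A site fails when any of `QD < qd_min`, `MQ < mq_min`,
#' `MQRankSum < mqranksum_min` holds (strict inequalities). Missing
#' annotations never fail a site (the annotation is uninformative, not
#' evidence against it); such sites are marked in `annotation_missing`.
#' Sites are flagged, not removed.
#'
#' @param vt SNP variant table.
#' @param cfg a [filter_config()].
#' @return `vt` with logical site columns `hard_fail` and
#'   `annotation_missing` added.
#' @export
hard_site_filter <- function(vt, cfg = filter_config()) {
  s <- vt$sites
  lt <- function(x, thr) !is.na(x) & x < thr
  fail <- lt(s$qd, cfg$qd_min) | lt(s$mq, cfg$mq_min) |
    lt(s$mqranksum, cfg$mqranksum_min)
  vt$sites$hard_fail <- fail
  vt$sites$annotation_missing <- is.na(s$qd) & is.na(s$mq) & is.na(s$mqranksum)
  vt
}

#' HDplot statistics per site
#'
#' For each site: `H`, the proportion of genotyped samples that are
#' heterozygous; `A` and `B`, the read counts of the two alleles summed
#' over heterozygotes; `ratio = A / (A + B)`; and the standardized
#' read-ratio deviation `D = (A - B) / sqrt(A + B)`. `ratio` and `D` are
#' `NA` when there are no heterozygote reads. Paralog-collapsed loci show
#' elevated H and/or allele ratios far from 0.5.
#'
#' @param vt variant table with AD matrices.
#' @return data.frame `H`, `A`, `B`, `ratio`, `D`, `n_het`, `n_called`.
#' @export
hdplot <- function(vt) {
  het <- !is.na(vt$gt) & vt$gt == 1L
  n_called <- rowSums(!is.na(vt$gt))
  n_het <- rowSums(het)
  A <- rowSums(ifelse(het, vt$ad_ref, 0L), na.rm = TRUE)
  B <- rowSums(ifelse(het, vt$ad_alt, 0L), na.rm = TRUE)
  tot <- A + B
  data.frame(H = ifelse(n_called > 0, n_het / n_called, NA_real_),
             A = A, B = B,
             ratio = ifelse(tot > 0, A / tot, NA_real_),
             D = ifelse(tot > 0, (A - B) / sqrt(tot), NA_real_),
             n_het = n_het, n_called = n_called)
}

#' HDplot paralog filter
#'
#' Flags a site when `H > hmax`, or its heterozygote allele ratio falls
#' outside `[raf_min, raf_max]`, or `D` falls outside `[d_min, d_max]`
#' (a site must pass every sub-rule to be kept). When no heterozygote
#' reads exist only the H rule applies.
#'
#' @param vt SNP variant table.
#' @param cfg a [filter_config()].
#' @return `vt` with logical site column `hd_fail` and the HDplot columns.
#' @export
hdplot_filter <- function(vt, cfg = filter_config()) {
  hd <- hdplot(vt)
  fail_h <- !is.na(hd$H) & hd$H > cfg$hmax
  fail_ratio <- !is.na(hd$ratio) &
    (hd$ratio < cfg$raf_min | hd$ratio > cfg$raf_max)
  fail_d <- !is.na(hd$D) & (hd$D < cfg$d_min | hd$D > cfg$d_max)
  vt$sites$hd_H <- hd$H
  vt$sites$hd_ratio <- hd$ratio
  vt$sites$hd_D <- hd$D
  vt$sites$hd_fail <- fail_h | fail_ratio | fail_d
  vt
}

#' Genotype-level filter
#'
#' Drops non-biallelic sites; masks genotypes with `DP < dp_min` or
#' `GQ < gq_min`; then keeps a locus only when depth is strictly above
#' `half_sample_dp` in at least half the samples AND the locus minor
#' allele is supported by at least `minor_reads_min` reads summed over all
#' samples. Returns the retained table and per-rule counts.
#'
#' @param vt SNP variant table.
#' @param cfg a [filter_config()].
#' @return list `vt` (retained sites, masked genotypes), `counts`.
#' @export
genotype_filter <- function(vt, cfg = filter_config()) {
  n0 <- nrow(vt$sites)
  alts <- strsplit(gsub(",?<NON_REF>", "", vt$sites$alt), ",", fixed = TRUE)
  biallelic <- lengths(alts) == 1L & vt$sites$alt != "."
  n_samp <- length(vt$samples)
  mask <- (!is.na(vt$dp) & vt$dp < cfg$dp_min) |
    (!is.na(vt$gq) & vt$gq < cfg$gq_min) |
    is.na(vt$dp) | is.na(vt$gq)
  gt <- vt$gt
  gt[mask] <- NA_integer_
  n_masked <- sum(mask & !is.na(vt$gt))
  half_ok <- rowSums(!is.na(vt$dp) & vt$dp > cfg$half_sample_dp) >=
    n_samp / 2
  ## minor allele = less frequent allele over called genotypes; its total
  ## read support summed over all samples with AD
  alt_dose <- rowSums(gt, na.rm = TRUE)
  called2 <- 2L * rowSums(!is.na(gt))
  minor_is_alt <- alt_dose <= called2 - alt_dose
  reads_alt <- rowSums(vt$ad_alt, na.rm = TRUE)
  reads_ref <- rowSums(vt$ad_ref, na.rm = TRUE)
  minor_reads <- ifelse(minor_is_alt, reads_alt, reads_ref)
  minor_ok <- minor_reads >= cfg$minor_reads_min
  keep <- biallelic & half_ok & minor_ok
  vt$gt <- gt
  out <- vt_subset(vt, keep)
  list(vt = out,
       counts = c(input = n0, non_biallelic = sum(!biallelic),
                  genotypes_masked = n_masked,
                  fail_half_depth = sum(biallelic & !half_ok),
                  fail_minor_reads = sum(biallelic & half_ok & !minor_ok),
                  retained = sum(keep)))
}

#' Remove samples with excessive missing data
#'
#' A sample is removed when its fraction of missing genotypes is strictly
#' greater than `max_missing` (a sample at exactly the bound is kept).
#'
#' @param vt variant table after genotype filtering.
#' @param max_missing threshold (default 0.80).
#' @return list `vt` (retained samples), `removed` (data.frame sample,
#'   missing_frac).
#' @export
sample_missingness_filter <- function(vt, max_missing = 0.80) {
  miss <- colMeans(is.na(vt$gt))
  drop <- miss > max_missing
  if (all(drop)) stop("all samples exceed the missingness threshold")
  list(vt = vt_subset(vt, j = !drop),
       removed = data.frame(sample = vt$samples[drop],
                            missing_frac = unname(miss[drop]),
                            stringsAsFactors = FALSE))
}

#' Filter invariant sites by depth
#'
#' Masks genotypes with `DP < dp_min`; keeps a site only when depth is
#' strictly above `half_sample_dp` in at least half the samples.
#'
#' @param vt invariant-site variant table.
#' @param cfg a [filter_config()].
#' @return list `vt`, `counts`.
#' @export
invariant_filter <- function(vt, cfg = filter_config()) {
  n0 <- nrow(vt$sites)
  mask <- is.na(vt$dp) | vt$dp < cfg$dp_min
  vt$gt[mask] <- NA_integer_
  keep <- rowSums(!is.na(vt$dp) & vt$dp > cfg$half_sample_dp) >=
    length(vt$samples) / 2
  list(vt = vt_subset(vt, keep),
       counts = c(input = n0, retained = sum(keep)))
}

#' Merge filtered SNPs and invariant sites into a V0 table
#'
#' Excludes SNP sites flagged by the hard or HDplot filters, concatenates
#' with the filtered invariant sites and sorts by coordinate. Threshold
#' provenance is recorded in the `provenance` attribute and written as
#' `##spetkit_filter` header lines by [write_vcf()] when supplied.
#'
#' @param snps filtered SNP table (with `hard_fail` / `hd_fail` columns if
#'   those filters ran).
#' @param invariants filtered invariant table.
#' @param cfg the [filter_config()] used (recorded as provenance).
#' @return a coordinate-sorted `variant_table` (V0).
#' @export
merge_v0 <- function(snps, invariants, cfg = filter_config()) {
  if (!identical(snps$samples, invariants$samples))
    stop("sample sets differ between SNP and invariant tables")
  flagged <- rep(FALSE, nrow(snps$sites))
  for (f in c("hard_fail", "hd_fail"))
    if (!is.null(snps$sites[[f]])) flagged <- flagged | snps$sites[[f]]
  snps <- vt_subset(snps, !flagged)
  common <- intersect(names(snps$sites), names(invariants$sites))
  snps$sites <- snps$sites[, common, drop = FALSE]
  invariants$sites <- invariants$sites[, common, drop = FALSE]
  comb <- function(f) {
    a <- snps[[f]]; b <- invariants[[f]]
    if (is.null(a) || is.null(b)) NULL else rbind(a, b)
  }
  vt <- variant_table(rbind(snps$sites, invariants$sites), comb("gt"),
                      comb("dp"), comb("gq"), comb("ad_ref"),
                      comb("ad_alt"), samples = snps$samples)
  ord <- order(vt$sites$chrom, vt$sites$pos)
  vt <- vt_subset(vt, ord)
  attr(vt, "provenance") <- sprintf("##spetkit_filter=%s=%s",
                                    names(cfg), unlist(cfg))
  vt
}

#' Remove curated samples to produce V1
#'
#' Drops the listed samples (outliers or non-clonal duplicates identified
#' downstream), then removes sites left with no called genotype.
#'
#' @param v0 the merged V0 table.
#' @param removal_list character vector of sample ids.
#' @return a `variant_table` (V1) with a `removed_samples` attribute.
#' @export
build_v1 <- function(v0, removal_list) {
  if (length(removal_list) == 0) return(v0)
  unknown <- setdiff(removal_list, v0$samples)
  if (length(unknown) > 0)
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  keep <- !(v0$samples %in% removal_list)
  vt <- vt_subset(v0, j = keep)
  vt <- vt_subset(vt, rowSums(!is.na(vt$gt)) > 0)
  attr(vt, "provenance") <- attr(v0, "provenance")
  attr(vt, "removed_samples") <- removal_list
  vt
}

#' Run the full V0 filter cascade
#'
#' Split, hard-filter, HDplot-filter, genotype-filter, sample-missingness
#' filter, invariant filter, merge. Returns the V0 table and a per-stage
#' count report.
#'
#' @param vt joint variant table (SNPs + invariants).
#' @param cfg a [filter_config()].
#' @return list `v0`, `report` (data.frame stage, count), `removed_samples`.
#' @export
filter_cascade <- function(vt, cfg = filter_config()) {
  sp <- split_sites(vt)
  snps <- hard_site_filter(sp$snps, cfg)
  snps <- hdplot_filter(snps, cfg)
  ## site-level flags act before the genotype stage so that downstream
  ## per-sample missingness is computed over surviving sites only
  n_hard <- sum(snps$sites$hard_fail)
  n_hd <- sum(snps$sites$hd_fail & !snps$sites$hard_fail)
  snps_clean <- vt_subset(snps, !(snps$sites$hard_fail | snps$sites$hd_fail))
  gf <- genotype_filter(snps_clean, cfg)
  sm <- sample_missingness_filter(gf$vt, cfg$sample_missing_max)
  inv <- invariant_filter(
    vt_subset(sp$invariants, j = match(sm$vt$samples, sp$invariants$samples)),
    cfg)
  v0 <- merge_v0(sm$vt, inv$vt, cfg)
  report <- data.frame(
    stage = c("input", "snp", "invariant", "discarded_non_snp",
              "hard_fail", "hd_fail", "non_biallelic", "fail_half_depth",
              "fail_minor_reads", "snp_retained", "samples_removed",
              "invariant_retained", "v0_sites"),
    count = c(nrow(vt$sites), sp$counts["snp"], sp$counts["invariant"],
              sp$counts["discarded"], n_hard, n_hd,
              gf$counts["non_biallelic"],
              gf$counts["fail_half_depth"], gf$counts["fail_minor_reads"],
              gf$counts["retained"], nrow(sm$removed),
              inv$counts["retained"], nrow(v0$sites)))
  list(v0 = v0, report = report, removed_samples = sm$removed)
}
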