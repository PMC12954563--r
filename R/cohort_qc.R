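# Cohort-level QC: KING-robust pairwise kinship for duplicate detection, a
# light dosage PCA for outlier screening, and technical-replicate
# concordance with a breakdown of discordance classes.

#' KING-robust pairwise kinship
#'
#' For each sample pair, over co-called biallelic loci:
#' `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j))` where `N_Aa,Aa`
#' counts loci heterozygous in both, `N_AA,aa` loci with opposite
#' homozygotes, and `N_Aa(.)` the per-sample heterozygote counts.
#' Duplicates (and monozygotic pairs) sit at 0.5, parent-offspring at
#' 0.25, unrelated pairs at 0.
#'
#' @param gt dosage matrix loci x samples (0/1/2, NA missing).
#' @param min_loci minimum co-called loci for a pair to be estimated
#'   (default 100); pairs below it are omitted with a warning.
#' @return data.frame: `sample_i`, `sample_j`, `phi`, `n_het_het`,
#'   `n_opp_hom`, `n_het_i`, `n_het_j`, `n_loci_used`.
#' @export
king_kinship <- function(gt, min_loci = 100L) {
  ns <- ncol(gt)
  ids <- colnames(gt) %||% paste0("S", seq_len(ns))
  out <- list(); skipped <- 0L
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      co <- !is.na(gt[, i]) & !is.na(gt[, j])
      n_co <- sum(co)
      if (n_co < min_loci) { skipped <- skipped + 1L; next }
      gi <- gt[co, i]; gj <- gt[co, j]
      n_hh <- sum(gi == 1L & gj == 1L)
      n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
      n_het_i <- sum(gi == 1L); n_het_j <- sum(gj == 1L)
      out[[length(out) + 1L]] <- data.frame(
        sample_i = ids[i], sample_j = ids[j],
        phi = (n_hh - 2 * n_opp) / (n_het_i + n_het_j),
        n_het_het = n_hh, n_opp_hom = n_opp,
        n_het_i = n_het_i, n_het_j = n_het_j, n_loci_used = n_co,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " pair(s) below min_loci omitted")
  if (length(out) == 0)
    return(data.frame(sample_i = character(0), sample_j = character(0),
                      phi = numeric(0), n_het_het = integer(0),
                      n_opp_hom = integer(0), n_het_i = integer(0),
                      n_het_j = integer(0), n_loci_used = integer(0)))
  do.call(rbind, out)
}

#' Flag putative duplicate pairs
#'
#' @param estimates data.frame from [king_kinship()].
#' @param threshold kinship cutoff (default `2^(-3/2)` = 0.354, the
#'   standard monozygotic/duplicate bound).
#' @return the subset of pairs with `phi > threshold`.
#' @export
flag_duplicates <- function(estimates, threshold = 2^(-3 / 2)) {
  estimates[!is.na(estimates$phi) & estimates$phi > threshold, ,
            drop = FALSE]
}

#' Genotype PCA for outlier screening
#'
#' Mean-imputes missing dosages per locus, centres and scales each locus,
#' and eigendecomposes the sample covariance (via `prcomp`). Deterministic
#' up to the sign of each axis.
#'
#' @param gt dosage matrix loci x samples.
#' @param n_components number of axes to return (default 10).
#' @return list `scores` (samples x components), `var_explained`.
#' @export
genotype_pca <- function(gt, n_components = 10L) {
  stopifnot(ncol(gt) >= 3, nrow(gt) >= 10)
  imp <- gt
  mu <- rowMeans(gt, na.rm = TRUE)
  idx <- which(is.na(imp), arr.ind = TRUE)
  if (nrow(idx) > 0) imp[idx] <- mu[idx[, 1]]
  sdv <- apply(imp, 1, sd)
  keep <- sdv > 0
  if (!any(keep)) stop("zero-variance genotype matrix")
  x <- t((imp[keep, , drop = FALSE] - mu[keep]) / sdv[keep])
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Technical-replicate concordance
#'
#' For each replicate pair: the fraction of co-called loci with identical
#' genotype calls, the discordant calls classified into the three
#' unordered classes (hom-ref vs het, het vs hom-alt, hom-ref vs hom-alt),
#' and the mean depth at concordant vs discordant calls. A pooled row sums
#' counts over pairs.
#'
#' @param vt a `variant_table` (needs `gt`; `dp` used for the depth
#'   contrast when present) — or a dosage matrix.
#' @param replicate_map data.frame with columns `sample`, `replicate`.
#' @return data.frame, one row per pair plus a `pooled` row: `n_cocalled`,
#'   `n_concordant`, `concordance`, `homref_het`, `het_homalt`,
#'   `homref_homalt`, `mean_dp_concordant`, `mean_dp_discordant`.
#' @export
replicate_concordance <- function(vt, replicate_map) {
  if (is.matrix(vt)) vt <- list(gt = vt, dp = NULL,
                                samples = colnames(vt))
  gt <- vt$gt
  rows <- list()
  for (k in seq_len(nrow(replicate_map))) {
    s1 <- replicate_map$sample[k]; s2 <- replicate_map$replicate[k]
    if (!(s1 %in% vt$samples) || !(s2 %in% vt$samples))
      stop("replicate pair references unknown sample: ", s1, "/", s2)
    g1 <- gt[, s1]; g2 <- gt[, s2]
    co <- !is.na(g1) & !is.na(g2)
    if (!any(co)) {
      warning("pair ", s1, "/", s2, " has no co-called loci; omitted")
      next
    }
    conc <- co & g1 == g2
    disc <- co & g1 != g2
    lohi <- function(a, b) pmin(g1, g2) == a & pmax(g1, g2) == b & disc
    dp_mean <- function(sel) {
      if (is.null(vt$dp) || !any(sel)) return(NA_real_)
      mean(c(vt$dp[sel, s1], vt$dp[sel, s2]), na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(s1, s2, sep = "/"),
      n_cocalled = sum(co), n_concordant = sum(conc),
      concordance = sum(conc) / sum(co),
      homref_het = sum(lohi(0L, 1L), na.rm = TRUE),
      het_homalt = sum(lohi(1L, 2L), na.rm = TRUE),
      homref_homalt = sum(lohi(0L, 2L), na.rm = TRUE),
      mean_dp_concordant = dp_mean(conc),
      mean_dp_discordant = dp_mean(disc),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(pair = character(0), n_cocalled = integer(0),
                      n_concordant = integer(0), concordance = numeric(0),
                      homref_het = integer(0), het_homalt = integer(0),
                      homref_homalt = integer(0),
                      mean_dp_concordant = numeric(0),
                      mean_dp_discordant = numeric(0)))
  out <- do.call(rbind, rows)
  pooled <- data.frame(
    pair = "pooled", n_cocalled = sum(out$n_cocalled),
    n_concordant = sum(out$n_concordant),
    concordance = sum(out$n_concordant) / sum(out$n_cocalled),
    homref_het = sum(out$homref_het), het_homalt = sum(out$het_homalt),
    homref_homalt = sum(out$homref_homalt),
    mean_dp_concordant = NA_real_, mean_dp_discordant = NA_real_,
    stringsAsFactors = FALSE)
  rbind(out, pooled)
}
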