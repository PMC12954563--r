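# Species-diagnostic marker discovery: merge per-species cohorts, compute
# filtered per-species allele frequencies, and retain sites whose largest
# pairwise frequency difference reaches a threshold (default 0.9,
# inclusive).

#' Merge per-species variant tables
#'
#' Takes a named list of `variant_table`s (one per species, shared
#' reference coordinates) and builds the union of sites with all samples
#' side by side. Genotypes of a cohort lacking a site are missing. Sites
#' with conflicting REF alleles across cohorts are dropped with a warning.
#'
#' @param vts named list of `variant_table`s; names are the species ids.
#' @return list `vt` (merged table), `species` (per-sample species label),
#'   `n_conflicts`.
#' @export
merge_species_cohorts <- function(vts) {
  stopifnot(length(vts) >= 2, !is.null(names(vts)))
  key_of <- function(v) paste(v$sites$chrom, v$sites$pos, sep = ":")
  keys <- lapply(vts, key_of)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  ## detect REF conflicts
  ref_by_key <- list()
  conflict <- character(0)
  for (v in vts) {
    k <- key_of(v)
    for (i in seq_along(k)) {
      prev <- ref_by_key[[k[i]]]
      if (is.null(prev)) ref_by_key[[k[i]]] <- v$sites$ref[i]
      else if (prev != v$sites$ref[i]) conflict <- c(conflict, k[i])
    }
  }
  conflict <- unique(conflict)
  if (length(conflict) > 0)
    warning(length(conflict), " site(s) with conflicting REF dropped")
  use_keys <- setdiff(all_keys, conflict)
  ## order by chrom, pos
  if (length(use_keys) > 0) {
    kp <- do.call(rbind, strsplit(use_keys, ":", fixed = TRUE))
    use_keys <- use_keys[order(kp[, 1], as.integer(kp[, 2]))]
  }
  n <- length(use_keys)
  samples <- unlist(lapply(vts, `[[`, "samples"), use.names = FALSE)
  species <- rep(names(vts), vapply(vts, function(v)
    length(v$samples), integer(1)))
  blank <- function() matrix(NA_integer_, n, length(samples),
                             dimnames = list(NULL, samples))
  gt <- blank(); dp <- blank(); gq <- blank()
  ad_ref <- blank(); ad_alt <- blank()
  first_site <- rep(NA_integer_, n)
  sites_src <- NULL
  col0 <- 0L
  for (si in seq_along(vts)) {
    v <- vts[[si]]
    rows <- match(key_of(v), use_keys)
    ok <- !is.na(rows)
    cols <- col0 + seq_along(v$samples)
    put <- function(dst, src) {
      if (!is.null(src)) dst[rows[ok], cols] <- src[ok, , drop = FALSE]
      dst
    }
    gt <- put(gt, v$gt); dp <- put(dp, v$dp); gq <- put(gq, v$gq)
    ad_ref <- put(ad_ref, v$ad_ref); ad_alt <- put(ad_alt, v$ad_alt)
    new_rows <- rows[ok][is.na(first_site[rows[ok]])]
    first_site[new_rows] <- 1L
    if (is.null(sites_src)) {
      sites_src <- v$sites[ok, c("chrom", "pos", "ref", "alt"),
                           drop = FALSE]
      sites_src$key <- key_of(v)[ok]
    } else {
      newk <- !(key_of(v)[ok] %in% sites_src$key)
      add <- v$sites[ok, c("chrom", "pos", "ref", "alt"), drop = FALSE][newk, ,
                                                                        drop = FALSE]
      add$key <- key_of(v)[ok][newk]
      sites_src <- rbind(sites_src, add)
    }
    col0 <- col0 + length(v$samples)
  }
  sites <- sites_src[match(use_keys, sites_src$key),
                     c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(sites) <- NULL
  list(vt = variant_table(sites, gt, dp, gq, ad_ref, ad_alt,
                          samples = samples),
       species = data.frame(sample = samples, species = species,
                            stringsAsFactors = FALSE),
       n_conflicts = length(conflict))
}

#' Per-species allele frequencies with quality filters
#'
#' Keeps biallelic SNP sites; masks genotypes with `DP < dp_min` or
#' `GQ < gq_min`; drops any site whose call rate falls below
#' `presence_min` in any species. Frequencies are of the alternate allele
#' over the retained calls.
#'
#' @param merged result of [merge_species_cohorts()] (or a list with `vt`
#'   and `species`).
#' @param dp_min,gq_min genotype-quality thresholds (defaults 6, 20).
#' @param presence_min minimum per-species call rate (default 0.8,
#'   inclusive).
#' @return data.frame: `chrom`, `pos`, one `freq_<species>` and
#'   `callrate_<species>` column per species.
#' @export
species_allele_freqs <- function(merged, dp_min = 6L, gq_min = 20L,
                                 presence_min = 0.8) {
  vt <- merged$vt
  spp <- merged$species
  sp_lv <- unique(spp$species)
  if (any(!spp$sample %in% vt$samples))
    stop("species map references unknown samples")
  cls <- site_class(vt$sites$ref, vt$sites$alt)
  alts <- strsplit(gsub(",?<NON_REF>", "", vt$sites$alt), ",", fixed = TRUE)
  biallelic <- cls == "snp" & lengths(alts) == 1L
  gt <- vt$gt
  if (!is.null(vt$dp)) gt[is.na(vt$dp) | vt$dp < dp_min] <- NA_integer_
  if (!is.null(vt$gq)) gt[is.na(vt$gq) | vt$gq < gq_min] <- NA_integer_
  out <- data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                    stringsAsFactors = FALSE)
  keep <- biallelic
  for (sp in sp_lv) {
    cols <- spp$sample[spp$species == sp]
    sub <- gt[, cols, drop = FALSE]
    n_called <- rowSums(!is.na(sub))
    if (all(n_called == 0)) stop("species ", sp, " has no retained calls")
    cr <- n_called / length(cols)
    out[[paste0("freq_", sp)]] <-
      ifelse(n_called > 0, rowSums(sub, na.rm = TRUE) / (2 * n_called),
             NA_real_)
    out[[paste0("callrate_", sp)]] <- cr
    keep <- keep & cr >= presence_min
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species-discriminant sites
#'
#' Retains sites whose maximum pairwise absolute allele-frequency
#' difference between species reaches `delta_min` (inclusive), listing the
#' discriminating pair(s).
#'
#' @param freqs data.frame from [species_allele_freqs()].
#' @param delta_min minimum |frequency difference| (default 0.9).
#' @return subset of `freqs` with `delta` (max pairwise |difference|) and
#'   `pair` (semicolon-separated discriminating species pairs) columns,
#'   sorted by coordinate.
#' @export
discriminant_sites <- function(freqs, delta_min = 0.9) {
  fcols <- grep("^freq_", names(freqs), value = TRUE)
  stopifnot(length(fcols) >= 2)
  spp <- sub("^freq_", "", fcols)
  pairs <- utils::combn(seq_along(fcols), 2)
  dmat <- vapply(seq_len(ncol(pairs)), function(k)
    abs(freqs[[fcols[pairs[1, k]]]] - freqs[[fcols[pairs[2, k]]]]),
    numeric(nrow(freqs)))
  dmat <- matrix(dmat, nrow = nrow(freqs))
  delta <- apply(dmat, 1, max)
  ## inclusive bound, robust to floating-point representation of the
  ## frequency difference
  eps <- 1e-9
  hit <- !is.na(delta) & delta >= delta_min - eps
  pair_str <- vapply(which(hit), function(i) {
    ks <- which(dmat[i, ] >= delta_min - eps)
    paste(vapply(ks, function(k)
      paste(spp[pairs[, k]], collapse = "-"), character(1)),
      collapse = ";")
  }, character(1))
  out <- freqs[hit, , drop = FALSE]
  out$delta <- delta[hit]
  out$pair <- pair_str
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
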