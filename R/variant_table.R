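# variant_table: the package's in-memory container for joint-genotyped
# sites x samples data. Genotypes are stored as biallelic dosage (0, 1, 2,
# NA = missing) with DP/GQ and allele-depth matrices alongside, plus the
# site annotations the filtering cascade consumes (QD, MQ, MQRankSum).
# Multiallelic genotypes are representable at the site level (comma in
# `alt`) and are classified/dropped by the filters, not dosage-coded.

#' Construct a variant table
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt` (`"."` for invariant sites), and optionally
#'   `qd`, `mq`, `mqranksum` (NA when absent) and `class` (one of `"snp"`,
#'   `"invariant"`, `"other"`; derived from ref/alt when missing).
#' @param gt integer matrix sites x samples of alt-allele dosage (0/1/2,
#'   NA missing).
#' @param dp,gq,ad_ref,ad_alt matching integer matrices (may be NULL).
#' @param samples character vector of sample names.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp = NULL, gq = NULL,
                          ad_ref = NULL, ad_alt = NULL,
                          samples = colnames(gt)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(gt) == nrow(sites))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  for (f in c("qd", "mq", "mqranksum"))
    if (is.null(sites[[f]])) sites[[f]] <- rep(NA_real_, nrow(sites))
  if (is.null(sites$class)) sites$class <- site_class(sites$ref, sites$alt)
  dimn <- list(NULL, samples)
  fix <- function(m) {
    if (is.null(m)) return(NULL)
    stopifnot(all(dim(m) == dim(gt)))
    if (!is.integer(m)) storage.mode(m) <- "integer"
    dimnames(m) <- dimn
    m
  }
  if (!is.integer(gt)) storage.mode(gt) <- "integer"
  dimnames(gt) <- dimn
  structure(list(sites = sites, gt = gt, dp = fix(dp), gq = fix(gq),
                 ad_ref = fix(ad_ref), ad_alt = fix(ad_alt),
                 samples = samples),
            class = "variant_table")
}

## classify a site from its REF/ALT strings (VCF semantics)
site_class <- function(ref, alt) {
  alt_clean <- gsub("<NON_REF>", "", alt, fixed = TRUE)
  alt_clean <- gsub("^,|,$", "", alt_clean)
  invariant <- alt_clean %in% c("", ".")
  alts <- strsplit(alt_clean, ",", fixed = TRUE)
  snp <- mapply(function(r, a) length(a) > 0 &&
                  any(nchar(a) == 1 & a %in% c("A", "C", "G", "T")) &&
                  nchar(r) == 1,
                ref, alts)
  ifelse(invariant, "invariant", ifelse(snp, "snp", "other"))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(sprintf("%s=%d", names(table(x$sites$class)),
                            table(x$sites$class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a variant table by sites and/or samples
#'
#' @param vt a `variant_table`.
#' @param i site index (logical or integer); `j` sample index.
#' @return a `variant_table`.
#' @export
vt_subset <- function(vt, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(vt$sites))
  if (is.null(j)) j <- seq_along(vt$samples)
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  variant_table(vt$sites[i, , drop = FALSE], sub(vt$gt), sub(vt$dp),
                sub(vt$gq), sub(vt$ad_ref), sub(vt$ad_alt),
                samples = vt$samples[j])
}

#' Write a variant table as VCF 4.2
#'
#' SNP and other variant records carry `FORMAT GT:DP:GQ:AD`; invariant
#' records carry `GT:DP` only. Site annotations QD/MQ/MQRankSum are written
#' to INFO when present. `header_extra` lines (e.g. filter provenance) are
#' inserted verbatim after the format definitions.
#'
#' @param vt a `variant_table`.
#' @param path output file (plain text).
#' @param header_extra character vector of additional `##` header lines.
#' @export
write_vcf <- function(vt, path, header_extra = character(0)) {
  n <- nrow(vt$sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=spetkit",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           header_extra,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vt$gt + 1L], nrow = n)
  gt_str[is.na(vt$gt)] <- "./."
  num_or_dot <- function(m) {
    if (is.null(m)) return(matrix(".", n, length(vt$samples)))
    s <- matrix(as.character(m), nrow = n)
    s[is.na(m)] <- "."
    s
  }
  dp_s <- num_or_dot(vt$dp); gq_s <- num_or_dot(vt$gq)
  ad_s <- if (!is.null(vt$ad_ref) && !is.null(vt$ad_alt))
    matrix(paste(num_or_dot(vt$ad_ref), num_or_dot(vt$ad_alt), sep = ","),
           nrow = n)
  else matrix(".", n, length(vt$samples))
  info <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    s <- vt$sites[i, ]
    if (!is.na(s$qd)) parts <- c(parts, sprintf("QD=%.2f", s$qd))
    if (!is.na(s$mq)) parts <- c(parts, sprintf("MQ=%.2f", s$mq))
    if (!is.na(s$mqranksum))
      parts <- c(parts, sprintf("MQRankSum=%.3f", s$mqranksum))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  inv <- vt$sites$class == "invariant"
  fmt <- ifelse(inv, "GT:DP", "GT:DP:GQ:AD")
  body <- vapply(seq_len(n), function(i) {
    cells <- if (inv[i]) paste(gt_str[i, ], dp_s[i, ], sep = ":")
    else paste(gt_str[i, ], dp_s[i, ], gq_s[i, ], ad_s[i, ], sep = ":")
    paste(c(vt$sites$chrom[i], vt$sites$pos[i], ".", vt$sites$ref[i],
            vt$sites$alt[i], ".", "PASS", info[i], fmt[i], cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses with `vcfR`; tolerates gVCF-style `<NON_REF>` alternates (treated
#' as invariant when no real alternate is present). Genotype dosage is the
#' count of `1` alleles; genotypes referencing alleles beyond the first
#' alternate are set NA (such sites are non-biallelic and handled at the
#' site level by the filters).
#'
#' @param path VCF file.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  get_info <- function(tag) {
    x <- vcfR::extract.info(v, tag, as.numeric = TRUE)
    if (is.null(x) || length(x) == 0) rep(NA_real_, n) else as.numeric(x)
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF,
                      alt = ifelse(is.na(fix$ALT), ".", fix$ALT),
                      qd = get_info("QD"), mq = get_info("MQ"),
                      mqranksum = get_info("MQRankSum"),
                      stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, "GT")
  alleles <- gsub("[|]", "/", gt_raw)
  spl <- strsplit(alleles, "/", fixed = TRUE)
  dose1 <- function(a) {
    if (any(is.na(a)) || any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }
  gt <- matrix(vapply(spl, dose1, integer(1)), nrow = n)
  num_mat <- function(tag) {
    x <- tryCatch(vcfR::extract.gt(v, tag, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(x)) return(NULL)
    matrix(as.integer(x), nrow = n)
  }
  dp <- num_mat("DP"); gq <- num_mat("GQ")
  ad_raw <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad_raw)) {
    parts <- strsplit(ad_raw, ",", fixed = TRUE)
    take <- function(k) matrix(vapply(parts, function(p) {
      if (length(p) < k || is.na(p[k]) || p[k] == ".") NA_integer_
      else as.integer(p[k])
    }, integer(1)), nrow = n)
    ad_ref <- take(1L); ad_alt <- take(2L)
  }
  variant_table(sites, gt, dp, gq, ad_ref, ad_alt,
                samples = colnames(gt_raw))
}
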