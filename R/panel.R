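# Panel assembly: random target sites drawn from eligible low-repeat
# regions, known targets ingested from VCF/BED, and a manifest of capture
# probes. At least half of the panel is random sites so that diversity
# estimates from the panel are free of ascertainment bias.

#' Select random target sites from eligible regions
#'
#' Draws `n` positions uniformly without replacement from the union of
#' region positions, subject to a minimum pairwise spacing on each
#' sequence. Deterministic given `seed`.
#'
#' @param regions data.frame from [eligible_regions()] (`seq_id`, `start`,
#'   `end`; 0-based half-open).
#' @param n number of sites.
#' @param seed RNG seed.
#' @param min_spacing minimum distance in bp between two selected sites on
#'   the same sequence (default 1000).
#' @param origin_species label recorded on the sites (default `"self"`).
#' @return data.frame `seq_id`, `pos` (0-based), `site_type = "random"`,
#'   `origin_species`, sorted by coordinate.
#' @export
select_random_sites <- function(regions, n, seed = 1L, min_spacing = 1000L,
                                origin_species = "self") {
  stopifnot(nrow(regions) > 0, n >= 1)
  ## capacity under optimal left-to-right packing
  capacity <- sum(vapply(seq_len(nrow(regions)), function(i) {
    len <- as.integer(regions$end[i] - regions$start[i])
    (len - 1L) %/% as.integer(min_spacing) + 1L
  }, integer(1)))
  if (n > capacity)
    stop(sprintf(paste0("capacity error: %d sites requested but regions can",
                        " hold at most %d at spacing %d (shortfall %d)"),
                 n, capacity, min_spacing, n - capacity))
  pool <- data.frame(
    seq_id = rep(regions$seq_id, regions$end - regions$start),
    pos = unlist(lapply(seq_len(nrow(regions)), function(i)
      seq(regions$start[i], regions$end[i] - 1L)), use.names = FALSE),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    for (attempt in 1:100) {
      avail <- rep(TRUE, nrow(pool))
      picked <- integer(0)
      while (length(picked) < n && any(avail)) {
        j <- resample(which(avail))
        picked <- c(picked, j)
        avail[pool$seq_id == pool$seq_id[j] &
                abs(pool$pos - pool$pos[j]) < min_spacing] <- FALSE
      }
      if (length(picked) == n) break
    }
    if (length(picked) < n)
      stop(sprintf("capacity error: only %d of %d sites placeable at spacing %d",
                   length(picked), n, min_spacing))
    out <- pool[picked, , drop = FALSE]
    out <- out[order(out$seq_id, out$pos), , drop = FALSE]
    out$site_type <- "random"
    out$origin_species <- origin_species
    rownames(out) <- NULL
    out
  })
}

#' Load known target sites from a VCF or BED file
#'
#' VCF records yield one site at POS (converted to 0-based); BED intervals
#' yield a site at the interval start, with a warning when the interval is
#' longer than 1 bp. Duplicate positions are collapsed with a warning.
#'
#' @param path VCF (detected by `##fileformat`/`.vcf` extension) or BED file.
#' @param origin_species label recorded on the sites.
#' @return data.frame `seq_id`, `pos` (0-based), `site_type = "known"`,
#'   `origin_species`, and `ref_allele` for VCF input.
#' @export
load_known_targets <- function(path, origin_species = "unknown") {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)
  if (is_vcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    out <- data.frame(seq_id = as.character(v@fix[, "CHROM"]),
                      pos = as.integer(v@fix[, "POS"]) - 1L,
                      site_type = "known", origin_species = origin_species,
                      ref_allele = as.character(v@fix[, "REF"]),
                      stringsAsFactors = FALSE)
  } else {
    bed <- tryCatch(
      read.table(path, sep = "\t", header = FALSE,
                 stringsAsFactors = FALSE),
      error = function(e) stop("malformed BED: ", conditionMessage(e)))
    if (ncol(bed) < 3 || !is.numeric(bed[[2]]) || !is.numeric(bed[[3]]))
      stop("malformed BED: need numeric start/end in columns 2-3")
    wide <- bed[[3]] - bed[[2]] > 1
    if (any(wide))
      warning(sum(wide), " BED interval(s) longer than 1 bp: using start")
    out <- data.frame(seq_id = as.character(bed[[1]]),
                      pos = as.integer(bed[[2]]),
                      site_type = "known", origin_species = origin_species,
                      ref_allele = NA_character_, stringsAsFactors = FALSE)
  }
  dup <- duplicated(paste(out$seq_id, out$pos))
  if (any(dup)) {
    warning(sum(dup), " duplicated target position(s) collapsed")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assemble a target panel honouring the random-site fraction
#'
#' Combines random and known target sites into a panel of exactly `total`
#' sites with at least `min_random_frac` random sites. Known sites beyond
#' their allowance are uniformly subsampled (seeded); positions present in
#' both lists are kept as known. Random sites beyond the remainder are
#' uniformly subsampled too.
#'
#' @param random,known site data.frames (see [select_random_sites()],
#'   [load_known_targets()]).
#' @param total panel size.
#' @param min_random_frac minimum fraction of random sites (default 0.5).
#' @param seed RNG seed for subsampling.
#' @return data.frame of `total` sites with a `site_type` column; attribute
#'   `summary` holds counts by type and origin species.
#' @export
assemble_panel <- function(random, known, total, min_random_frac = 0.5,
                           seed = 1L) {
  if (is.null(known)) known <- random[0, , drop = FALSE]
  key <- function(d) paste(d$seq_id, d$pos)
  clash <- key(random) %in% key(known)
  if (any(clash)) random <- random[!clash, , drop = FALSE]  # known wins
  if (nrow(random) + nrow(known) < total)
    stop("not enough candidate sites: ", nrow(random) + nrow(known),
         " available, ", total, " requested")
  max_known <- floor((1 - min_random_frac) * total)
  with_seed(seed, {
    if (nrow(known) > max_known)
      known <- known[sort(resample(seq_len(nrow(known)), max_known)), ,
                     drop = FALSE]
    n_random <- total - nrow(known)
    if (nrow(random) < n_random)
      stop(sprintf(paste0("constraint error: need %d random sites to keep ",
                          "the random fraction >= %.2f but only %d available"),
                   n_random, min_random_frac, nrow(random)))
    if (nrow(random) > n_random)
      random <- random[sort(resample(seq_len(nrow(random)), n_random)), ,
                       drop = FALSE]
  })
  cols <- c("seq_id", "pos", "site_type", "origin_species")
  panel <- rbind(random[, cols], known[, cols])
  panel <- panel[order(panel$seq_id, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  stopifnot(sum(panel$site_type == "random") / nrow(panel) >=
              min_random_frac)
  attr(panel, "summary") <- as.data.frame(
    table(site_type = panel$site_type,
          origin_species = panel$origin_species))
  panel
}

#' Build the probe manifest for a panel
#'
#' A probe is the `probe_len` reference bases immediately 5' of the target
#' on the chosen strand, so that primer extension sequences into the target
#' site. `strand_rule = "auto"` places the probe upstream on `+` when the
#' target has enough left flank, otherwise on `-`; targets with no valid
#' placement are skipped with a message.
#'
#' @param panel site data.frame from [assemble_panel()].
#' @param ref reference sequences.
#' @param probe_len probe length in bp (default 40).
#' @param strand_rule `"auto"`, `"plus"` or `"minus"`.
#' @param out_dir if non-NULL, writes `panel_manifest.tsv`, `probes.fa` and
#'   `targets.bed` there.
#' @return data.frame manifest: `probe_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, `sequence`, `target_pos` (0-based),
#'   `site_type`, `origin_species`. Skipped targets are recorded in the
#'   `skipped` attribute.
#' @export
emit_probe_manifest <- function(panel, ref, probe_len = 40L,
                                strand_rule = c("auto", "plus", "minus"),
                                out_dir = NULL) {
  strand_rule <- match.arg(strand_rule)
  ref <- as_reference(ref)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(panel))) {
    sid <- panel$seq_id[i]; pos <- panel$pos[i]
    L <- nchar(ref[[sid]])
    plus_ok <- pos - probe_len >= 0
    minus_ok <- pos + 1L + probe_len <= L
    strand <- switch(strand_rule,
                     plus = if (plus_ok) "+" else NA,
                     minus = if (minus_ok) "-" else NA,
                     auto = if (plus_ok) "+" else if (minus_ok) "-" else NA)
    if (is.na(strand)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        seq_id = sid, pos = pos, reason = "insufficient flank")
      next
    }
    if (strand == "+") {
      start <- pos - probe_len; end <- pos
      seqn <- substr(ref[[sid]], start + 1L, end)
    } else {
      start <- pos + 1L; end <- pos + 1L + probe_len
      seqn <- revcomp(substr(ref[[sid]], start + 1L, end))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = NA_character_, seq_id = sid, start = start, end = end,
      strand = strand, sequence = seqn, target_pos = pos,
      site_type = panel$site_type[i],
      origin_species = panel$origin_species[i], stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0)
    message(length(skipped), " target(s) skipped: insufficient flank")
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               sequence = character(0), target_pos = integer(0),
               site_type = character(0), origin_species = character(0))
  manifest$probe_id <- sprintf("probe%05d", seq_len(nrow(manifest)))
  attr(manifest, "skipped") <-
    if (length(skipped)) do.call(rbind, skipped) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel_manifest(manifest, file.path(out_dir, "panel_manifest.tsv"))
    writeLines(as.vector(rbind(paste0(">", manifest$probe_id),
                               manifest$sequence)),
               file.path(out_dir, "probes.fa"))
    write.table(data.frame(manifest$seq_id, manifest$target_pos,
                           manifest$target_pos + 1L, manifest$probe_id),
                file.path(out_dir, "targets.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest
}

#' Write / read a probe manifest TSV
#'
#' The TSV carries the target position 1-based in a dedicated
#' `target_pos_1based` column; in-memory coordinates stay 0-based.
#' Re-reading reproduces the manifest exactly.
#'
#' @param manifest data.frame from [emit_probe_manifest()].
#' @param path TSV file.
#' @export
write_panel_manifest <- function(manifest, path) {
  out <- manifest
  out$target_pos_1based <- out$target_pos + 1L
  out$target_pos <- NULL
  write_tsv(out, path)
}

#' @rdname write_panel_manifest
#' @export
read_panel_manifest <- function(path) {
  d <- read_tsv(path, colClasses = c(sequence = "character"))
  d$target_pos <- d$target_pos_1based - 1L
  d$target_pos_1based <- NULL
  d[, c("probe_id", "seq_id", "start", "end", "strand", "sequence",
        "target_pos", "site_type", "origin_species")]
}
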