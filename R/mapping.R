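# Exact placement of error-free read pairs. This is an exact-match mapper,
# valid only for reads simulated without errors; real-read alignment is out
# of scope (done upstream with a general aligner). Used to anchor transcripts
# onto a related genome when no own-species genome exists.

## index all exact matches of a set of equal-length patterns against every
## reference sequence; returns data.frame(pattern, seq_id, start0)
exact_hits <- function(patterns, ref) {
  has_n <- grepl("N", patterns, fixed = TRUE)
  ok <- which(!has_n)
  out <- list()
  if (length(ok) > 0) {
    pd <- PDict(DNAStringSet(patterns[ok]))
    for (sid in names(ref)) {
      subj <- DNAStringSet(ref[[sid]])[[1]]
      m <- matchPDict(pd, subj)
      si <- startIndex(m)
      nh <- lengths(si)
      if (sum(nh) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        pattern = rep(ok[nh > 0], nh[nh > 0]),
        seq_id = sid,
        start0 = unlist(si[nh > 0], use.names = FALSE) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(pattern = integer(0), seq_id = character(0),
                      start0 = integer(0)))
  do.call(rbind, out)
}

#' Exactly map error-free read pairs to a reference
#'
#' Finds every exact placement of each mate on either strand, then counts
#' consistent forward-reverse (FR) co-placements of the pair on one sequence.
#' A pair is `unique` when exactly one such placement exists, and `proper`
#' when the placement's insert length lies within
#' `insert_mean +/- sd_window * insert_sd`.
#'
#' Only valid for reads that are exact substrings of the reference (or its
#' reverse complement); reads containing `N` never match.
#'
#' @param pairs data.frame with columns `pair_id`, `mate1`, `mate2`
#'   (equal-length DNA strings), e.g. from [simulate_perfect_read_pairs()].
#' @param ref reference sequences (named character vector, `DNAStringSet`,
#'   or FASTA path).
#' @param insert_mean,insert_sd,sd_window define the proper-pair insert
#'   window (defaults 400, 25, 4).
#' @return data.frame, one row per pair: `pair_id`, `n_hits`, `unique`,
#'   `proper`, and the representative placement (`seq_id`, `start1`,
#'   `strand1`, `start2`, `strand2`, `insert`; 0-based starts, NA when
#'   unplaced). The representative is the first placement in (seq, position)
#'   order.
#' @export
map_perfect_reads <- function(pairs, ref, insert_mean = 400L,
                              insert_sd = 25L, sd_window = 4L) {
  ref <- as_reference(ref)
  stopifnot(all(c("pair_id", "mate1", "mate2") %in% names(pairs)))
  mates <- c(pairs$mate1, pairs$mate2)
  if (any(grepl("[^ACGTN]", mates)))
    stop("read containing non-ACGTN symbol")
  rl <- unique(nchar(mates))
  if (length(rl) != 1) stop("all mates must have the same length")
  n <- nrow(pairs)

  fwd <- exact_hits(mates, ref)                 # read matches + strand
  rev <- exact_hits(revcomp(mates), ref)        # read matches - strand
  fwd_idx <- split(seq_len(nrow(fwd)), fwd$pattern)
  rev_idx <- split(seq_len(nrow(rev)), rev$pattern)
  get_hits <- function(df, idx, p) {
    i <- idx[[as.character(p)]]
    if (is.null(i)) df[0, ] else df[i, , drop = FALSE]
  }

  lo <- insert_mean - sd_window * insert_sd
  hi <- insert_mean + sd_window * insert_sd
  res <- vector("list", n)
  for (i in seq_len(n)) {
    ## FR placements: forward mate left of (or at) reverse mate
    combos <- list()
    for (orient in 1:2) {
      pf <- if (orient == 1) i else n + i       # which mate is forward
      pr <- if (orient == 1) n + i else i
      hf <- get_hits(fwd, fwd_idx, pf)
      hr <- get_hits(rev, rev_idx, pr)
      if (nrow(hf) == 0 || nrow(hr) == 0) next
      for (j in seq_len(nrow(hf))) {
        same <- hr$seq_id == hf$seq_id[j] & hr$start0 >= hf$start0[j]
        if (!any(same)) next
        rs <- hr$start0[same]
        combos[[length(combos) + 1L]] <- data.frame(
          seq_id = hf$seq_id[j], fstart = hf$start0[j], rstart = rs,
          insert = rs + rl - hf$start0[j], orient = orient,
          stringsAsFactors = FALSE)
      }
    }
    if (length(combos) == 0) {
      res[[i]] <- data.frame(pair_id = pairs$pair_id[i], n_hits = 0L,
                             unique = FALSE, proper = NA,
                             seq_id = NA_character_, start1 = NA_integer_,
                             strand1 = NA_character_, start2 = NA_integer_,
                             strand2 = NA_character_, insert = NA_integer_,
                             stringsAsFactors = FALSE)
      next
    }
    cb <- do.call(rbind, combos)
    cb <- cb[order(cb$seq_id, cb$fstart, cb$rstart, cb$orient), , drop = FALSE]
    top <- cb[1, ]
    if (top$orient == 1) {                      # mate1 forward
      s1 <- top$fstart; st1 <- "+"; s2 <- top$rstart; st2 <- "-"
    } else {
      s1 <- top$rstart; st1 <- "-"; s2 <- top$fstart; st2 <- "+"
    }
    res[[i]] <- data.frame(pair_id = pairs$pair_id[i], n_hits = nrow(cb),
                           unique = nrow(cb) == 1L,
                           proper = top$insert >= lo & top$insert <= hi,
                           seq_id = top$seq_id, start1 = s1, strand1 = st1,
                           start2 = s2, strand2 = st2,
                           insert = as.integer(top$insert),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Transcript-genome contiguity regions
#'
#' Identifies intervals of each transcript that are contiguous with the
#' genome of a related species, the substrate for probe design when no
#' own-species genome exists. Read pairs simulated from the transcriptome and
#' exactly mapped to the genome are kept when uniquely and properly placed
#' AND collinear: the genomic fragment span equals the transcript fragment
#' span exactly (reads are error-free, so any intron between the mates
#' enlarges the genomic span and disqualifies the pair). Kept fragments cover
#' their transcript interval; covered intervals are merged and those at least
#' `min_len` bp long are returned. Reads that cross an exon-intron junction
#' fail full-length exact placement, so junctions always break coverage.
#'
#' @param alignments output of [map_perfect_reads()] for the simulated pairs
#'   against the genome.
#' @param pairs the simulated pairs with their transcript source records
#'   (`pair_id`, `seq_id`, `frag_start`, `frag_end`), from
#'   [simulate_perfect_read_pairs()].
#' @param min_len minimum region length in transcript bases (default 200).
#' @param max_gap upper bound on the genomic fragment span (default 500,
#'   i.e. insert mean 400 + 4 x sd 25).
#' @return data.frame `seq_id` (transcript), `start`, `end` (0-based
#'   half-open), `mean_kmer` (NA: not applicable here).
#' @export
contiguity_regions <- function(alignments, pairs, min_len = 200L,
                               max_gap = 500L) {
  if (nrow(alignments) == 0) {
    warning("empty alignment set: no contiguity regions")
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), mean_kmer = numeric(0)))
  }
  stopifnot(all(c("pair_id", "seq_id", "frag_start", "frag_end") %in%
                names(pairs)))
  m <- match(alignments$pair_id, pairs$pair_id)
  if (anyNA(m)) stop("alignment pair_id absent from pairs")
  t_span <- pairs$frag_end[m] - pairs$frag_start[m]
  keep <- alignments$n_hits == 1L & alignments$unique &
    !is.na(alignments$proper) & alignments$proper &
    alignments$insert == t_span & alignments$insert <= max_gap
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), mean_kmer = numeric(0)))
  cov <- data.frame(seq_id = pairs$seq_id[m][keep],
                    start = pairs$frag_start[m][keep],
                    end = pairs$frag_end[m][keep])
  out <- list()
  for (sid in sort(unique(cov$seq_id))) {
    cc <- cov[cov$seq_id == sid, , drop = FALSE]
    ## min.gapwidth = 0: abutting fragments do NOT merge -- two fragments
    ## meeting exactly at an uncovered point (e.g. an exon junction) must
    ## not produce a region spanning it
    merged <- reduce(IRanges(start = cc$start + 1L, end = cc$end),
                     min.gapwidth = 0L)
    wide <- width(merged) >= min_len
    if (!any(wide)) next
    out[[length(out) + 1L]] <- data.frame(
      seq_id = sid, start = start(merged)[wide] - 1L, end = end(merged)[wide],
      mean_kmer = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), mean_kmer = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
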