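# k-mer occurrence counting and mappability over a reference.
#
# A position's mappability value is the genome-wide occurrence count of the
# k-mer starting there; low values mean locally unique sequence where capture
# probes can be placed without ambiguity. Counting is canonical (strand-folded)
# by default since hybridisation capture is strand-symmetric.

## forward and reverse-complement k-mer windows of one sequence.
## Returns list(fwd, rc, has_n) each of length L - k + 1 (or NULL if L < k).
kmer_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(NULL)
  n_win <- L - k + 1L
  starts <- seq_len(n_win)
  fwd <- substring(seq, starts, starts + k - 1L)
  ## revcomp of window at p = window of revcomp(seq) at L - k - p + 2
  rc_seq <- revcomp(seq)
  rc <- substring(rc_seq, L - k - starts + 2L, L - starts + 1L)
  ## window contains N iff cumulative N count increases across it
  is_n <- as.integer(strsplit(seq, "", fixed = TRUE)[[1]] == "N")
  cn <- cumsum(is_n)
  has_n <- (cn[starts + k - 1L] - c(0L, cn)[starts]) > 0L
  list(fwd = fwd, rc = rc, has_n = has_n)
}

canonical_kmers <- function(w, canonical = TRUE) {
  if (canonical) pmin(w$fwd, w$rc) else w$fwd
}

#' Build a k-mer occurrence index over a reference
#'
#' Counts every k-length window that contains no `N`, over all sequences of
#' the reference. By default windows are folded into canonical classes (the
#' lexicographically smaller of a k-mer and its reverse complement), so both
#' strands contribute to one count.
#'
#' @param ref reference sequences: a named character vector, a
#'   `DNAStringSet`, or a FASTA file path.
#' @param k k-mer size (default 20).
#' @param canonical fold reverse complements into one class (default `TRUE`).
#' @return an object of class `kmer_index`: list with elements `k`,
#'   `canonical`, and `counts` (named integer vector, every count >= 1).
#' @examples
#' idx <- build_kmer_index(c(chr = "AAAAA"), k = 4)
#' idx$counts
#' @export
build_kmer_index <- function(ref, k = 20L, canonical = TRUE) {
  stopifnot(k >= 2)
  ref <- as_reference(ref)
  all_kmers <- character(0)
  for (s in ref) {
    w <- kmer_windows(s, k)
    if (is.null(w)) next
    all_kmers <- c(all_kmers, canonical_kmers(w, canonical)[!w$has_n])
  }
  if (length(all_kmers) == 0)
    stop("no sequence of length >= k: cannot build an empty k-mer index")
  u <- unique(all_kmers)
  counts <- tabulate(match(all_kmers, u), nbins = length(u))
  structure(list(k = as.integer(k), canonical = canonical,
                 counts = setNames(as.integer(counts), u)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %s, %d distinct k-mers, %d windows\n",
              x$k, if (x$canonical) "canonical" else "single-strand",
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Per-position mappability track
#'
#' For every position p of each reference sequence, the occurrence count (from
#' a prebuilt index) of the k-mer starting at p. Windows containing `N` are
#' `NA` (undefined): no probe can be designed over them.
#'
#' @param index a `kmer_index` built over a superset of `ref` with the same k.
#' @param ref reference sequences (see [build_kmer_index()]).
#' @return object of class `mappability_track`: list with `k` and `values`, a
#'   named list of integer vectors of length `L - k + 1` (NA where undefined).
#' @export
mappability_track <- function(index, ref) {
  stopifnot(inherits(index, "kmer_index"))
  ref <- as_reference(ref)
  k <- index$k
  values <- lapply(ref, function(s) {
    w <- kmer_windows(s, k)
    if (is.null(w)) return(integer(0))
    km <- canonical_kmers(w, index$canonical)
    v <- unname(index$counts[km])
    if (anyNA(v[!w$has_n]))
      stop("k-mer present in reference but absent from index: ",
           "index was not built over a superset of this reference")
    v[w$has_n] <- NA_integer_
    as.integer(v)
  })
  structure(list(k = k, values = values), class = "mappability_track")
}

## deterministic refinement of one candidate run [s, e] (1-based inclusive
## indices into v): if the run fails the mean criterion, split at the leftmost
## maximum and recurse on both halves.
split_run <- function(v, s, e, min_len, mean_max) {
  if (e - s + 1L < min_len) return(NULL)
  if (mean(v[s:e]) < mean_max) {
    return(data.frame(start = s, end = e))
  }
  m <- s - 1L + which.max(v[s:e])  # which.max -> leftmost tie
  rbind(split_run(v, s, m - 1L, min_len, mean_max),
        split_run(v, m + 1L, e, min_len, mean_max))
}

#' Detect regions eligible for random target sites
#'
#' Scans a mappability track for stretches of locally unique sequence:
#' maximal runs of defined positions whose per-position count is at most
#' `pos_cap` are refined (recursive splitting at the leftmost maximal count)
#' until every emitted region is at least `min_len` positions long with mean
#' count strictly below `mean_max`.
#'
#' Coordinates are 0-based half-open over k-mer start positions.
#'
#' @param track a `mappability_track`.
#' @param min_len minimum region length in positions (default 200).
#' @param mean_max strict upper bound on the mean k-mer count (default 2.0).
#' @param pos_cap per-position count cap defining candidate runs (default 4);
#'   prevents a single strong repeat spike from being averaged away.
#' @return data.frame with columns `seq_id`, `start`, `end`, `mean_kmer`,
#'   sorted and non-overlapping. Zero rows if nothing qualifies.
#' @export
eligible_regions <- function(track, min_len = 200L, mean_max = 2.0,
                             pos_cap = 4L) {
  stopifnot(inherits(track, "mappability_track"))
  out <- list()
  for (sid in names(track$values)) {
    v <- track$values[[sid]]
    if (length(v) == 0) next
    ok <- !is.na(v) & v <= pos_cap
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      regs <- split_run(v, starts[i], ends[i], min_len, mean_max)
      if (is.null(regs) || nrow(regs) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sid,
        start = regs$start - 1L,            # to 0-based
        end = regs$end,                     # half-open
        mean_kmer = vapply(seq_len(nrow(regs)), function(j)
          mean(v[regs$start[j]:regs$end[j]]), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), mean_kmer = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write eligible regions as BED
#'
#' BED score column carries `round(mean_kmer * 100)`.
#'
#' @param regions data.frame from [eligible_regions()].
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$seq_id, start = regions$start,
                    end = regions$end,
                    name = sprintf("region_%04d", seq_len(nrow(regions))),
                    score = round(regions$mean_kmer * 100))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a mappability track as bedGraph
#'
#' Adjacent positions with equal counts are merged into one interval;
#' undefined (N-window) positions are omitted.
#'
#' @param track a `mappability_track`.
#' @param path output file.
#' @export
write_track_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sid in names(track$values)) {
    v <- track$values[[sid]]
    if (length(v) == 0) next
    r <- rle(ifelse(is.na(v), -1L, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values >= 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%d", sid, starts[keep] - 1L,
                       ends[keep], r$values[keep]), con)
  }
  invisible(path)
}
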