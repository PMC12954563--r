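# Independent brute-force oracles used to verify the implementation.
# Deliberately written with different machinery (per-window loops,
# Biostrings reverseComplement, pairwise enumeration) than the package code.

## dictionary k-mer count by explicit window loop
naive_kmer_count <- function(seq, k, canonical = TRUE) {
  counts <- new.env(hash = TRUE)
  L <- nchar(seq)
  for (p in seq_len(L - k + 1)) {
    w <- substr(seq, p, p + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    if (canonical) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
      w <- min(w, rc)
    }
    counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

## naive eligible-region enumeration: scan maximal runs by explicit loop,
## then apply the documented split rule with a stack instead of recursion
naive_eligible_regions <- function(v, min_len, mean_max, pos_cap) {
  runs <- list(); s <- NA
  for (p in seq_along(v)) {
    ok <- !is.na(v[p]) && v[p] <= pos_cap
    if (ok && is.na(s)) s <- p
    if (!ok && !is.na(s)) { runs[[length(runs) + 1]] <- c(s, p - 1); s <- NA }
  }
  if (!is.na(s)) runs[[length(runs) + 1]] <- c(s, length(v))
  out <- list()
  for (r in runs) {
    stack <- list(r)
    while (length(stack) > 0) {
      seg <- stack[[1]]; stack <- stack[-1]
      if (seg[2] - seg[1] + 1 < min_len) next
      vals <- v[seg[1]:seg[2]]
      if (sum(vals) / length(vals) < mean_max) {
        out[[length(out) + 1]] <- seg
      } else {
        m <- seg[1] - 1 + which(vals == max(vals))[1]
        stack <- c(list(c(seg[1], m - 1), c(m + 1, seg[2])), stack)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  d <- do.call(rbind, lapply(out, function(x)
    data.frame(start = x[1] - 1L, end = x[2])))
  d[order(d$start), , drop = FALSE]
}

## brute-force pi: expand genotypes to allele copies, enumerate all pairs
naive_pi <- function(gt) {
  num <- 0; denom <- 0
  for (i in seq_len(nrow(gt))) {
    copies <- integer(0)
    for (g in gt[i, ]) {
      if (is.na(g)) next
      copies <- c(copies, if (g == 0L) c(0L, 0L)
                  else if (g == 1L) c(0L, 1L) else c(1L, 1L))
    }
    n <- length(copies)
    if (n < 2) next
    for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
      denom <- denom + 1
      if (copies[a] != copies[b]) num <- num + 1
    }
  }
  num / denom
}

## brute-force depth of reads over a single position
naive_depth <- function(reads, sid, pos) {
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$seq_id[i] == sid && reads$start[i] <= pos &&
        pos < reads$start[i] + reads$len[i]) n <- n + 1L
  }
  n
}

## Hamming-ball UMI grouping oracle for tiny inputs: brute-force connected
## grouping by greedy center assignment in frequency order
naive_umi_groups <- function(umis, max_dist) {
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  tab <- sort(table(umis), decreasing = TRUE)
  u <- names(tab)[order(-as.integer(tab), names(tab))]
  centers <- character(0); assign <- character(0)
  for (x in u) {
    placed <- FALSE
    for (ctr in centers) if (hd(x, ctr) <= max_dist) {
      assign[x] <- ctr; placed <- TRUE; break
    }
    if (!placed) { centers <- c(centers, x); assign[x] <- x }
  }
  length(unique(assign[umis]))
}
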