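# UMI-based removal of PCR duplicates from aligned capture reads. Reads are
# grouped by (sequence, start of read 1, strand, UMI); one representative
# per group is retained. Optional Hamming-distance collapsing absorbs UMIs
# within `umi_mismatch` of a more abundant UMI in the same positional group.

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## greedy Hamming-ball clustering of UMIs within one positional group:
## centers taken in order of decreasing read count (ties: lexicographic)
cluster_umis <- function(umis, counts, max_dist) {
  ord <- order(-counts, umis)
  centers <- character(0)
  assign <- character(length(umis))
  for (i in ord) {
    hit <- NA_character_
    for (ctr in centers) {
      if (hamming(umis[i], ctr) <= max_dist) { hit <- ctr; break }
    }
    if (is.na(hit)) { centers <- c(centers, umis[i]); hit <- umis[i] }
    assign[i] <- hit
  }
  setNames(assign, umis)
}

#' Remove UMI duplicates from aligned reads
#'
#' Groups reads by (seq_id, start, strand, UMI) and retains one
#' representative per group: the read with the highest mean base quality,
#' ties broken by lexicographically smallest read id. With
#' `umi_mismatch > 0`, UMIs within that Hamming distance of a more abundant
#' UMI at the same position are collapsed into its group first.
#'
#' @param records data.frame of aligned reads with columns `read_id`,
#'   `umi`, `seq_id`, `start`, `strand`, `baseq` (e.g.
#'   `simulate_capture_reads()$reads`).
#' @param umi_mismatch maximum Hamming distance for UMI collapsing
#'   (default 0 = exact).
#' @return list with `retained` (data.frame of kept reads), `duplicates`
#'   (data.frame of removed reads with their group key) and `report`
#'   (n_reads, n_groups, n_duplicates).
#' @export
dedup <- function(records, umi_mismatch = 0L) {
  stopifnot(all(c("read_id", "umi", "seq_id", "start", "strand", "baseq")
                %in% names(records)))
  if (nrow(records) == 0)
    return(list(retained = records, duplicates = records,
                report = data.frame(n_reads = 0L, n_groups = 0L,
                                    n_duplicates = 0L)))
  if (any(grepl("[^ACGT]", records$umi))) stop("UMI with non-ACGT symbol")
  if (length(unique(nchar(records$umi))) != 1)
    stop("inconsistent UMI length across records")
  pos_key <- paste(records$seq_id, records$start, records$strand, sep = "|")
  umi_eff <- records$umi
  if (umi_mismatch > 0) {
    for (pk in unique(pos_key)) {
      sel <- pos_key == pk
      tab <- table(records$umi[sel])
      map <- cluster_umis(names(tab), as.integer(tab), umi_mismatch)
      umi_eff[sel] <- unname(map[records$umi[sel]])
    }
  }
  grp <- paste(pos_key, umi_eff, sep = "|")
  ord <- order(grp, -records$baseq, records$read_id)
  first <- !duplicated(grp[ord])
  keep_idx <- ord[first]
  dup_idx <- ord[!first]
  dups <- records[dup_idx, , drop = FALSE]
  if (nrow(dups) > 0) dups$group <- grp[dup_idx]
  else dups$group <- character(0)
  ret <- records[sort(keep_idx), , drop = FALSE]
  rownames(ret) <- NULL
  list(retained = ret,
       duplicates = dups,
       report = data.frame(n_reads = nrow(records),
                           n_groups = length(unique(grp)),
                           n_duplicates = length(dup_idx)))
}
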