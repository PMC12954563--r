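# Synthetic genome / read-pair / capture simulators. These are first-class,
# deterministic generators providing known truth (repeat masks, gene models,
# duplicate structure) for every downstream stage.

## sample from a vector even when it has length 1 (avoids sample()'s
## integer-shorthand surprise)
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## place n_blocks non-overlapping intervals of given widths on [1, L],
## avoiding `occupied` (IRanges); returns start positions (1-based) or errors
place_blocks <- function(L, widths, occupied, max_tries = 2000L) {
  starts <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - w + 1L, 1L)
      cand <- IRanges(start = s, end = s + w - 1L)
      if (length(occupied) == 0 ||
          sum(IRanges::countOverlaps(cand, occupied)) == 0) {
        occupied <- c(occupied, cand)
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place feature: genome too small for the ",
                      "requested repeat/gene content")
  }
  list(starts = starts, occupied = occupied)
}

#' Simulate a genome with repeat families and gene models
#'
#' Generates a random genome carrying exact repeat-family copies and
#' multi-exon gene models, together with full truth annotations: repeat
#' placements, a repeat mask, exon intervals, and the spliced transcript of
#' every gene. Deterministic given `seed`.
#'
#' @param length genome length in bp.
#' @param n_genes number of gene models to place (default 0).
#' @param repeat_spec list of repeat families, each a list with `length`
#'   (copy length, bp) and `copies` (number of exact copies).
#' @param exon_range,intron_range,n_exon_range ranges (min,max) for exon
#'   length, intron length and exon count per gene.
#' @param seed RNG seed.
#' @return object of class `genome_truth`: list with `genome` (named
#'   character, one sequence `chr1`), `repeats` (data.frame family, copy,
#'   start, end; 0-based half-open), `mask` (logical vector, TRUE =
#'   repetitive), `genes` (data.frame gene_id, exon, start, end),
#'   `transcripts` (named character vector of spliced sequences).
#' @export
simulate_genome <- function(length, n_genes = 0L, repeat_spec = list(),
                            exon_range = c(400L, 800L),
                            intron_range = c(300L, 1500L),
                            n_exon_range = c(1L, 3L), seed = 1L) {
  stopifnot(length >= 200)
  rep_total <- sum(vapply(repeat_spec, function(r)
    r$length * r$copies, numeric(1)))
  if (rep_total > 0.8 * length)
    stop("repeat content exceeds genome capacity")
  with_seed(seed, {
    g <- random_dna(length)
    occupied <- IRanges()
    repeats <- list()
    for (fi in seq_along(repeat_spec)) {
      fam <- repeat_spec[[fi]]
      unit <- random_dna(fam$length)
      pl <- place_blocks(length, rep(fam$length, fam$copies), occupied)
      occupied <- pl$occupied
      for (ci in seq_len(fam$copies)) {
        s <- pl$starts[ci]
        substr(g, s, s + fam$length - 1L) <- unit
        repeats[[base::length(repeats) + 1L]] <- data.frame(
          family = paste0("rep", fi), copy = ci,
          start = s - 1L, end = s + fam$length - 1L)
      }
    }
    genes <- list(); transcripts <- character(0)
    for (gi in seq_len(n_genes)) {
      ne <- resample(seq(n_exon_range[1], n_exon_range[2]))
      el <- resample(seq(exon_range[1], exon_range[2]), ne, replace = TRUE)
      il <- if (ne > 1)
        resample(seq(intron_range[1], intron_range[2]), ne - 1L,
                 replace = TRUE)
      else integer(0)
      span <- sum(el) + sum(il)
      pl <- place_blocks(length, span, occupied)
      occupied <- pl$occupied
      s <- pl$starts[1]
      offs <- s
      exon_bounds <- matrix(0L, ne, 2)
      for (e in seq_len(ne)) {
        exon_bounds[e, ] <- c(offs, offs + el[e] - 1L)
        genes[[base::length(genes) + 1L]] <- data.frame(
          gene_id = sprintf("gene%03d", gi), exon = e,
          start = offs - 1L, end = offs + el[e] - 1L)
        offs <- offs + el[e] + if (e < ne) il[e] else 0L
      }
      ## make splice boundaries informative: the first/last intron base must
      ## differ from the adjacent exon continuation, so an exact-matching
      ## read can never coincidentally read through a junction
      if (ne > 1) for (e in seq_len(ne - 1L)) {
        i_start <- exon_bounds[e, 2] + 1L
        i_end <- exon_bounds[e + 1L, 1] - 1L
        avoid1 <- c(substr(g, exon_bounds[e + 1L, 1], exon_bounds[e + 1L, 1]),
                    if (i_start == i_end)
                      substr(g, exon_bounds[e, 2], exon_bounds[e, 2]))
        substr(g, i_start, i_start) <-
          resample(setdiff(c("A", "C", "G", "T"), avoid1))
        avoid2 <- c(substr(g, exon_bounds[e, 2], exon_bounds[e, 2]),
                    if (i_start == i_end) avoid1)
        substr(g, i_end, i_end) <-
          resample(setdiff(c("A", "C", "G", "T"), avoid2))
      }
      tx <- character(ne)
      for (e in seq_len(ne))
        tx[e] <- substr(g, exon_bounds[e, 1], exon_bounds[e, 2])
      transcripts[sprintf("gene%03d", gi)] <- paste(tx, collapse = "")
    }
    mask <- rep(FALSE, length)
    for (r in repeats) mask[(r$start + 1L):r$end] <- TRUE
    structure(list(
      genome = c(chr1 = g),
      repeats = if (base::length(repeats)) do.call(rbind, repeats)
                else data.frame(family = character(0), copy = integer(0),
                                start = integer(0), end = integer(0)),
      mask = mask,
      genes = if (base::length(genes)) do.call(rbind, genes)
              else data.frame(gene_id = character(0), exon = integer(0),
                              start = integer(0), end = integer(0)),
      transcripts = transcripts,
      seed = seed), class = "genome_truth")
  })
}

#' Simulate error-free paired-end reads
#'
#' Draws fragments uniformly from the reference with insert lengths
#' Normal(`insert_mean`, `insert_sd`) truncated to at least `2 * read_len`
#' and at most the sequence length, and emits exact, error-free FR mate
#' pairs. Each pair carries its source record (sequence, fragment interval,
#' mate-1 strand) as ground truth. Deterministic given `seed`.
#'
#' @param ref reference sequences (named character vector, `DNAStringSet`
#'   or FASTA path).
#' @param n_pairs number of pairs.
#' @param read_len mate length (default 150).
#' @param insert_mean,insert_sd insert-length model (default 400, 25).
#' @param seed RNG seed.
#' @return data.frame: `pair_id`, `mate1`, `mate2`, `seq_id`, `frag_start`,
#'   `frag_end` (0-based half-open), `mate1_strand`.
#' @export
simulate_perfect_read_pairs <- function(ref, n_pairs, read_len = 150L,
                                        insert_mean = 400L, insert_sd = 25L,
                                        seed = 1L) {
  ref <- as_reference(ref)
  lens <- nchar(ref)
  usable <- lens >= 2L * read_len
  if (!any(usable)) stop("no reference sequence can hold a fragment")
  with_seed(seed, {
    ins <- pmax(2L * read_len, as.integer(round(rnorm(n_pairs, insert_mean,
                                                      insert_sd))))
    sids <- sample(names(ref)[usable], n_pairs, replace = TRUE,
                   prob = lens[usable])
    ins <- pmin(ins, lens[sids])
    start0 <- vapply(seq_len(n_pairs), function(i)
      sample.int(lens[sids[i]] - ins[i] + 1L, 1L) - 1L, integer(1))
    frag <- substring(ref[sids], start0 + 1L, start0 + ins)
    left <- substring(frag, 1L, read_len)
    right <- revcomp(substring(frag, ins - read_len + 1L, ins))
    flip <- runif(n_pairs) < 0.5
    data.frame(
      pair_id = sprintf("pair%06d", seq_len(n_pairs)),
      mate1 = ifelse(flip, right, left),
      mate2 = ifelse(flip, left, right),
      seq_id = sids,
      frag_start = start0,
      frag_end = start0 + ins,
      mate1_strand = ifelse(flip, "-", "+"),
      stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Write read pairs to a pair of FASTQ files
#'
#' UMIs, if present in a `umi` column, are appended to the read name after
#' a colon. Base qualities are uniform `I` (Q40): the simulators are
#' error-free by construction.
#'
#' @param pairs data.frame with `pair_id`, `mate1`, `mate2`.
#' @param path1,path2 output FASTQ paths for mate 1 / mate 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  nm <- pairs$pair_id
  if (!is.null(pairs$umi)) nm <- paste(nm, pairs$umi, sep = ":")
  for (side in 1:2) {
    seqs <- if (side == 1) pairs$mate1 else pairs$mate2
    lines <- as.vector(rbind(paste0("@", nm, "/", side), seqs, "+",
                             strrep("I", nchar(seqs))))
    writeLines(lines, if (side == 1) path1 else path2)
  }
  invisible(c(path1, path2))
}

#' Simulate UMI-tagged capture reads for one sample
#'
#' Emulates single-primer capture: for each probe, a number of original DNA
#' fragments (Poisson with mean `mean_fragments * efficiency`) is captured,
#' each tagged with a random UMI of `umi_len` bases; PCR then re-reads each
#' fragment `1 + Poisson(dup_rate)` times. Reads start at the probe's 3' end
#' and extend `read_len` bases into the target, so all reads of one probe
#' share a start coordinate and duplicates are distinguishable only by UMI.
#' The truth table records fragment identity of every read.
#'
#' @param panel a probe manifest (data.frame from [emit_probe_manifest()]),
#'   needing columns `probe_id`, `seq_id`, `start`, `end`, `strand`.
#' @param genome reference the probes live on.
#' @param efficiency per-probe capture efficiency in `[0,1]` (scalar or
#'   vector over probes).
#' @param mean_fragments mean original fragments per fully-efficient probe.
#' @param dup_rate mean number of extra PCR copies per fragment (0 = no
#'   duplicates).
#' @param umi_len UMI length in bases (default 6).
#' @param read_len read length into the target (default 100).
#' @param seed RNG seed.
#' @return list of class `capture_sim` with `reads` (data.frame: read_id,
#'   probe_id, fragment_id, umi, seq_id, start, strand, baseq, len) and
#'   `fragments` (truth: fragment_id, probe_id, umi, n_reads).
#' @export
simulate_capture_reads <- function(panel, genome, efficiency = 1,
                                   mean_fragments = 20, dup_rate = 0.5,
                                   umi_len = 6L, read_len = 100L, seed = 1L) {
  genome <- as_reference(genome)
  stopifnot(umi_len >= 1)
  np <- nrow(panel)
  eff <- rep_len(efficiency, np)
  with_seed(seed, {
    n_frag <- rpois(np, mean_fragments * eff)
    frag_rows <- rep(seq_len(np), n_frag)
    nf <- length(frag_rows)
    if (nf == 0)
      return(structure(list(
        reads = data.frame(read_id = character(0), probe_id = character(0),
                           fragment_id = character(0), umi = character(0),
                           seq_id = character(0), start = integer(0),
                           strand = character(0), baseq = numeric(0),
                           len = integer(0)),
        fragments = data.frame(fragment_id = character(0),
                               probe_id = character(0), umi = character(0),
                               n_reads = integer(0))), class = "capture_sim"))
    umis <- vapply(seq_len(nf), function(i)
      paste(sample(c("A", "C", "G", "T"), umi_len, replace = TRUE),
            collapse = ""), character(1))
    n_reads <- 1L + rpois(nf, dup_rate)
    frag_id <- sprintf("frag%06d", seq_len(nf))
    ## read start: + probe reads [end, end+read_len); - probe reads
    ## [start-read_len, start) on the minus strand
    p_start <- ifelse(panel$strand[frag_rows] == "+",
                      panel$end[frag_rows],
                      panel$start[frag_rows] - read_len)
    read_rows <- rep(seq_len(nf), n_reads)
    reads <- data.frame(
      read_id = sprintf("read%07d", seq_along(read_rows)),
      probe_id = panel$probe_id[frag_rows][read_rows],
      fragment_id = frag_id[read_rows],
      umi = umis[read_rows],
      seq_id = panel$seq_id[frag_rows][read_rows],
      start = as.integer(p_start[read_rows]),
      strand = panel$strand[frag_rows][read_rows],
      baseq = round(runif(length(read_rows), 30, 40), 2),
      len = read_len,
      stringsAsFactors = FALSE)
    structure(list(
      reads = reads,
      fragments = data.frame(fragment_id = frag_id,
                             probe_id = panel$probe_id[frag_rows],
                             umi = umis, n_reads = n_reads,
                             stringsAsFactors = FALSE)),
      class = "capture_sim")
  })
}
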