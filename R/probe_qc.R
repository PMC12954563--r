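# Probe-level quality control: depth at target positions, working-probe
# classification (>= min_depth in >= min_frac of samples), size of the
# captured genome, and cross-species probe transferability.

#' Depth at target positions, per probe and sample
#'
#' Counts deduplicated reads overlapping each probe's target position.
#'
#' @param reads_by_sample named list (one element per sample) of aligned
#'   read data.frames with `seq_id`, `start`, `len`.
#' @param panel probe manifest with `probe_id`, `seq_id`, `target_pos`.
#' @return integer matrix probes x samples, with probe ids as row names.
#' @export
depth_at_targets <- function(reads_by_sample, panel) {
  stopifnot(length(reads_by_sample) > 0, !is.null(names(reads_by_sample)))
  m <- matrix(0L, nrow(panel), length(reads_by_sample),
              dimnames = list(panel$probe_id, names(reads_by_sample)))
  for (s in names(reads_by_sample)) {
    r <- reads_by_sample[[s]]
    if (nrow(r) == 0) {
      warning("sample ", s, " has zero reads")
      next
    }
    for (i in seq_len(nrow(panel))) {
      tp <- panel$target_pos[i]
      m[i, s] <- sum(r$seq_id == panel$seq_id[i] &
                       r$start <= tp & tp < r$start + r$len)
    }
  }
  m
}

#' Classify working probes
#'
#' A probe is working when at least `min_frac` of the samples reach depth
#' `min_depth` at its target position (both bounds inclusive).
#'
#' @param depth matrix from [depth_at_targets()].
#' @param panel probe manifest (for the per-type/per-origin summary);
#'   optional.
#' @param min_depth minimum depth (default 6).
#' @param min_frac minimum fraction of samples (default 0.5).
#' @return list with `status` (data.frame probe_id, working,
#'   frac_samples_ge_min, mean_depth_working_samples) and `summary`
#'   (counts by site_type and origin_species when `panel` given).
#' @export
working_probes <- function(depth, panel = NULL, min_depth = 6L,
                           min_frac = 0.5) {
  stopifnot(nrow(depth) > 0)
  frac <- rowMeans(depth >= min_depth)
  mean_dp <- vapply(seq_len(nrow(depth)), function(i) {
    v <- depth[i, depth[i, ] >= min_depth]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  status <- data.frame(probe_id = rownames(depth),
                       working = frac >= min_frac,
                       frac_samples_ge_min = frac,
                       mean_depth_working_samples = mean_dp,
                       stringsAsFactors = FALSE, row.names = NULL)
  summary <- NULL
  if (!is.null(panel)) {
    m <- match(status$probe_id, panel$probe_id)
    summary <- as.data.frame(table(
      site_type = panel$site_type[m],
      origin_species = panel$origin_species[m],
      working = status$working))
  }
  list(status = status, summary = summary)
}

## per-position coverage of one sample over one sequence (difference array)
coverage_vector <- function(reads, seq_len) {
  d <- integer(seq_len + 1L)
  s <- pmax(reads$start, 0L) + 1L
  e <- pmin(reads$start + reads$len, seq_len)
  ok <- s <= e
  for (i in which(ok)) {
    d[s[i]] <- d[s[i]] + 1L
    d[e[i] + 1L] <- d[e[i] + 1L] - 1L
  }
  cumsum(d[seq_len(seq_len)])
}

#' Total captured bases and captured intervals
#'
#' A genome position is captured when its coverage is at least `min_depth`
#' in at least `min_frac` of the samples. Returns the captured-base count
#' and the merged intervals as a BED-like data.frame.
#'
#' @param reads_by_sample named list of aligned read data.frames
#'   (`seq_id`, `start`, `len`).
#' @param seq_lengths named integer vector of reference sequence lengths.
#' @param min_depth,min_frac criterion (defaults 6, 0.5).
#' @return list with `total_bases` and `bed` (seq_id, start, end).
#' @export
captured_bases <- function(reads_by_sample, seq_lengths, min_depth = 6L,
                           min_frac = 0.5) {
  n_samp <- length(reads_by_sample)
  beds <- list(); total <- 0L
  for (sid in names(seq_lengths)) {
    L <- seq_lengths[[sid]]
    n_ok <- integer(L)
    for (s in names(reads_by_sample)) {
      r <- reads_by_sample[[s]]
      r <- r[r$seq_id == sid, , drop = FALSE]
      cov <- if (nrow(r) == 0) integer(L) else coverage_vector(r, L)
      n_ok <- n_ok + (cov >= min_depth)
    }
    hit <- n_ok / n_samp >= min_frac
    total <- total + sum(hit)
    if (any(hit)) {
      r <- rle(hit)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values
      beds[[length(beds) + 1L]] <- data.frame(
        seq_id = sid, start = starts[keep] - 1L, end = ends[keep],
        stringsAsFactors = FALSE)
    }
  }
  list(total_bases = total,
       bed = if (length(beds)) do.call(rbind, beds)
             else data.frame(seq_id = character(0), start = integer(0),
                             end = integer(0)))
}

#' Cross-species probe transferability table
#'
#' Cross-tabulates working probes by the species they were originally
#' designed for, across several genotyping runs sharing one panel.
#'
#' @param status_by_run named list of [working_probes()] results, one per
#'   genotyped sample set.
#' @param panel the shared probe manifest.
#' @return data.frame: rows = runs, columns = origin species, cells =
#'   working-probe counts, plus a `total` column.
#' @export
transferability_summary <- function(status_by_run, panel) {
  origins <- sort(unique(panel$origin_species))
  rows <- lapply(names(status_by_run), function(run) {
    st <- status_by_run[[run]]$status
    if (!identical(sort(st$probe_id), sort(panel$probe_id)))
      stop("run ", run, " does not share the panel")
    m <- match(st$probe_id, panel$probe_id)
    counts <- vapply(origins, function(o)
      sum(st$working & panel$origin_species[m] == o), integer(1))
    data.frame(run = run, t(counts), total = sum(st$working),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("run", origins, "total")
  out
}
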