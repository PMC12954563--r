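# depth at targets, working-probe classification, captured bases,
# transferability

toy_panel <- data.frame(probe_id = c("p1", "p2"), seq_id = "chr1",
                        start = c(60L, 460L), end = c(100L, 500L),
                        strand = "+", target_pos = c(100L, 500L),
                        site_type = c("random", "known"),
                        origin_species = c("abies", "picea"),
                        stringsAsFactors = FALSE)

toy_reads <- function(n1, n2, len = 100L) {
  mk <- function(n, start0) {
    if (n == 0) return(data.frame(read_id = character(0), seq_id = character(0),
                                  start = integer(0), len = integer(0)))
    data.frame(read_id = sprintf("r%d_%d", start0, seq_len(n)),
               seq_id = "chr1", start = start0, len = len,
               stringsAsFactors = FALSE)
  }
  rbind(mk(n1, 100L), mk(n2, 500L))
}

test_that("depth at targets counts overlapping reads per sample", {
  rs <- list(sA = toy_reads(7, 0), sB = toy_reads(2, 3))
  m <- depth_at_targets(rs, toy_panel)
  expect_equal(m["p1", "sA"], 7L)
  expect_equal(m["p2", "sA"], 0L)
  expect_equal(m["p2", "sB"], 3L)
  ## zero-read sample warns and yields a zero column
  rs$sC <- toy_reads(0, 0)
  expect_warning(m2 <- depth_at_targets(rs, toy_panel), "zero reads")
  expect_true(all(m2[, "sC"] == 0L))
})

test_that("depth equals the brute-force overlap count on random reads", {
  set.seed(801)
  reads <- data.frame(read_id = sprintf("r%03d", 1:100),
                      seq_id = sample(c("chr1", "chr2"), 100, TRUE),
                      start = sample(0:900, 100, TRUE), len = 100L,
                      stringsAsFactors = FALSE)
  panel <- data.frame(probe_id = sprintf("p%d", 1:5),
                      seq_id = c("chr1", "chr1", "chr2", "chr2", "chr1"),
                      target_pos = c(50L, 500L, 250L, 888L, 999L))
  m <- depth_at_targets(list(s = reads), panel)
  for (i in 1:5)
    expect_equal(m[i, "s"],
                 naive_depth(reads, panel$seq_id[i], panel$target_pos[i]))
})

test_that("working classification uses inclusive bounds", {
  depth <- rbind(p1 = c(rep(6L, 5), rep(0L, 5)),   # 5/10 at >= 6: working
                 p2 = rep(5L, 10),                 # never reaches 6
                 p3 = c(rep(6L, 4), rep(0L, 6)))   # 4/10: not working
  colnames(depth) <- sprintf("s%02d", 1:10)
  wp <- working_probes(depth)
  expect_equal(wp$status$working, c(TRUE, FALSE, FALSE))
  expect_equal(wp$status$frac_samples_ge_min, c(0.5, 0, 0.4))
})

test_that("raising thresholds never increases working counts or captured bases", {
  set.seed(802)
  depth <- matrix(rpois(200, 8), 20, 10,
                  dimnames = list(sprintf("p%02d", 1:20), NULL))
  n1 <- sum(working_probes(depth, min_depth = 6)$status$working)
  n2 <- sum(working_probes(depth, min_depth = 10)$status$working)
  n3 <- sum(working_probes(depth, min_depth = 6,
                           min_frac = 0.8)$status$working)
  expect_lte(n2, n1)
  expect_lte(n3, n1)
  ## conservation
  wp <- working_probes(depth)
  expect_equal(sum(wp$status$working) + sum(!wp$status$working), 20L)
})

test_that("captured bases match a per-position brute force on a 1 kb toy", {
  set.seed(803)
  rs <- lapply(1:4, function(s) {
    n <- sample(20:40, 1)
    data.frame(read_id = sprintf("s%d_r%d", s, 1:n), seq_id = "chr1",
               start = sample(0:900, n, TRUE), len = 100L,
               stringsAsFactors = FALSE)
  })
  names(rs) <- sprintf("s%d", 1:4)
  cb <- captured_bases(rs, c(chr1 = 1000L), min_depth = 2, min_frac = 0.5)
  ## brute force
  want <- 0L
  for (p in 0:999) {
    n_ok <- sum(vapply(rs, function(r)
      sum(r$start <= p & p < r$start + r$len) >= 2, logical(1)))
    if (n_ok / 4 >= 0.5) want <- want + 1L
  }
  expect_equal(cb$total_bases, want)
  expect_equal(sum(cb$bed$end - cb$bed$start), want)
  ## trivial cases
  one <- list(s1 = data.frame(read_id = "r", seq_id = "chr1", start = 100L,
                              len = 200L))
  cb2 <- captured_bases(one, c(chr1 = 1000L), min_depth = 1, min_frac = 1)
  expect_equal(cb2$total_bases, 200L)
  expect_equal(captured_bases(one, c(chr1 = 1000L), min_depth = 6,
                              min_frac = 0.5)$total_bases, 0L)
})

test_that("transferability table conserves working totals by origin", {
  depthA <- rbind(p1 = rep(10L, 4), p2 = rep(10L, 4))
  depthB <- rbind(p1 = rep(10L, 4), p2 = rep(0L, 4))
  runs <- list(runA = working_probes(depthA),
               runB = working_probes(depthB))
  tab <- transferability_summary(runs, toy_panel)
  expect_equal(tab$total, c(2L, 1L))
  expect_equal(tab$abies + tab$picea, tab$total)
  expect_equal(tab$abies[2], 1L)   # p1 (abies) still works in runB
  bad <- list(runC = list(status = data.frame(probe_id = "px",
                                              working = TRUE)))
  expect_error(transferability_summary(bad, toy_panel), "share the panel")
})
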