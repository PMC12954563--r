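# random-site selection, known-target ingestion, panel assembly, manifest

regions_fixture <- data.frame(seq_id = "chr1", start = 0L, end = 5000L,
                              mean_kmer = 1.0, stringsAsFactors = FALSE)

test_that("random sites honour spacing, determinism and capacity", {
  s <- select_random_sites(regions_fixture, 3, seed = 7, min_spacing = 1000)
  expect_equal(nrow(s), 3L)
  expect_true(all(diff(s$pos) >= 1000))
  expect_identical(s, select_random_sites(regions_fixture, 3, seed = 7,
                                          min_spacing = 1000))
  expect_error(select_random_sites(regions_fixture, 10, seed = 7,
                                   min_spacing = 1000),
               "capacity")
})

test_that("known targets load from VCF and BED with duplicate collapsing", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               sprintf("chr1\t%d\t.\tA\tG\t.\tPASS\t.", c(10, 20, 30, 40, 50))),
             vcf)
  k <- load_known_targets(vcf, "quercus")
  expect_equal(nrow(k), 5L)
  expect_equal(k$pos, c(9L, 19L, 29L, 39L, 49L))  # 0-based
  expect_true(all(k$site_type == "known"))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t105\tx", "chr1\t100\t101\ty", "chr2\t7\t8\tz"),
             bed)
  expect_warning(expect_warning(kb <- load_known_targets(bed, "sp"),
                                "longer than 1"),
                 "duplicated")
  expect_equal(nrow(kb), 2L)
  expect_equal(kb$pos[1], 100L)
})

test_that("panel assembly enforces the minimum random fraction", {
  mk <- function(n, type, chrom = "chr1", offset = 0) {
    data.frame(seq_id = chrom, pos = offset + seq_len(n) * 10L,
               site_type = type, origin_species = "self",
               stringsAsFactors = FALSE)
  }
  ## equal supply: known capped at half
  p <- assemble_panel(mk(600, "random"), mk(600, "known", offset = 1e6),
                      total = 1000, seed = 3)
  expect_equal(sum(p$site_type == "known"), 500L)
  expect_equal(sum(p$site_type == "random"), 500L)
  ## all random is fine
  p2 <- assemble_panel(mk(1000, "random"), NULL, total = 1000, seed = 3)
  expect_true(all(p2$site_type == "random"))
  ## too few random sites for the fraction
  expect_error(assemble_panel(mk(400, "random"),
                              mk(800, "known", offset = 1e6),
                              total = 1000, seed = 3),
               "constraint")
  ## position collisions resolve in favour of known
  r <- mk(600, "random"); k <- mk(300, "known")   # k collides with r[1:300]
  pc <- assemble_panel(r, k, total = 600, seed = 1)
  expect_true(all(pc$site_type[pc$pos %in% k$pos] == "known"))
  expect_equal(sum(pc$site_type == "random"), 300L)
})

test_that("probes slice the reference 5' of the target and round-trip", {
  set.seed(601)
  ref <- c(chr1 = random_dna(1000))
  panel <- data.frame(seq_id = "chr1", pos = c(100L, 10L, 990L),
                      site_type = "random", origin_species = "self",
                      stringsAsFactors = FALSE)
  expect_message(man <- emit_probe_manifest(panel, ref, probe_len = 40,
                                            strand_rule = "plus"),
                 "skipped")
  expect_equal(nrow(man), 2L)   # pos 10 has no 40 bp left flank
  expect_equal(man$start[1], 60L)
  expect_equal(man$end[1], 100L)
  expect_equal(man$sequence[1], substr(ref[[1]], 61, 100))
  ## auto rule places the short-flank target on the minus strand
  man2 <- emit_probe_manifest(panel, ref, probe_len = 40,
                              strand_rule = "auto")
  expect_equal(nrow(man2), 3L)
  m10 <- man2[man2$target_pos == 10L, ]
  expect_equal(m10$strand, "-")
  expect_equal(m10$sequence, revcomp(substr(ref[[1]], 12, 51)))

  tsv <- tempfile(fileext = ".tsv")
  write_panel_manifest(man2, tsv)
  expect_equal(read_panel_manifest(tsv), man2, ignore_attr = TRUE)
})

test_that("panel files are byte-identical across runs with one seed", {
  set.seed(602)
  ref <- c(chr1 = random_dna(20000))
  reg <- data.frame(seq_id = "chr1", start = 100L, end = 19000L,
                    mean_kmer = 1.0)
  out1 <- tempfile(); out2 <- tempfile()
  for (o in c(out1, out2)) {
    s <- select_random_sites(reg, 10, seed = 11, min_spacing = 500)
    p <- assemble_panel(s, NULL, total = 10, seed = 11)
    emit_probe_manifest(p, ref, out_dir = o)
  }
  f1 <- file.path(out1, "panel_manifest.tsv")
  f2 <- file.path(out2, "panel_manifest.tsv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("random probes always fall inside their source regions", {
  set.seed(603)
  ref <- c(chr1 = random_dna(30000))
  reg <- data.frame(seq_id = "chr1", start = c(1000L, 20000L),
                    end = c(5000L, 26000L), mean_kmer = 1.0)
  s <- select_random_sites(reg, 12, seed = 2, min_spacing = 300)
  inside <- vapply(s$pos, function(p)
    any(reg$start <= p & p < reg$end), logical(1))
  expect_true(all(inside))
})
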