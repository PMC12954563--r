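---
title: "spetkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spetkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spetkit)
```

spetkit supports genetic monitoring of natural populations (its motivating
use case is forest-tree conservation units) with single-primer enrichment
(SPET) panels: targeted genotyping assays in which a single probe primes
sequencing into an adjacent region, so each probe genotypes a known target
site plus nearby de novo variants. This vignette documents the models and
estimators the package implements, the choices that were genuinely open,
and what the synthetic-data generators do and do not emulate.

## Panel design from k-mer mappability

Capture probes must avoid repetitive sequence. `build_kmer_index()` counts
every 20-mer of the reference (canonical, i.e. strand-folded, by default:
hybridisation is strand-symmetric; a single-strand mode exists for
comparison with strand-aware counters), and `mappability_track()` writes
the count of the k-mer starting at every position. Positions whose window
contains `N` are undefined: no probe can be designed there, and undefined
positions break candidate regions.

`eligible_regions()` looks for stretches at least 200 positions long whose
mean 20-mer count is strictly below 2 — i.e. regions that are, on average,
close to single-copy. Two refinements are deliberate design choices:

* **Per-position cap** (`pos_cap = 4`): candidate runs may not contain any
  position with count above the cap. Without it, a single high-copy repeat
  spike inside an otherwise unique region would be averaged away and could
  receive a probe.
* **Deterministic splitting**: a candidate run that fails the mean
  criterion is split at its leftmost maximum-count position and both
  halves are re-examined recursively. This removes the repeat-densest
  point first and is fully deterministic, so region lists are reproducible
  byte for byte. The tests verify the whole construction against a naive
  re-implementation on plain vectors.

Random target sites are drawn uniformly without replacement from eligible
regions with a minimum spacing (default 1000 bp — close sites would
capture redundant fragments), and panels are assembled with at least half
random sites (`assemble_panel()` enforces `min_random_frac = 0.5`),
because diversity estimated from pre-ascertained markers alone is biased
(see the last section). Probe geometry is our convention: the probe is the
40 reference bases immediately 5' of the target on the chosen strand, so
extension sequences into the target.

## Transcriptome anchoring without an own-species genome

When only a transcriptome is available, probes must avoid exon–intron
junctions, which are invisible in transcript coordinates. The package
simulates error-free 150 bp read pairs from the transcriptome
(insert ~ Normal(400, 25) truncated at twice the read length, emulating a
typical paired-end library) and places them on the genome of a related
species by exact matching (`map_perfect_reads()`). Exact matching is valid
here precisely because the reads are synthetic and error-free; real-read
alignment is out of scope and is done upstream by a general aligner.

`contiguity_regions()` keeps pairs that are uniquely and properly placed
**and collinear in the strict sense that the genomic fragment span equals
the transcript fragment span**. A gap-threshold rule alone (genomic span
below some bound) would let fragments silently bridge introns shorter
than the slack in the insert distribution; with error-free reads the
span-equality test is exact and costs nothing. Reads that cross a
junction fail full-length exact placement, so junctions always interrupt
coverage; merged covered intervals of at least 200 bp are reported.
Abutting coverage intervals are *not* merged (only overlapping ones),
because two fragments meeting exactly at an uncovered point must not
fabricate contiguity across it.

The genome generator makes splice boundaries informative: the first and
last intron base are forced to differ from the adjacent exon
continuation, so an exact-matching read can never coincidentally read
one or more bases past a junction. Real splice sites are close to this
(the canonical GT..AG intron motif rarely continues the exon), but real
capture data would still show occasional read-through from sequencing
error; the generator does not emulate that, and the junction guarantees
shown by the tests are guarantees about error-free reads only.

## UMI deduplication and probe QC

Capture reads carry a 6 bp unique molecular identifier (UMI) per original
DNA fragment. `dedup()` groups reads by (sequence, read start, strand,
UMI) and keeps the highest-mean-base-quality read per group (ties:
smallest read id, for determinism). Because SPET reads of one probe all
start at the probe's 3' end, fragments of a probe are distinguished by
UMI alone; UMI collisions (two fragments drawing the same 6-mer, ~1/4096
per pair) therefore merge groups and slightly over-remove. The simulator
exposes the collision count so the tests can condition on collision-free
settings; an optional Hamming-distance-1 collapse handles UMI sequencing
errors and is verified against a ball-grouping oracle. The grouping key
ignores the mate's start — the published workflows this mirrors do not
document their key, and this is stated as an assumption.

A probe is **working** when at least 50% of samples reach depth >= 6 at
its target position (both bounds inclusive — "at least"), computed on
deduplicated reads. `captured_bases()` counts genome positions covered
>= 6x in at least half the samples, and `transferability_summary()`
cross-tabulates working probes by the species they were designed for.

## The V0/V1 filter cascade

`filter_cascade()` reproduces a lenient population-genetics filtering
workflow over joint-genotyped variant+invariant calls:

1. **Split**: SNPs, invariant sites (no observed alternate; symbolic
   `<NON_REF>` tolerated), everything else discarded with counts.
2. **Hard site filter**: fail if `QD < 2.0 || MQ < 40.0 ||
   MQRankSum < -12.5` (strict; a missing annotation is uninformative and
   never fails a site — the GATK convention).
3. **HDplot paralog filter**: per site, `H` = heterozygote proportion;
   `A`, `B` = allele reads summed over heterozygotes; `ratio = A/(A+B)`;
   `D = (A-B)/sqrt(A+B)`. A site is kept only if `H <= 0.6`,
   `ratio` in `[0.2, 0.8]` **and** `D` in `[-10, 10]`; the sub-rules are
   combined conjunctively for keeping because each captures an
   independent paralog signature (the source method lists the option
   values without combination logic). With no heterozygote reads only
   the H rule applies. The ratio bound is applied to the per-site
   (pooled) ratio, not per-sample ratios.
4. **Genotype filter**: non-biallelic sites dropped; genotypes with
   `DP < 6` or `GQ < 20` set missing; a locus is kept only if depth is
   *strictly above* 6 in at least half the samples (the workflow's
   wording is "greater than six", distinct from the `DP >= 6` genotype
   rule — both are implemented as written) and the locus minor allele is
   supported by >= 3 reads summed over all samples (a per-sample variant
   of the rule is available via configuration).
5. **Sample missingness**: samples with strictly more than 80% missing
   genotypes are removed — computed over sites that survived the site
   filters, which is why the cascade drops flagged sites before this
   stage (the standalone functions flag without deleting, keeping an
   audit trail).
6. **Invariant filter**: `DP < 6` masked; site kept if depth strictly
   above 6 in at least half the (remaining) samples.
7. **Merge** into a coordinate-sorted V0 with threshold provenance
   recorded; `build_v1()` removes curated samples (outliers, non-clonal
   duplicates). Deciding whether a flagged duplicate is a natural clone
   is curation, not computation: the package only flags.

Every boundary in this cascade (QD 1.9/2.0, MQ 39.9/40.0, MQRankSum
-12.6/-12.5, H 0.6/0.7, ratio 0.2/0.8, D at 10.73, DP 5/6/7, GQ 19/20,
minor reads 2/3, missingness 0.80/0.81, invariant DP 6/7) is exercised by
a 50-site fixture whose outcome was enumerated by hand.

## Diversity and differentiation estimators

* **Hs** (expected heterozygosity) uses the Nei–Chesser unbiased
  estimator per locus and population, `n/(n-1) * (1 - p^2 - q^2 -
  Ho/(2n))`, averaged over populations then loci. Averaging per
  population first matches the convention of the standard hierarchical
  F-statistics packages; the alternative (pooling populations) answers a
  different question and is not offered.
* **FST** is Weir & Cockerham's theta from per-locus variance components
  `a` (among populations), `b` (among individuals within populations),
  `c` (within individuals), combined as a **ratio of sums** over loci —
  never a mean of per-locus ratios, which is biased for loci with small
  denominators. Loci with undefined components (fewer than two
  populations with data) leave both sums. The bootstrap CI resamples
  loci with replacement (1000 draws, percentile interval, seeded).
* **pi** follows the invariant-aware estimator: per site, differing
  pairs `D = n_ref * n_alt` over comparable pairs `C = n(n-1)/2` among
  called allele copies; `pi = sum(D)/sum(C)`. Invariant sites contribute
  `C` with `D = 0`, which is what makes the estimate robust to
  missingness and filtering. Windowed values carry their numerator and
  denominator so aggregation reproduces the global value exactly.
* **Kinship** is the KING-robust estimator
  `phi = (N_Aa,Aa - 2 N_AA,aa) / (N_Aa(i) + N_Aa(j))` over co-called
  loci; duplicates sit at 0.5 and are flagged above `2^(-3/2)` (the
  standard monozygotic cutoff; the source workflow used its tool's
  default without stating a number, so the cutoff is configurable).
* **Species-diagnostic markers**: after merging per-species cohorts and
  filtering (biallelic, DP >= 6, GQ >= 20, call rate >= 0.8 *per
  species* — the stricter reading of "present in at least 80% of
  individuals"), sites whose maximum pairwise absolute allele-frequency
  difference reaches 0.9 (inclusive, with a 1e-9 floating-point guard)
  are reported with their discriminating pairs. The difference is
  unsigned; a signed variant would only change which pair is listed.

## The synthetic-data generators

The generators define the package's study conditions; their defaults are
fixed and the tests run at those defaults.

* `simulate_genome()`: uniform random DNA with exact repeat-family copies
  and multi-exon gene models (exons 400–800 bp, introns 300–1500 bp,
  1–3 exons), with full truth annotations. Real genomes have diverged
  (not exact) repeats, GC structure and nested repeat families; the
  exact-copy model is the right substrate for testing *mappability*
  logic, not repeat biology.
* `simulate_perfect_read_pairs()`: error-free FR pairs, insert
  Normal(400, 25) truncated at 300. No sequencing error, no chimeras, no
  indels — by design, since the anchoring procedure is specified for
  perfect reads.
* `simulate_capture_reads()`: per probe, original fragments ~
  Poisson(mean 20 x efficiency), each with a uniform random 6 bp UMI and
  `1 + Poisson(dup_rate)` PCR copies. No capture-efficiency gradients,
  no strand bias, no UMI sequencing errors (the Hamming-1 collapse is
  tested on constructed cases instead).
* `simulate_population_vcf()`: island model with Balding–Nichols
  population frequencies — at each locus with ancestral frequency `p`,
  population frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) — chosen because
  Weir–Cockerham theta estimates exactly this `F`. Ancestral minor
  allele frequencies are uniform on [0.05, 0.5] by default. Sequencing
  noise: depth ~ negative binomial (mean 40, size 5, matching the depth
  range of typical SPET runs), allele depths binomial with per-read
  error 0.01, genotypes re-called by maximum likelihood from the allele
  depths, GQ as the capped phred gap between the best and second-best
  genotype. Paralog-collapsed loci sum the reads of a latent duplicate
  locus (duplicate allele frequency uniform on 0.2–0.8, so collapsed
  sites are reliably polymorphic — near-fixed duplicates would be
  undetectable by any read-ratio method and are not what the filter is
  specified against). Technical replicates re-emit the called genotypes
  with a configurable flip probability; real replicate discordance is
  depth-dependent rather than uniform, so the replicate model supports
  closed-form concordance checks, not depth-stratified ones. There is
  no linkage disequilibrium and no indel simulation.

Passing tests on these simulations demonstrate estimator correctness
under the stated models — they do not validate behaviour under model
misspecification (diverged repeats, batch effects, allele-specific
capture bias).

## Emulating ascertainment bias

The package contrasts "known/array" markers with randomly discovered
ones (`ascertainment_comparison()`: one-sided rank-sum tests on MAF and
observed heterozygosity, per-class theta, and the relative FST
underestimation `(theta_random - theta_known)/theta_random`). In testing
this, the emulation of array ascertainment matters: conditioning the
known class on *pooled* MAF >= 0.2 inflates MAF and Ho but does **not**
produce FST underestimation in an island model (we measured a slightly
negative ratio), because pooled-common loci are not depleted of
among-population variance. Conditioning on MAF >= 0.2 **in every
population** — which is what a multi-population array discovery panel
effectively does — both inflates diversity and depletes differentiated
loci, yielding a clearly positive underestimation ratio. The tests and
the acceptance script use the per-population form.

## Numerical and determinism notes

* All coordinates are 0-based half-open internally; VCF positions are
  1-based on read/write; BED output is 0-based.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical inputs and seeds give byte-identical
  outputs (region lists, manifests, simulated data).
* `n_hits` for a read pair counts FR-oriented co-placements on one
  sequence with positive insert and no upper insert bound; the insert
  bound (mean ± 4 sd) defines `proper` only. "Unique" means exactly one
  such placement.
* Problem sizes in the test suite (10 kb oracle genomes, 100 kb
  round-trip genome with 10,000 pairs, 2000-locus simulations, 20 FST
  replicates with 1000 bootstraps) were chosen so the full suite
  completes in a few minutes while keeping Monte-Carlo noise well below
  the asserted tolerances.

## Known limitations

* The exact-match mapper is not a general aligner and must not be used
  on real reads.
* VCF support covers the GT/DP/GQ/AD + QD/MQ/MQRankSum subset the
  workflow consumes; arbitrary FORMAT fields are not round-tripped.
* Kinship pairs are computed densely (all pairs); for cohorts of many
  thousands of samples a blocked implementation would be needed.
* The UMI collision rate fixes a floor on dedup accuracy that no
  algorithm can beat; the package reports collisions (from simulation
  truth) rather than pretending to resolve them.
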