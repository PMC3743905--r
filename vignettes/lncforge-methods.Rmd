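---
title: "Identifying and characterizing lncRNAs with lncforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing lncRNAs with lncforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncforge)
```

## The problem

Deep RNA-seq of a tissue yields hundreds of thousands of assembled
transcript models, most of which are fragments, noise, or isoforms of known
genes. `lncforge` implements the post-assembly half of a long non-coding
RNA (lncRNA) discovery pipeline: a staged filter cascade that reduces
assembled models to credible lncRNA candidates, a genomic classifier that
partitions candidates by their relation to reference gene models, a set of
multi-omic characterizations (ESTs, repeats, ribosome footprints, CAGE,
conservation, chromatin marks), exclusion-aware permutation tests with
empirical p-values, gene-list construction for functional enrichment, and a
percentile-threshold caller for RNAi knockdown microarray screens.

Everything upstream of the assembled models — read alignment, transcript
assembly, coding-potential scoring, peak calling — is out of scope; those
results enter as inputs (GTF, a transcript side table, BED tracks).

## The filter cascade

Stages are applied in a fixed order, and every removed transcript is
attributed to exactly one stage:

1. **Redundancy merge.** Models with identical exon chains are collapsed;
   per-stage expression is max-merged and stage support unioned. The
   lexicographically smallest id is kept so output ids are stable.
2. **Length.** Small RNAs are excluded by keeping only models whose total
   exonic length is *strictly greater* than 200 nt.
3. **Single-exon support.** Single-exon models are noisy assembly output;
   they are kept only when assembled independently in at least two
   developmental stages. The rule reads assembly support
   (`stage_presence`), not expression, because it precedes the expression
   filter in the cascade.
4. **Expression.** A transcript is kept when its maximum RPKM over stages
   is at least the noise threshold (default 0.3 RPKM; values below it in
   every stage are treated as transcriptional noise). Max-over-stages is
   the least destructive aggregate and matches per-stage assembly support.
   Alternatively the cutoff can be derived from the average read mapping
   rate: with a fraction $m$ of reads mapping, the bottom $100(1-m)$
   percent of the pooled expression values are treated as noise, and the
   nearest-rank percentile at that level becomes the cutoff ($m = 0.84$
   gives the 16th percentile). Nearest-rank is used because it is exact,
   monotone, and matches a sort-and-index oracle; the percentile method is
   configurable.
5. **Class codes.** Only assembler class codes u (novel intergenic),
   i (intronic), j (novel isoform) and x (exonic antisense) are retained;
   other codes mark likely artifacts or run-on fragments. A missing code
   is reported and removed.
6. **Coding potential.** Candidates need a coding-potential score strictly
   below −1; a missing score fails the filter (conservative: an unscored
   model cannot be certified non-coding).
7. **Classification** (below) — no removals, but categories are needed by
   the next stage.
8. **Coding proximity.** Intergenic candidates closer than 1,000 bp to a
   coding-gene span are removed, guarding against unannotated UTR
   extensions and promoter-proximal divergent transcription.

The cascade is monotone (each stage's output is a subset of its input),
idempotent, and invariant to input order; the audit counts telescope.

## Genomic classification

Candidates are partitioned with a fixed rule precedence:
intergenic (span overlaps no reference gene span, coding or noncoding) →
intronic (span entirely inside a single intron of a protein-coding gene,
either orientation) → cis-antisense (≥ 1 bp exon–exon overlap with a
reference exon on the opposite strand) → alternatively spliced (the
residual). The precedence makes the categories mutually exclusive without
any further tie-breaking; containment deliberately beats antisense, so an
antisense model fully inside an intron is intronic. Introns are taken from
the union-exon gene model to avoid isoform-dependent ambiguity, and
unstranded candidates can never be cis-antisense (single-end libraries
carry no strand). Whether "intergenic" should also be clear of noncoding
reference genes is genuinely open; the default says yes (intergenic means
clear of *all* annotation) and a toggle provides the alternative.

## Characterization

* **Annotation stacking**: each candidate takes the label of the
  highest-priority track (ESTs > mRNAs > NONCODE > TransMap) covering at
  least 10% of its exonic length, else "Unannotated". The 10% fraction is
  measured over the transcript's exonic length by default (the natural
  reading); a toggle measures it over the annotation interval instead.
* **EST / ribosome flags**: a single shared nucleotide with the exon chain
  counts as support.
* **Repeats**: flagged when repeat bases exceed 5% of exonic length
  (strictly).
* **CAGE**: the distance from the putative TSS to the nearest CAGE cluster
  is the absolute base-coordinate difference (0 inside a cluster).
  Matching is strand-agnostic by default because the emulated libraries
  are unstranded.
* **Conservation**: the score of the concatenated exonic region, with
  uncovered bases scoring 0. Both the mean (default) and the per-base
  median are implemented: the source material describes the method as an
  average but labels one figure as median, so both readings are available
  and the discrepancy is noted here rather than hidden.
* **Chromatin marks**: the default criterion flags a candidate when any
  peak of a mark falls in the half-open window [TSS − 5 kb, TSS + 5 kb);
  the alternative body-fraction criterion (peak bases ≥ 50% of exonic
  length) is available because the two readings are conflated in the
  narrative this pipeline emulates. The window criterion is monotone in
  the window size.
* **Expression-matched sampling**: comparisons across transcript classes
  use samples drawn with replacement from quantile bins of
  $\log_{10}(\mathrm{RPKM} + 10^{-3})$ (10 bins by default), proportional
  to the reference bin masses. The pseudo-count admits zeros; an empty
  pool bin falls back to its nearest non-empty neighbour and says so.

## Permutation tests

The null model re-places each candidate span (length preserved, exon
structure not — mirroring a bedtools-style whole-span shuffle) uniformly
over all genomic start positions at which it fits entirely inside a
chromosome and touches zero excluded bases (repeat-masked regions plus
annotated gene spans for the intergenic null; only introns for the
intronic null, where an intron is chosen with probability proportional to
its count of eligible starts). Placement enumerates the valid start set
exactly instead of rejection sampling: it satisfies the same uniformity
contract, costs a deterministic amount of work, and fails immediately and
informatively when no placement exists.

The empirical p-value is the plain exceedance fraction
$\#\{T_\mathrm{perm} \ge T_\mathrm{obs}\}/N$; a zero is reported as
"< 1/N". An add-one variant is available for conservative reporting but is
not the default, since the plain fraction is what a "fewer than 5 in
10,000" significance rule counts. The CAGE-distance comparison contrasts
the observed TSS-to-cluster distances with those of a single permuted
replicate via the Mann–Whitney U test (exact enumeration when the smaller
sample has at most 8 values and no ties; tie-corrected normal
approximation otherwise).

`null_calibration_pvalues()` packages the calibration experiment: a world
with no planted signal in which the "observed" candidate set is drawn by
the same shuffler that builds the null, making the empirical p-value
exchangeable-uniform by construction. The default sizes (1,000 spans,
clusters whose 100 kb zones cover about half of the placeable genome) were
chosen so the discrete overlap-count statistic has enough spread that ties
— which make the plain-fraction p conservative — stay rare; with few
hundred spans the conservativeness is measurable and a type-I check at
$\alpha = 0.05$ can drift below its binomial band.

## Knockdown screen

Microarray probes are assigned to candidates when exonic bases cover more
than 99% of the probe; probes matching several candidates map to all of
them and are flagged ambiguous. Per probe, the 5th and 95th nearest-rank
percentiles across the control profiles bound the normal range
("ranked overall control expression" is read per probe, not as one pooled
global ranking, because per-probe dynamic ranges on arrays differ by
orders of magnitude; the pooled variant sits behind a flag). A knockdown
calls a lncRNA up (down) when, under the default `both` rule, every
replicate of a mapped probe exceeds (undershoots) its threshold — the
replicate-agreement policy is genuinely open, so a `mean` rule is also
implemented. Conflicting probes within one lncRNA cancel to no call.
The per-target null permutes the probe-to-lncRNA label assignment; this
comparator is an interpretation (the emulated screen does not define its
"permutated" distribution) and is documented as such.

## Gene lists and enrichment

For functional readout, intergenic candidates contribute their nearest
coding gene when closer than 500 kb, intronic candidates their host gene
unless the containing intron exceeds 100 kb, and cis-antisense candidates
their opposite-strand partners; all lists are deduplicated. The
term-enrichment step is a generic hypergeometric upper-tail test with
Benjamini–Hochberg adjustment over a user-supplied term-to-gene map; it
stands in for curated web services whose database contents are versioned
and unreproducible. The default background is the supplied coding gene
set, which is a documented divergence from service-internal backgrounds.

## The synthetic fixture

`generate_fixture()` builds the study conditions the tests run under.
Every property is planted *by construction*, never sampled and then
re-measured, so the manifest is an exact oracle:

* 4 chromosomes of 12 Mb; 700 coding and 100 noncoding reference genes
  with realistic exon/intron geometry (first introns of at least 6 kb keep
  promoter-proximal peak planting unambiguous).
* 2,000 candidate models partitioned into per-stage planted failures
  (100 duplicates, 150 short, 150 unsupported single-exon, 250
  sub-threshold expression, 150 bad class codes, 200 coding-potential
  failures, 100 coding-proximal intergenic) and 900 survivors
  (200 intergenic, 300 intronic, 100 cis-antisense, 300 alternatively
  spliced), each violating exactly the criterion of its destined stage.
* Expression is log-normal with the lncRNA median one tenth of the coding
  median (3 vs 30 RPKM, sdlog 1); coding-potential scores are drawn from
  truncated normals on either side of the −1 cutoff.
* Annotation tracks realize the planted rates exactly: 82% spliced-EST
  support, 30% unspliced-EST, 40% repeat (>5% of exonic length), 5%
  ribosome, 60% CAGE-at-TSS, and per-mark TSS rates led by H3K4me3 at
  50%. Items are laid out with ≥ 6 kb separation so a planted TSS-window
  peak can never leak into a neighbour's window.
* The last chromosome is an imprinted zone: 10 clusters (a desk-scale
  stand-in for the 216 nonredundant imprinted loci of the emulated study,
  which would saturate a 48 Mb genome with 100 kb windows), with a quarter
  of the intergenic survivors planted within 100 kb — the remaining
  survivors live on other chromosomes, making the proximity flag exact.
* Background unspliced ESTs are scattered outside all candidate and gene
  zones at a density computed analytically to give a ~10% null hit rate
  for a shuffled intergenic span, so the planted 30% support is roughly a
  three-fold enrichment.

`generate_kd_experiment()` mirrors the emulated screen: 55 control
profiles, 40 protein + 226 lncRNA targets with two replicates (532
profiles), 187 probes mapped onto candidate exons (180 lncRNAs, seven with
two probes) plus 13 unmapped probes, and four planted regulators with
81/2, 3/64, 62/2 and 0/47 up/down effects shifted one unit beyond the
percentile band. Unaffected KD values copy the per-probe control median —
strictly inside the band whenever the band is non-degenerate — so with
replicate noise 0 the caller recovers the planted sets exactly; the
default replicate noise of 0.2 (log2 units) leaves recovery within a few
percent.

What the fixture does **not** emulate: mapping and assembly artifacts,
fragmented or chimeric models, isoform complexity within loci, sequencing
depth effects on RPKM, array normalization issues, or correlated noise
across profiles. Passing tests therefore certify the *logic* of the
pipeline — thresholds, conventions, set algebra, null construction — not
its robustness to upstream data pathologies.

## Numerical and design choices

* Internal coordinates are GenomicRanges-native (1-based, closed);
  BED (0-based half-open) and GTF (1-based closed) are converted at I/O by
  rtracklayer. All boundary semantics (book-ended intervals at distance 0,
  strict thresholds) are asserted in the converted system.
* Chromosome names match by exact string equality; there is no "chr"
  aliasing.
* The TSS of an unstranded transcript defaults to its span start, with a
  warning.
* Distances are span-to-span; whether gene-proximity rules should instead
  be TSS-to-feature is unknowable from the emulated description, so the
  span convention is fixed and stated.
* Standard statistics are delegated: `wilcox.test` (rank-sum),
  `phyper` (hypergeometric tails), `p.adjust` (BH). The test suite checks
  them against independent enumeration oracles rather than re-deriving
  them.
* Problem sizes in the packaged tests (2,000-candidate fixture, 10,000
  placements for shuffle validation, 200 calibration replicates at 500
  permutations, 1,000 permutations for planted-effect recovery) keep the
  full suite within a few minutes while leaving every check
  statistically meaningful.

## Known limitations

* Whole-span shuffling ignores exon structure; an exon-aware null is out
  of scope.
* The classifier assigns one category per transcript; real loci can admit
  several readings, and the fixed precedence is a modelling choice.
* The enrichment stand-in does not reproduce any curated annotation
  content; its results depend entirely on the supplied term map.
* The KD caller assumes pre-normalized, finite expression matrices;
  normalization and background correction are upstream concerns.
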