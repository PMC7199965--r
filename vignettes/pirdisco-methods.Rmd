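---
title: "Methods: identifying and characterizing putative piRNAs with pirdisco"
author: "pirdisco authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing putative piRNAs with pirdisco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

PIWI-interacting RNAs (piRNAs) are 24-34 nt small RNAs that, outside the
germline, appear at low abundance in somatic tissues such as differentiating
cardiac cells. Identifying them in bulk small RNA-seq is dominated by two
confounders: the far more abundant miRNA fraction (20-23 nt) and degradation
fragments of structural non-coding RNAs (tRNA, rRNA, snoRNA) that happen to
fall in the piRNA length range. `pirdisco` implements the standard
computational defense, starting from *aligned* reads (adapter trimming and
genome alignment are upstream, out of scope):

1. **Length filter.** Keep reads with 24 <= RL <= 34 (the strict bounds
   23 < RL < 35 stated as inclusive integers). Exposed as
   `min_len`/`max_len`.
2. **Strand-specific ncRNA subtraction.** Remove any read with a
   same-strand overlap (>= 1 bp by default; a minimum overlap fraction is
   configurable) with an annotated non-piRNA ncRNA. Opposite-strand
   overlap never removes a read, and piRNA annotations never subtract.
3. **Quantification.** Surviving reads are counted against a piRNA locus
   catalog; a read overlapping several loci is assigned to the largest
   same-strand overlap, ties broken by lexicographically smallest locus id
   (a deterministic variant of union counting; an `ambiguous_drop` mode
   reproduces the stricter behavior of discarding multi-locus reads).
4. **Expressed sets.** A locus is called expressed in a stage when its mean
   *raw* count across that stage's replicates is >= 3; the union over
   stages is the identified catalog. The threshold is applied to raw
   counts, not CPM, because replicate means of raw counts are what the
   rule was defined on; a pooled-mean variant is also reported.

All interval logic is strand-aware and lives on `GenomicRanges` containers;
coordinates are 1-based closed internally (the Bioconductor convention) and
converted losslessly at the BED/SAM/GTF boundaries by `rtracklayer`,
`Rsamtools` and `GenomicAlignments`. Multi-mapped reads are handled by
keeping primary alignments only: whether a multi-mapper should count once
or per alignment is not decidable downstream, and the primary-only set is
the reproducible choice.

## Differential expression

Counts are normalized by **median-of-ratios size factors** (the factor for
sample *j* is the median over all-nonzero features of
count~ij~ / geometric mean~i~). Per feature, the dispersion
&alpha; of the negative-binomial variance model
var = &mu; + &alpha;&mu;&sup2; is estimated by method of moments from the
**pooled within-condition variance** (df-weighted across the two conditions
of the contrast). Pooling the *data* across conditions would conflate the
treatment effect with biological dispersion and makes the test measurably
conservative, so the within-condition form is used. The effect is

log2FC = log2((mean~B~ + &epsilon;) / (mean~A~ + &epsilon;)),
&epsilon; = 0.5,

tested with a Wald statistic whose standard error follows the NB variance
model through the delta method and is referred to a *t* distribution with
n~A~ + n~B~ - 2 degrees of freedom. The *t* reference (rather than the
normal) absorbs the estimation noise of the moment dispersion at
three-replicate design sizes; in null simulations (2,000 features,
&mu; = 50, &alpha; = 0.05, 3 vs 3) the realized type-I error at p < 0.05 is
~ 0.035, and with 10% planted four-fold effects the empirical FDR at
BH-adjusted p < 0.1 is far below the nominal level while the mean absolute
log2FC error stays below 0.3. &alpha; = 0 degenerates to Poisson.
Significance uses the dual rule: |log2FC| >= 1 **and** p < 0.05 **and**
BH-adjusted p < 0.1. Features with all-zero counts in both conditions are
reported untested rather than silently dropped.

Two caveats documented deliberately:

* The &epsilon; pseudo-count stabilizes zero means but breaks *exact*
  invariance of log2FC under a common scaling of all columns; the residual
  perturbation is < 0.02 at typical counts and vanishes with depth.
* Median-of-ratios assumes most features are not differentially expressed.
  With >= 20% one-sided planted effects the reference itself shifts and
  log2FC estimates acquire a visible bias; this is a property of the
  normalization family, not of this implementation.

This module re-implements the model family rather than wrapping an
existing package; an installed independent implementation is used in the
test suite as a cross-check oracle (log2FC correlation > 0.97 on simulated
data), never as the computation.

## Soft clustering of temporal trajectories

Replicates are collapsed to stage means of log2(CPM + 1), each feature's
trajectory is z-scored (n-1 denominator; rows with sd < 1e-8 are dropped
and reported), and the standardized trajectories are clustered with
classic **fuzzy c-means**: memberships
u~ik~ = 1 / &Sigma;~j~ (d~ik~/d~ij~)^(2/(m-1)), centers the u^m-weighted
means, iterated until the largest center shift is below 1e-6 (cap 1000
iterations). Defaults are c = 8 clusters and fuzzifier m = 1.15 — a nearly
crisp setting appropriate for well-separated temporal patterns; c is a
parameter, not estimated, and a minimum-centroid-distance diagnostic over
c = 2..12 is provided to justify it. Initialization samples c data rows as
centers; five seeded restarts keep the best objective, making the fit
bit-reproducible under a seed. Features whose distance to a center
underflows are pinned to that center with membership 1. The recorded
objective trace is non-increasing — an invariant the tests assert.

Cluster-to-template matching in the tests uses an exact bitmask dynamic
program (equivalent to the Hungarian algorithm at these sizes) maximizing
total center-template Pearson correlation; no assignment-solver dependency
is needed.

## Biogenesis signatures

* **Base composition / 5'U bias.** Per position from the 5' end, the
  A/C/G/U frequency over reads long enough to reach that position,
  computed on read-strand-oriented sequences (minus-strand SAM records are
  reverse-complemented at ingest). Primary piRNAs carry a 5' uridine
  preference, so `freq(U, 1)` is the headline statistic.
* **Ping-pong signature.** For every opposite-strand read pair on a
  contig, the 5'-5' distance s = q - p + 1 (p = plus-read start, q =
  minus-read end). The histogram h(s), s = 1..20, is computed exactly by
  multiplying 5'-position multiplicities (verified against a quadratic
  all-pairs oracle), and z10 = (h(10) - mean h(s != 10)) / sd h(s != 10)
  quantifies the secondary-biogenesis peak. z10 is reported as undefined
  (not 0) when the off-10 bins have no spread — e.g. single-strand input.
* **Coverage meta-profile.** Same-strand per-base depth over each locus,
  CPM-normalized, rescaled to a 100-point grid oriented 5'&rarr;3' of the
  locus, and averaged over loci.

## Genomic context

Host genes are assigned by >= 1 bp overlap, sense meaning strand equality;
a piRNA may host-map to several overlapping genes. Enrichment of
gene-origin is tested against an interval-shuffling null: each of 1500
shuffles relocates every piRNA to a uniform random start on its *original*
contig, preserving length and strand (contig preservation keeps the
chromosome composition of the catalog; whole-genome placement would
confound it), and the count of piRNAs intersecting protein-coding / lncRNA
genes in sense / antisense is recomputed. Reported per cell:
log2 fold enrichment = log2(observed / null mean) and the empirical
p-value (#{null >= observed} + 1)/(n~shuffles~ + 1); the +1 correction
avoids zero p at finite shuffle counts. An observed count of zero yields a
-Inf sentinel with p = 1. Host-gene percent coverage uses the union of
read intervals (duplicates never double-count) intersected with the gene
body; piRNAs-per-gene tallies count sense assignments only, binned
1/2/3/>=4. Gene-set overrepresentation is the standard upper-tail
hypergeometric test with BH adjustment, taking user-supplied gene sets and
an explicit universe (no ontology semantics).

## The synthetic data generator

Every stage of the pipeline is testable without downloads because the
package ships a generator that emulates the *structure* of the real inputs
(it is first-class, tested code, not a fixture):

* a toy genome (defaults: chr1 300 kb, chr2 200 kb, and a 16 kb
  mitochondria-like `chrM`);
* three annotation layers mirroring the real databases — a piRNA locus
  catalog, a nuclear ncRNA exclusion set (tRNA/rRNA/snoRNA/miRNA), and
  gene models with biotypes. The chrM tRNA/rRNA genes appear in the gene
  models but are **deliberately absent** from the ncRNA layer, recreating
  the annotation gap through which mitochondrial ncRNA fragments leak into
  piRNA catalogs — the pipeline's tests assert both the leak and its
  disappearance when the gap is closed;
* reads for 3 stages (PSC, MPC, CPC) x 3 replicates. Per locus and
  sample, counts are negative binomial (variance &mu; + &alpha;&mu;&sup2;,
  one global &alpha; = 0.05, matching the DE model family) with mean =
  baseline x one of eight multiplicative stage templates (monotone
  rise/fall, mid peak/dip, late and early shifts). Baselines are uniform
  on [1, 50] — the lower bound sits *below* the expressed-set threshold so
  that calling is genuinely exercised. piRNA reads are 24-34 nt anchored
  at the locus 5' end (piRNA 5' termini are sharply defined in vivo;
  length heterogeneity is 3'), with the 5' base drawn as U with
  probability 0.8 and uniformly from A/C/G otherwise, so the realized 5'U
  fraction equals the planted bias. Optional antisense partners are
  emitted with an exact 10-nt 5'-5' overlap — the detection statistic is
  purely positional, so partners are defined by geometry with
  reverse-complemented genomic sequence;
* background components: 20-23 nt miRNA reads at miRNA loci (per-locus
  means 50-500, the dominant fraction of a real library), degradation
  fragments 18-40 nt scattered sense-strand over ncRNA and gene bodies
  (2 per kb per sample; 25x on chrM tRNA/rRNA, since mitochondrial
  structural RNA dominates real degradation), and unannotated genomic
  background (5 fragments per kb per sample, both strands). The genomic
  background is what populates the off-signal bins of the ping-pong
  histogram, as in real libraries; without it the z-score denominator is
  degenerate.

What the generator does **not** emulate: sequencing errors and quality
scores, adapter artifacts, mappability structure, multi-mapping, isoform
structure (genes are bodies, not spliced transcripts), and any realistic
sequence composition beyond uniform random contigs. Passing tests
therefore demonstrate the correctness and calibration of the *algorithms*
under the stated statistical model, not performance on real libraries.
The degradation model in particular is a uniform-fragment stand-in; no
quantitative model of ncRNA decay is claimed.

A single integer seed drives every draw (`build_toy_genome` uses it
directly, `simulate_reads` uses seed + 1), so identical configurations
produce byte-identical files.

## Pipeline, determinism, problem sizes

`run_pipeline()` composes simulate &rarr; filter &rarr; count &rarr;
expressed sets &rarr; DE (all later-vs-earlier stage contrasts: MPC vs
PSC, CPC vs PSC, CPC vs MPC) &rarr; clustering &rarr; signatures &rarr;
genomic context, writing deterministic TSVs (fixed numeric formatting,
full precision for p-values, key-sorted rows) plus a JSON manifest of
configuration digest and per-file checksums; two runs with the same
configuration and seed are byte-identical. Degenerate configurations
(e.g. an unreachable expression threshold) propagate as valid empty
outputs rather than failures.

The shipped test suite and the acceptance script run the default design —
300 loci, 9 samples, roughly 300k reads, 1500 shuffles — with
multi-seed calibration studies at 2,000 features x 20 seeds (DE), 10
seeds (ping-pong), and 20 seeds (5'U recovery, enrichment null). These
sizes were chosen as the smallest at which the binomial/NB standard
errors make the stated tolerances meaningful.

## Numerical and degenerate-input choices

* Expression threshold boundary is inclusive (mean exactly 3 is
  expressed).
* Assignment ties (equal overlap) and membership ties (equal top
  membership) break to the lexicographically/index-smallest candidate, so
  results are order-independent.
* `cpm_normalize` errors on a zero library rather than emitting NaN;
  `length_density` returns an empty table for empty samples.
* The CPM library size defaults to all post-filter reads (assigned +
  unassigned); an assigned-only variant is selectable.
* Zero observed enrichment is reported as -Inf with empirical p = 1;
  a zero null mean is NA with a warning.
* BH adjustment excludes untested (NA) features from the family.
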