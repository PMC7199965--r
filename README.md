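# pirdisco

Identification and characterization of putative PIWI-interacting RNAs
(piRNAs) in aligned small RNA-seq data across a differentiation time
course.

## The problem

piRNAs are 24–34 nt small RNAs classically restricted to the germline but
increasingly reported in somatic cells — pluripotent, neural, and cardiac
among them. Calling them confidently in bulk small RNA-seq is hard because
the candidate length window is contaminated by degradation fragments of
abundant structural ncRNAs (tRNA, rRNA, snoRNA) and flanked by the much
larger miRNA fraction (20–23 nt). `pirdisco` is for analysts who have
aligned small-RNA reads (BAM/SAM/BED), a piRNA locus catalog
(piRBase-style BED), an ncRNA exclusion annotation (DASHR-style BED), and
gene models (GENCODE-style GTF), and want a reproducible, tested path from
reads to an expressed piRNA catalog with its temporal and genomic
characterization.

## What it computes

- **Filtering cascade** — keep reads with 24 ≤ RL ≤ 34, then remove reads
  with a same-strand overlap with any non-piRNA ncRNA annotation, with
  per-sample accounting.
- **Quantification and expressed sets** — largest-overlap assignment of
  reads to piRNA loci; a locus is expressed in a stage when its mean raw
  count across replicates is ≥ 3; CPM normalization.
- **Differential expression** — negative-binomial Wald test
  (median-of-ratios size factors, moment dispersion from pooled
  within-condition variance, *t* reference with n−2 df), calls at
  |log2FC| ≥ 1, p < 0.05 and BH-adjusted p (fdr) < 0.1; between-stage
  Pearson correlation of log2(CPM+1).
- **Soft clustering** — fuzzy c-means (c = 8, m = 1.15) of z-scored
  stage-mean trajectories, with seeded restarts and an exact
  template-matching utility.
- **Biogenesis signatures** — per-position base composition (5′ uridine
  bias), ping-pong 5′–5′ overlap histogram with
  z10 = (h(10) − mean h(s≠10)) / sd h(s≠10), and CPM-scaled coverage
  meta-profiles over loci.
- **Genomic context** — host-gene assignment with orientation, 1500×
  interval-shuffling enrichment null
  (log2FE = log2(observed / null mean), empirical p with +1 correction),
  host-gene percent coverage, sense piRNAs-per-gene tallies, and
  hypergeometric gene-set overrepresentation.
- **Synthetic data** — a generator producing a toy genome, the three
  annotation layers, and per-sample reads with planted ground truth
  (cluster templates, 5′U bias, optional ping-pong partners, and a
  chrM-like annotation gap), so the whole pipeline is testable offline.

## Worked example

```r
library(pirdisco)

cfg <- simulation_config(seed = 1)        # 3 stages x 3 replicates, 300 loci
sim <- simulate_dataset(cfg)              # or write files with dir = "sim/"

fc <- filter_cascade(sim$reads, sim$ncrna)
head(fc$report[, 1:4], 3)
#>   sample_id n_unfiltered n_after_length n_after_ncrna
#> 1      CPC1        36008          20125         20103
#> 2      CPC2        34577          19758         19738
#> 3      CPC3        35749          20162         20143

counts <- count_reads(fc$reads, sim$pirna, sim$samples)
counts
#> pirna_counts: 300 loci x 9 samples; 169651 assigned, 11898 unassigned reads

expressed <- call_expressed(counts, min_mean = 3)
expressed
#> expressed piRNAs (mean count >= 3 ): 300 in union; PSC=294, MPC=298, CPC=295

de <- classify_de(nb_test(counts, c("PSC", "CPC")))
attr(de, "summary")
#>       up     down       ns untested
#>      107      114       79        0

pir_reads <- IRanges::subsetByOverlaps(fc$reads, sim$pirna)
base_frequency(pir_reads)$U[1]     # 5' uridine frequency at position 1
#> [1] 0.798

pingpong_profile(fc$reads)
#> ping-pong profile: h(10) = 1603 ; z10 = -0.515
```

Reading: the length filter keeps ~56% of reads and the ncRNA subtraction
trims the remainder; all 300 planted loci are recovered in the union
catalog with stage sets of 294/298/295; the PSC→CPC contrast calls 221
loci differentially expressed (107 up, 114 down); the 5′U frequency 0.798
recovers the planted bias of 0.8; and with no planted ping-pong pairs the
10-nt overlap z-score sits inside the null band (|z10| < 2).

`run_pipeline(pipeline_config(seed = 1), "out/")` runs every stage in
order and writes deterministic TSVs plus a checksum manifest; identical
config and seed reproduce the output tree byte for byte.

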