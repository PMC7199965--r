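suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# read GRanges from parallel vectors; random sequences unless given
make_reads <- function(chrom, start, width, strand, sample_id = "s1",
                       seq = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gr <- GRanges(chrom, IRanges(start, width = width), strand = strand)
  if (is.null(seq))
    seq <- vapply(width(gr), function(w)
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
            collapse = ""), character(1))
  mcols(gr)$seq <- seq
  mcols(gr)$sample_id <- rep_len(sample_id, length(gr))
  gr
}

make_annotations <- function(chrom, start, end, strand, ids, classes) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr) <- DataFrame(
    feature_id = ids,
    feature_class = factor(classes, levels = pirdisco:::FEATURE_CLASSES))
  names(gr) <- ids
  gr
}

# uniformly random reads over a toy contig set, mixed lengths 15..45
random_reads <- function(n, seed, contigs = c(chrA = 50000L, chrB = 30000L),
                         sample_id = "s1") {
  set.seed(seed)
  len <- sample(15:45, n, replace = TRUE)
  ci <- sample(seq_along(contigs), n, replace = TRUE)
  start <- 1L + floor(runif(n) * (contigs[ci] - len + 1L))
  make_reads(names(contigs)[ci], start, len,
             sample(c("+", "-"), n, TRUE), sample_id = sample_id)
}

# minimal sample sheet
make_samples <- function(stages = c("PSC", "MPC", "CPC"), reps = 3) {
  df <- expand.grid(replicate = seq_len(reps), stage = stages,
                    stringsAsFactors = FALSE)[, c(2, 1)]
  df$sample_id <- paste0(df$stage, df$replicate)
  df$stage <- factor(df$stage, levels = stages)
  df
}

# small fast simulation used by several tests; ... overrides any default
fast_sim_config <- function(seed, ...) {
  args <- list(seed = seed,
               contigs = c(chr1 = 120000L, chr2 = 80000L, chrM = 16000L),
               n_pirna_loci = 100L, n_chrm_pirna_loci = 4L,
               n_mirna_loci = 15L, n_protein_coding = 12L,
               n_lncrna = 5L, n_trna = 8L, n_rrna = 3L, n_snorna = 5L)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}
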