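#' Filter reads by length
#'
#' Keeps reads whose length lies in the putative piRNA range. The strict
#' bounds 23 < RL < 35 used upstream of piRNA discovery translate to an
#' inclusive 24-34 nt window, the defaults here.
#'
#' @param reads `GRanges` of aligned reads.
#' @param min_len,max_len inclusive bounds in nt.
#' @return the retained reads, input order preserved.
#' @export
filter_by_length <- function(reads, min_len = 24L, max_len = 34L) {
  stopifnot(min_len >= 1, min_len <= max_len)
  reads[width(reads) >= min_len & width(reads) <= max_len]
}

#' Subtract reads overlapping non-piRNA ncRNA annotations
#'
#' Removes every read with a same-strand overlap of at least
#' `min_overlap_frac` of its length (default: any overlap, >= 1 bp) with an
#' annotation whose class is in `excluded_classes`. Overlap with
#' opposite-strand features, or with piRNA annotations, never removes a
#' read.
#'
#' @param reads `GRanges` of aligned reads.
#' @param ncrna annotation `GRanges` with a `feature_class` column.
#' @param excluded_classes classes whose same-strand overlap removes a
#'   read; defaults to all ncRNA classes except piRNA.
#' @param min_overlap_frac minimum overlap as a fraction of read length;
#'   0 means any (>= 1 bp) overlap.
#' @return the surviving reads, input order preserved.
#' @export
subtract_ncrna <- function(reads, ncrna, excluded_classes = NCRNA_CLASSES,
                           min_overlap_frac = 0) {
  stopifnot(!"piRNA" %in% excluded_classes)
  excl <- ncrna[as.character(ncrna$feature_class) %in% excluded_classes]
  if (length(excl) == 0 || length(reads) == 0) return(reads)
  hits <- findOverlaps(reads, excl, ignore.strand = FALSE)
  if (min_overlap_frac > 0 && length(hits)) {
    ov <- width(pintersect(reads[queryHits(hits)], excl[subjectHits(hits)]))
    hits <- hits[ov >= min_overlap_frac * width(reads)[queryHits(hits)]]
  }
  if (length(hits) == 0) return(reads)
  reads[-unique(queryHits(hits))]
}

#' Per-sample read-length density
#'
#' Relative frequency of each observed read length, per sample.
#'
#' @param reads `GRanges` with a `sample_id` metadata column.
#' @return data.frame with columns `sample_id`, `length`, `frequency`;
#'   frequencies sum to 1 within each sample. Samples with no reads are
#'   absent (no NaN rows).
#' @export
length_density <- function(reads) {
  if (length(reads) == 0)
    return(data.frame(sample_id = character(0), length = integer(0),
                      frequency = numeric(0)))
  tab <- table(sample_id = reads$sample_id, length = width(reads))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$length <- as.integer(df$length)
  df <- df[df$Freq > 0, ]
  tot <- tapply(df$Freq, df$sample_id, sum)
  df$frequency <- df$Freq / as.numeric(tot[df$sample_id])
  df <- df[order(df$sample_id, df$length), c("sample_id", "length",
                                             "frequency")]
  rownames(df) <- NULL
  df
}

#' Run the two-step filtering cascade with per-step accounting
#'
#' Length filter followed by strand-specific ncRNA subtraction, plus the
#' per-sample read accounting (counts and percentages of unfiltered reads
#' retained at each step).
#'
#' @param reads `GRanges` with `sample_id`.
#' @inheritParams filter_by_length
#' @inheritParams subtract_ncrna
#' @return list with `reads` (the filtered GRanges) and `report`
#'   (data.frame: `sample_id`, `n_unfiltered`, `n_after_length`,
#'   `n_after_ncrna`, `pct_after_length`, `pct_after_ncrna`).
#' @export
filter_cascade <- function(reads, ncrna, min_len = 24L, max_len = 34L,
                           excluded_classes = NCRNA_CLASSES,
                           min_overlap_frac = 0) {
  after_len <- filter_by_length(reads, min_len, max_len)
  after_nc <- subtract_ncrna(after_len, ncrna, excluded_classes,
                             min_overlap_frac)
  sids <- sort(unique(reads$sample_id))
  cnt <- function(r) {
    t <- table(factor(r$sample_id, levels = sids))
    as.integer(t)
  }
  n0 <- cnt(reads); n1 <- cnt(after_len); n2 <- cnt(after_nc)
  report <- data.frame(sample_id = sids, n_unfiltered = n0,
                       n_after_length = n1, n_after_ncrna = n2,
                       pct_after_length = ifelse(n0 > 0, 100 * n1 / n0, NA),
                       pct_after_ncrna = ifelse(n0 > 0, 100 * n2 / n0, NA))
  list(reads = after_nc, report = report)
}
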