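#' Per-position base composition of reads
#'
#' Frequency of A/C/G/U at each position from the 5' end, computed over all
#' reads long enough to reach that position. Sequences must be stored
#' read-strand oriented (as [read_alignments()] and the simulator
#' guarantee); T is reported as U.
#'
#' @param reads `GRanges` with a `seq` metadata column.
#' @param n_positions number of 5' positions to profile.
#' @return data.frame with columns `position`, `A`, `C`, `G`, `U`,
#'   `n_reads`; at every position with `n_reads > 0` the four frequencies
#'   sum to 1.
#' @export
base_frequency <- function(reads, n_positions = 34L) {
  sq <- reads$seq
  if (is.null(sq) || all(is.na(sq)))
    stop("reads carry no sequences; base_frequency needs them")
  sq <- sq[!is.na(sq)]
  out <- data.frame(position = seq_len(n_positions), A = 0, C = 0, G = 0,
                    U = 0, n_reads = 0L)
  nc <- nchar(sq)
  for (p in seq_len(n_positions)) {
    b <- substr(sq[nc >= p], p, p)
    b <- b[b %in% c("A", "C", "G", "T")]
    n <- length(b)
    out$n_reads[p] <- n
    if (n > 0) {
      tb <- table(factor(b, levels = c("A", "C", "G", "T")))
      out[p, c("A", "C", "G", "U")] <- as.numeric(tb) / n
    }
  }
  out
}

#' Ping-pong 5'-5' overlap profile
#'
#' For every pair of opposite-strand reads on the same contig, the
#' signature distance is s = q - p + 1, where p is the plus read's 5'
#' position (its start) and q the minus read's 5' position (its end). The
#' histogram h(s) over 1 <= s <= `max_overlap` is computed exactly by
#' multiplying 5'-position multiplicities, and the ping-pong z-score
#' compares h(10) with the remaining bins:
#' z10 = (h(10) - mean(h(s), s != 10)) / sd(h(s), s != 10).
#'
#' @param reads `GRanges` of aligned reads.
#' @param max_overlap largest overlap bin, nt.
#' @return list of class `pingpong_profile`: `histogram` (data.frame
#'   `overlap`, `pairs`) and `z10` (`NA` when the off-10 bins have no
#'   spread, e.g. single-strand input).
#' @export
pingpong_profile <- function(reads, max_overlap = 20L) {
  h <- numeric(max_overlap)
  for (ch in unique(as.character(seqnames(reads)))) {
    r <- reads[seqnames(reads) == ch]
    p5 <- start(r)[as.logical(strand(r) == "+")]
    m5 <- end(r)[as.logical(strand(r) == "-")]
    if (!length(p5) || !length(m5)) next
    tp <- table(p5); tm <- table(m5)
    pp <- as.integer(names(tp)); np <- as.numeric(tp)
    mp <- as.integer(names(tm)); nm <- as.numeric(tm)
    for (s in seq_len(max_overlap)) {
      idx <- match(pp + s - 1L, mp)
      ok <- !is.na(idx)
      if (any(ok)) h[s] <- h[s] + sum(np[ok] * nm[idx[ok]])
    }
  }
  off <- h[-10]
  z10 <- if (length(unique(off)) < 2) NA_real_
         else (h[10] - mean(off)) / sd(off)
  structure(list(histogram = data.frame(overlap = seq_len(max_overlap),
                                        pairs = h),
                 z10 = z10),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("ping-pong profile: h(10) =", x$histogram$pairs[10],
      "; z10 =", format(x$z10, digits = 3), "\n")
  invisible(x)
}

#' Meta-profile of read coverage over a locus set
#'
#' Per-base same-strand depth over each locus, normalized to counts per
#' million (divided by total reads / 1e6), rescaled to a common
#' `grid`-point coordinate (5' -> 3' of the locus), and averaged across
#' loci.
#'
#' @param reads `GRanges` of aligned reads.
#' @param loci annotation `GRanges`.
#' @param grid number of scaled positions.
#' @param total_reads library size used for the CPM scaling; defaults to
#'   `length(reads)`.
#' @return data.frame with `position` (1..grid) and `mean_cpm`.
#' @export
coverage_profile <- function(reads, loci, grid = 100L,
                             total_reads = length(reads)) {
  stopifnot(length(loci) > 0)
  prof <- matrix(0, length(loci), grid)
  for (str in c("+", "-")) {
    li <- which(as.logical(strand(loci) == str))
    if (!length(li)) next
    cov <- coverage(reads[strand(reads) == str])
    for (k in li) {
      ch <- as.character(seqnames(loci))[k]
      if (!ch %in% names(cov)) next
      pos <- start(loci)[k]:end(loci)[k]
      covlen <- length(cov[[ch]])
      v <- numeric(length(pos))
      inb <- pos <= covlen
      if (any(inb)) v[inb] <- as.numeric(cov[[ch]][pos[inb]])
      if (str == "-") v <- rev(v)  # orient 5' -> 3' of the locus
      prof[k, ] <- if (length(v) == 1) rep(v, grid)
                   else approx(seq_along(v), v, n = grid)$y
    }
  }
  scale <- if (total_reads > 0) total_reads / 1e6 else 1
  data.frame(position = seq_len(grid),
             mean_cpm = colMeans(prof) / scale)
}
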