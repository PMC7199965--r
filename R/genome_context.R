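#' Assign piRNAs to host genes
#'
#' Any overlap (>= 1 bp) between a piRNA locus and a gene body defines
#' intersection; orientation is sense when the strands agree. A piRNA may
#' host-map to several overlapping genes; piRNAs with no gene overlap are
#' intergenic.
#'
#' @param pirnas piRNA annotation `GRanges` (typically the expressed set).
#' @param genes gene-body annotation `GRanges` with `feature_class`.
#' @return data.frame (`pirna_id`, `gene_id`, `gene_class`, `orientation`)
#'   with one row per piRNA-gene pair; intergenic piRNAs appear with `NA`
#'   gene columns. Attribute `pct_genic` is the percentage of piRNAs with
#'   at least one gene overlap.
#' @export
assign_hosts <- function(pirnas, genes) {
  hits <- findOverlaps(pirnas, genes, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  orientation <- ifelse(as.character(strand(pirnas))[q] ==
                          as.character(strand(genes))[s],
                        "sense", "antisense")
  df <- data.frame(pirna_id = pirnas$feature_id[q],
                   gene_id = genes$feature_id[s],
                   gene_class = as.character(genes$feature_class)[s],
                   orientation = orientation)
  inter <- setdiff(pirnas$feature_id, df$pirna_id)
  if (length(inter))
    df <- rbind(df, data.frame(pirna_id = inter, gene_id = NA,
                               gene_class = NA, orientation = NA))
  df <- df[order(df$pirna_id, df$gene_id), ]
  rownames(df) <- NULL
  attr(df, "pct_genic") <-
    100 * (1 - length(inter) / max(1L, length(pirnas)))
  df
}

# count piRNAs intersecting >= 1 gene per (gene_class, orientation)
host_counts <- function(pirnas, genes,
                        classes = c("protein_coding", "lncRNA")) {
  out <- matrix(0L, length(classes), 2,
                dimnames = list(classes, c("sense", "antisense")))
  for (cl in classes) {
    g <- genes[as.character(genes$feature_class) == cl]
    if (!length(g)) next
    out[cl, "sense"] <-
      sum(countOverlaps(pirnas, g, ignore.strand = FALSE) > 0)
    gflip <- g
    strand(gflip) <- ifelse(as.character(strand(g)) == "+", "-", "+")
    out[cl, "antisense"] <-
      sum(countOverlaps(pirnas, gflip, ignore.strand = FALSE) > 0)
  }
  out
}

#' Shuffle-based null distribution of gene-intersection counts
#'
#' Each shuffle relocates every piRNA to a uniformly random start on its
#' original contig, preserving length and strand (whole-contig placement,
#' overlaps among shuffled piRNAs allowed), and recounts, per gene class
#' and orientation, how many piRNAs intersect at least one gene.
#'
#' @param pirnas piRNA annotation `GRanges`.
#' @param contig_lengths named integer vector of contig lengths.
#' @param genes gene annotation `GRanges`.
#' @param n_shuffles number of shuffles (default 1500).
#' @param seed integer seed.
#' @param classes gene classes scored.
#' @return list: `null` (array shuffles x classes x orientations) and
#'   `observed` (classes x orientations matrix).
#' @export
shuffle_null <- function(pirnas, contig_lengths, genes, n_shuffles = 1500L,
                         seed = 1L, classes = c("protein_coding", "lncRNA")) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  w <- width(pirnas)
  ch <- as.character(seqnames(pirnas))
  if (any(w > contig_lengths[ch]))
    stop("piRNA longer than its contig")
  set.seed(seed)
  n <- length(pirnas)
  null <- array(0L, dim = c(n_shuffles, length(classes), 2),
                dimnames = list(NULL, classes, c("sense", "antisense")))
  # one findOverlaps over all shuffles at once, in blocks
  block <- max(1L, min(n_shuffles, ceiling(2e6 / n)))
  done <- 0L
  while (done < n_shuffles) {
    b <- min(block, n_shuffles - done)
    maxs <- rep(contig_lengths[ch] - w + 1L, b)
    starts <- 1L + floor(runif(n * b) * maxs)
    shuf <- GRanges(rep(ch, b), IRanges(starts, width = rep(w, b)),
                    strand = rep(as.character(strand(pirnas)), b))
    grp <- factor(rep(seq_len(b), each = n), levels = seq_len(b))
    for (cl in classes) {
      g <- genes[as.character(genes$feature_class) == cl]
      if (!length(g)) next
      hit_s <- countOverlaps(shuf, g, ignore.strand = FALSE) > 0
      gflip <- g
      strand(gflip) <- ifelse(as.character(strand(g)) == "+", "-", "+")
      hit_a <- countOverlaps(shuf, gflip, ignore.strand = FALSE) > 0
      null[done + seq_len(b), cl, "sense"] <-
        as.integer(tapply(hit_s, grp, sum))
      null[done + seq_len(b), cl, "antisense"] <-
        as.integer(tapply(hit_a, grp, sum))
    }
    done <- done + b
  }
  list(null = null, observed = host_counts(pirnas, genes, classes))
}

#' Fold enrichment of gene-origin against the shuffle null
#'
#' log2 fold enrichment = log2(observed / null mean) per gene class and
#' orientation, with the empirical upper-tail p-value
#' (#\{null >= observed\} + 1) / (n_shuffles + 1).
#'
#' @param shuffles output of [shuffle_null()] (or a compatible list with
#'   `observed` and `null`).
#' @return data.frame: `gene_class`, `orientation`, `observed`,
#'   `null_mean`, `null_sd`, `log2_fold_enrichment`, `p_emp`,
#'   `n_shuffles`. A zero observed count yields `-Inf` enrichment; a zero
#'   null mean yields `NA` with a warning.
#' @export
fold_enrichment <- function(shuffles) {
  obs <- shuffles$observed
  null <- shuffles$null
  n_sh <- dim(null)[1]
  rows <- expand.grid(gene_class = rownames(obs),
                      orientation = colnames(obs),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    cl <- rows$gene_class[i]; orn <- rows$orientation[i]
    nv <- null[, cl, orn]
    mu <- mean(nv)
    fe <- if (mu == 0) { warning("null mean 0 for ", cl, " ", orn); NA_real_
          } else log2(obs[cl, orn] / mu)
    data.frame(gene_class = cl, orientation = orn,
               observed = obs[cl, orn], null_mean = mu, null_sd = sd(nv),
               log2_fold_enrichment = fe,
               p_emp = (sum(nv >= obs[cl, orn]) + 1) / (n_sh + 1),
               n_shuffles = n_sh)
  }))
  rownames(out) <- NULL
  out
}

#' Percent of gene-body bases covered by reads
#'
#' Per gene, the union of read intervals on the matching (sense) or
#' opposite (antisense) strand is intersected with the gene body; the
#' percentage of covered bases is reported with its median over genes.
#'
#' @param reads filtered `GRanges` of aligned reads.
#' @param genes gene `GRanges` (typically the piRNA-hosting genes).
#' @param orientation `"sense"` or `"antisense"`.
#' @return data.frame (`gene_id`, `percent_covered`) with attribute
#'   `median_percent`.
#' @export
gene_coverage <- function(reads, genes, orientation = c("sense",
                                                        "antisense")) {
  orientation <- match.arg(orientation)
  gr <- genes
  if (orientation == "antisense")
    strand(gr) <- ifelse(as.character(strand(genes)) == "+", "-", "+")
  red <- reduce(granges(reads))  # strand-aware union of read intervals
  hits <- findOverlaps(gr, red, ignore.strand = FALSE)
  cov_bp <- rep(0L, length(gr))
  if (length(hits)) {
    ov <- width(pintersect(gr[queryHits(hits)], red[subjectHits(hits)]))
    agg <- tapply(ov, queryHits(hits), sum)
    cov_bp[as.integer(names(agg))] <- as.integer(agg)
  }
  df <- data.frame(gene_id = genes$feature_id,
                   percent_covered = 100 * cov_bp / width(genes))
  attr(df, "median_percent") <- median(df$percent_covered)
  df
}

#' Sense piRNAs per host gene
#'
#' Tally of sense-oriented piRNA assignments per gene, with the histogram
#' binned 1 / 2 / 3 / >=4.
#'
#' @param hosts data.frame from [assign_hosts()].
#' @return data.frame (`gene_id`, `n_pirnas`) sorted by decreasing count;
#'   attribute `histogram` gives the binned gene counts.
#' @export
pirnas_per_gene <- function(hosts) {
  sh <- hosts[!is.na(hosts$orientation) & hosts$orientation == "sense", ]
  if (nrow(sh) == 0) {
    out <- data.frame(gene_id = character(0), n_pirnas = integer(0))
    attr(out, "histogram") <- setNames(integer(4),
                                       c("1", "2", "3", ">=4"))
    return(out)
  }
  tab <- table(sh$gene_id)
  out <- data.frame(gene_id = names(tab), n_pirnas = as.integer(tab))
  out <- out[order(-out$n_pirnas, out$gene_id), ]
  rownames(out) <- NULL
  bins <- cut(out$n_pirnas, c(0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("1", "2", "3", ">=4"))
  attr(out, "histogram") <- setNames(as.integer(table(bins)),
                                     levels(bins))
  out
}

#' Hypergeometric gene-set overrepresentation
#'
#' For each named gene set, the upper-tail hypergeometric probability of
#' observing at least the seen number of query hits given the universe,
#' BH-adjusted across sets. Gene sets are intersected with the universe
#' before testing.
#'
#' @param query character vector of genes of interest (subset of
#'   `universe`).
#' @param gene_sets named list of character vectors (GMT-style).
#' @param universe character vector of all eligible genes.
#' @return data.frame (`gene_set_id`, `k`, `K`, `n`, `N`, `p`, `padj`)
#'   sorted by `padj`.
#' @export
overrepresentation <- function(query, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(gene_set_id = id, k = k, K = K, n = n, N = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$padj, out$p, out$gene_set_id), ]
  rownames(out) <- NULL
  out
}

#' Per-chromosome piRNA tally
#'
#' @param pirnas piRNA annotation `GRanges`.
#' @param ids optional subset of feature ids (e.g. the expressed catalog).
#' @return data.frame `chrom`, `n`.
#' @export
pirnas_per_chromosome <- function(pirnas, ids = NULL) {
  if (!is.null(ids)) pirnas <- pirnas[pirnas$feature_id %in% ids]
  tab <- table(as.character(seqnames(pirnas)))
  data.frame(chrom = names(tab), n = as.integer(tab))
}
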