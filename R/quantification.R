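#' Count filtered reads per piRNA locus
#'
#' Assigns each read to the same-strand piRNA annotation it overlaps. A
#' read overlapping several piRNA loci goes to the one with the largest
#' overlap, ties broken by lexicographically smallest `feature_id`
#' (`mode = "largest_overlap"`, the default, deterministic analogue of
#' union counting with ambiguity resolution); with `mode = "ambiguous_drop"`
#' multi-locus reads are discarded instead. Reads overlapping no piRNA are
#' tallied as unassigned.
#'
#' @param reads filtered `GRanges` with `sample_id`.
#' @param pirnas piRNA annotation `GRanges` (`feature_id` column).
#' @param samples sample sheet data.frame (`sample_id`, `stage`,
#'   `replicate`).
#' @param mode `"largest_overlap"` or `"ambiguous_drop"`.
#' @return object of class `pirna_counts`: list with `counts` (integer
#'   matrix, features x samples), `samples`, and `unassigned` (named
#'   integer vector of filtered-but-unassigned reads per sample).
#' @export
count_reads <- function(reads, pirnas, samples,
                        mode = c("largest_overlap", "ambiguous_drop")) {
  mode <- match.arg(mode)
  samples <- validate_sample_sheet(samples,
                                   stages = levels(factor(samples$stage)))
  feats <- sort(pirnas$feature_id)
  sids <- samples$sample_id
  counts <- matrix(0L, length(feats), length(sids),
                   dimnames = list(feats, sids))
  n_reads <- table(factor(reads$sample_id, levels = sids))
  assigned <- rep(NA_character_, length(reads))
  hits <- findOverlaps(reads, pirnas, ignore.strand = FALSE)
  if (length(hits)) {
    q <- queryHits(hits); s <- subjectHits(hits)
    ov <- width(pintersect(reads[q], pirnas[s]))
    fid <- pirnas$feature_id[s]
    o <- order(q, -ov, fid)
    q <- q[o]; fid <- fid[o]
    first <- !duplicated(q)
    if (mode == "ambiguous_drop") {
      multi <- unique(q[duplicated(q)])
      keep <- first & !(q %in% multi)
      assigned[q[keep]] <- fid[keep]
    } else {
      assigned[q[first]] <- fid[first]
    }
  }
  ok <- !is.na(assigned)
  if (any(ok)) {
    t2 <- table(factor(assigned[ok], levels = feats),
                factor(reads$sample_id[ok], levels = sids))
    counts[] <- counts + as.integer(t2)
  }
  unassigned <- as.integer(n_reads) - colSums(counts)
  names(unassigned) <- sids
  structure(list(counts = counts, samples = samples,
                 unassigned = unassigned),
            class = "pirna_counts")
}

#' @export
print.pirna_counts <- function(x, ...) {
  cat("pirna_counts:", nrow(x$counts), "loci x", ncol(x$counts),
      "samples;", sum(x$counts), "assigned,", sum(x$unassigned),
      "unassigned reads\n")
  invisible(x)
}

#' Counts-per-million normalization
#'
#' `value = count / library_size * 1e6`. The library size is, per sample,
#' either all post-filter reads (assigned + unassigned, the default) or the
#' assigned reads only.
#'
#' @param x a `pirna_counts` object, or a bare count matrix (then
#'   `library = "assigned"` is forced).
#' @param library `"post_filter"` or `"assigned"`.
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm_normalize <- function(x, library = c("post_filter", "assigned")) {
  library <- match.arg(library)
  if (is.matrix(x)) {
    counts <- x
    lib <- colSums(counts)
  } else {
    counts <- x$counts
    lib <- colSums(counts) +
      if (library == "post_filter") x$unassigned[colnames(counts)] else 0
  }
  zero <- which(lib == 0)
  if (length(zero))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Call per-stage expressed piRNA sets
#'
#' A locus is expressed in a stage when its mean raw count across that
#' stage's replicates is at least `min_mean` (default 3). The union over
#' stages is the identified catalog; a pooled variant (mean over all
#' samples >= `min_mean`) is reported alongside.
#'
#' @param x a `pirna_counts` object.
#' @param min_mean expression threshold on the raw-count stage mean.
#' @return list of class `expressed_sets`: `stage_sets` (named list of
#'   feature-id vectors), `union`, `pooled` (the pooled-threshold variant),
#'   `min_mean`.
#' @export
call_expressed <- function(x, min_mean = 3) {
  stopifnot(inherits(x, "pirna_counts"))
  stages <- levels(x$samples$stage)
  stage_sets <- setNames(lapply(stages, function(st) {
    sids <- x$samples$sample_id[x$samples$stage == st]
    m <- rowMeans(x$counts[, sids, drop = FALSE])
    rownames(x$counts)[m >= min_mean]
  }), stages)
  un <- sort(unique(unlist(stage_sets, use.names = FALSE)))
  pooled <- rownames(x$counts)[rowMeans(x$counts) >= min_mean]
  structure(list(stage_sets = stage_sets, union = un, pooled = pooled,
                 min_mean = min_mean),
            class = "expressed_sets")
}

#' @export
print.expressed_sets <- function(x, ...) {
  cat("expressed piRNAs (mean count >=", x$min_mean, "):",
      length(x$union), "in union;",
      paste(sprintf("%s=%d", names(x$stage_sets),
                    lengths(x$stage_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Stage-set sizes and intersections
#'
#' Per-stage sizes plus all pairwise and higher-order intersection counts.
#'
#' @param sets an `expressed_sets` object or a named list of id vectors.
#' @return data.frame with columns `combination` (stage names joined by
#'   `&`) and `n`.
#' @export
set_overlaps <- function(sets) {
  if (inherits(sets, "expressed_sets")) sets <- sets$stage_sets
  stages <- names(sets)
  combos <- unlist(lapply(seq_along(stages), function(k)
    utils::combn(stages, k, simplify = FALSE)), recursive = FALSE)
  data.frame(
    combination = vapply(combos, paste, character(1), collapse = "&"),
    n = vapply(combos, function(cmb)
      length(Reduce(intersect, sets[cmb])), integer(1)))
}
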