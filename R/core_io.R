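#' Read aligned small-RNA reads into a GRanges
#'
#' Ingests mapped reads from BAM, SAM or BED into a `GRanges` with one range
#' per primary alignment. Unmapped, secondary and supplementary records are
#' dropped. Sequences are stored read-strand oriented (the biological 5'->3'
#' of the small RNA): for minus-strand BAM/SAM records the reference-forward
#' SEQ field is reverse-complemented on ingest. BED input carries the
#' sequence, already read-oriented, in a seventh column.
#'
#' @param path path to a BAM, SAM or BED file.
#' @param format one of `"auto"`, `"BAM"`, `"SAM"`, `"BED"`. `"auto"` picks
#'   by file extension.
#' @param sample_id sample identifier attached to every read
#'   (`mcols(.)$sample_id`); defaults to the file name without extension.
#' @return `GRanges` with metadata columns `seq` (character, may be `NA`
#'   for BED without a sequence column) and `sample_id`.
#' @export
read_alignments <- function(path, format = c("auto", "BAM", "SAM", "BED"),
                            sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bam = "BAM", sam = "SAM", bed = "BED",
                     stop("cannot infer format from extension of ", path))
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "BED") {
    gr <- read_reads_bed(path)
  } else {
    bam <- path
    if (format == "SAM")
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "seq")
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    gr <- granges(ga)
    sq <- mcols(ga)$seq
    neg <- as.logical(strand(gr) == "-")
    if (any(neg)) sq[neg] <- reverseComplement(sq[neg])
    mcols(gr)$seq <- as.character(sq)
  }
  mcols(gr)$sample_id <- sample_id
  gr
}

# BED6 with optional 7th column holding the read-oriented sequence
read_reads_bed <- function(path) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(tab) < 6)
    stop("reads BED needs >= 6 columns (chrom start end name score strand): ",
         path)
  st <- suppressWarnings(as.integer(tab[[2]]))
  en <- suppressWarnings(as.integer(tab[[3]]))
  bad <- which(is.na(st) | is.na(en) | !tab[[6]] %in% c("+", "-"))
  if (length(bad))
    stop("malformed BED record at line ", bad[1], " of ", path)
  gr <- GRanges(tab[[1]], IRanges(st + 1L, en), strand = tab[[6]])
  names(gr) <- tab[[4]]
  mcols(gr)$seq <- if (ncol(tab) >= 7) tab[[7]] else NA_character_
  if (ncol(tab) >= 7) {
    mism <- which(nchar(tab[[7]]) != width(gr))
    if (length(mism))
      stop("sequence length != interval width at line ", mism[1],
           " of ", path)
  }
  gr
}

#' Read a feature annotation set from BED or GTF
#'
#' Builds the strand-aware annotation container used throughout the
#' pipeline: a `GRanges` with `feature_id` (unique) and `feature_class`
#' drawn from the closed vocabulary piRNA / miRNA / tRNA / rRNA / snoRNA /
#' other_ncRNA / protein_coding / lncRNA. GTF input is collapsed to
#' gene-body intervals (rows with `type == "gene"` when a type column is
#' present), classed through `class_map` on the `gene_type` attribute. BED
#' input is classed by `class_map` on the name column; entries of
#' `class_map` may be exact names, or prefix rules written `"prefix*"`.
#'
#' @param path file path.
#' @param format `"auto"`, `"BED"` or `"GTF"`.
#' @param class_map named character vector mapping attribute values (GTF
#'   `gene_type`) or name patterns (BED) to feature classes. Unmatched
#'   features fall back to `other_ncRNA` with a warning.
#' @return `GRanges` with `feature_id` and `feature_class` metadata columns.
#' @export
read_annotations <- function(path, format = c("auto", "BED", "GTF"),
                             class_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bed = "BED", gtf = "GTF", gff = "GTF",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "GTF") {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(mcols(gr)) &&
        any(as.character(mcols(gr)$type) == "gene"))
      gr <- gr[as.character(mcols(gr)$type) == "gene"]
    ids <- mcols(gr)$gene_id
    raw_class <- mcols(gr)$gene_type
    if (is.null(ids)) stop("GTF lacks gene_id attribute: ", path)
    if (is.null(raw_class)) raw_class <- rep(NA_character_, length(gr))
    cls <- map_feature_class(raw_class, class_map, exact = TRUE)
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    gr <- granges(bed)
    ids <- mcols(bed)$name
    if (is.null(ids)) stop("BED lacks a name column: ", path)
    cls <- map_feature_class(ids, class_map, exact = FALSE)
  }
  if (length(gr) == 0) stop("no features parsed from ", path)
  if (anyDuplicated(ids))
    stop("duplicate feature_id in ", path, ": ",
         ids[duplicated(ids)][1])
  out <- granges(gr)
  mcols(out) <- DataFrame(feature_id = as.character(ids),
                          feature_class = cls)
  names(out) <- out$feature_id
  out
}

map_feature_class <- function(values, class_map, exact = TRUE) {
  values <- as.character(values)
  out <- rep(NA_character_, length(values))
  if (!is.null(class_map)) {
    for (k in names(class_map)) {
      hit <- if (exact && !endsWith(k, "*")) values == k
             else startsWith(values, sub("\\*$", "", k))
      out[hit & is.na(out)] <- class_map[[k]]
    }
  }
  # GTF biotypes that already are vocabulary members map through directly
  direct <- is.na(out) & values %in% FEATURE_CLASSES
  out[direct] <- values[direct]
  if (anyNA(out)) {
    warning(sum(is.na(out)), " feature(s) with unmapped class -> other_ncRNA")
    out[is.na(out)] <- "other_ncRNA"
  }
  bad <- setdiff(unique(out), FEATURE_CLASSES)
  if (length(bad))
    stop("class_map maps to unknown classes: ", paste(bad, collapse = ", "))
  factor(out, levels = FEATURE_CLASSES)
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `stage`, `replicate`,
#' `path`. Stages are ordered as first encountered unless `stages` is
#' given.
#'
#' @param path TSV file path.
#' @param stages optional ordered character vector of stage names.
#' @return data.frame with `stage` as an ordered factor.
#' @export
read_sample_sheet <- function(path, stages = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if ("path" %in% names(df)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dirname(path), df$path[rel])
  }
  validate_sample_sheet(df, stages)
}

validate_sample_sheet <- function(df, stages = NULL) {
  need <- c("sample_id", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (anyDuplicated(df[c("stage", "replicate")]))
    stop("duplicate (stage, replicate) pair in sample sheet")
  if (is.null(stages)) stages <- unique(df$stage)
  df$stage <- factor(df$stage, levels = stages)
  if (anyNA(df$stage)) stop("sample sheet contains stages outside: ",
                            paste(stages, collapse = ", "))
  df
}

#' Write a result table deterministically
#'
#' Tab-separated with header; numeric columns rendered at 6 significant
#' digits except columns named `p`, `padj`, `pvalue` or `p_emp`, written at
#' full precision. Rows are sorted by `key` so repeated runs are
#' byte-identical.
#'
#' @param rows data.frame.
#' @param path output path.
#' @param key column name(s) to sort by; default first column.
#' @param allow_empty permit a header-only file.
#' @export
write_table <- function(rows, path, key = NULL, allow_empty = TRUE) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0 && !allow_empty)
    stop("refusing to write empty table to ", path)
  if (is.null(key)) key <- names(rows)[1]
  if (nrow(rows) > 0)
    rows <- rows[do.call(order, rows[key]), , drop = FALSE]
  full_prec <- c("p", "padj", "pvalue", "p_emp")
  fmt <- rows
  for (j in names(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
      digits <- if (j %in% full_prec) 17L else 6L
      fmt[[j]] <- formatC(fmt[[j]], digits = digits, format = "g")
    }
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotations as BED6
#'
#' @param ann annotation `GRanges` (from [read_annotations()] or the
#'   simulator).
#' @param path output path.
#' @export
write_annotations_bed <- function(ann, path) {
  df <- data.frame(chrom = as.character(seqnames(ann)),
                   start = start(ann) - 1L, end = end(ann),
                   name = ann$feature_id, score = 0L,
                   strand = as.character(strand(ann)))
  df <- df[order(df$chrom, df$start, df$name), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# reads GRanges (seq, sample_id) -> BED6+seq, deterministic order
write_reads_bed <- function(reads, path) {
  df <- data.frame(chrom = as.character(seqnames(reads)),
                   start = start(reads) - 1L, end = end(reads),
                   name = if (is.null(names(reads)))
                     sprintf("r%06d", seq_along(reads)) else names(reads),
                   score = 0L,
                   strand = as.character(strand(reads)),
                   seq = reads$seq)
  df <- df[order(df$chrom, df$start, df$end, df$name), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# gene-body GTF rows with gene_id/gene_type attributes
write_genes_gtf <- function(genes, path, source = "pirdisco") {
  bt <- as.character(genes$feature_class)
  attrs <- sprintf('gene_id "%s"; gene_type "%s";', genes$feature_id, bt)
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   source = source, type = "gene",
                   start = start(genes), end = end(genes),
                   score = ".", strand = as.character(strand(genes)),
                   frame = ".", attrs = attrs)
  df <- df[order(df$chrom, df$start, df$attrs), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
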