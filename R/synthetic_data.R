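#' Default temporal expression templates
#'
#' Eight multiplicative stage trajectories covering the qualitative shapes a
#' three-stage differentiation course can show: monotone rise/fall, mid
#' peak/dip, late rise/fall, early rise/fall. Rows are clusters, columns
#' stages.
#'
#' @param n_stages number of stages (columns).
#' @return numeric matrix with 8 rows.
#' @export
default_cluster_patterns <- function(n_stages = 3) {
  base <- rbind(c(1, 2, 4), c(4, 2, 1), c(1, 4, 1), c(4, 1, 4),
                c(1, 1, 4), c(4, 4, 1), c(1, 4, 4), c(4, 1, 1))
  if (n_stages == 3) return(base)
  t(apply(base, 1, function(r) approx(seq_len(3), r, n = n_stages)$y))
}

#' Build a simulation configuration
#'
#' Bundles every knob of the synthetic small RNA-seq generator with the
#' study-design defaults: three differentiation stages (PSC, MPC, CPC) with
#' three replicates each, 300 piRNA loci of 24-34 nt reads with a 0.8
#' probability of a 5' uridine, negative-binomial counts (variance
#' mu + alpha*mu^2, alpha = 0.05) following one of eight stage templates,
#' miRNA-length background, ncRNA/mRNA degradation fragments, and a
#' mitochondria-like contig whose tRNA/rRNA genes appear in the gene models
#' but not in the ncRNA exclusion set.
#'
#' @param seed integer RNG seed; every stochastic draw flows from it.
#' @param contigs named integer vector of contig lengths; must contain one
#'   contig named `chrM`.
#' @param n_pirna_loci total piRNA loci, including `n_chrm_pirna_loci`.
#' @param n_chrm_pirna_loci piRNA loci planted inside chrM tRNA/rRNA genes
#'   (sense), reproducing the annotation leak-through scenario.
#' @param pirna_length_range inclusive read-length range of piRNA reads, nt.
#' @param pirna_locus_length_range locus length range, bp.
#' @param u5_bias probability that a piRNA read's 5' base is uridine; the
#'   remaining mass is spread uniformly over A/C/G so the realized 5'U
#'   fraction equals `u5_bias`.
#' @param n_mirna_loci miRNA loci (22 bp) emitting 20-23 nt reads.
#' @param mirna_mean_range per-locus miRNA mean count range.
#' @param degradation_rate expected background fragments per kb of
#'   ncRNA/gene body per sample.
#' @param background_per_kb expected spurious genomic fragments (18-40 nt,
#'   random strand) per kb of genome per sample - the unannotated
#'   low-level background real libraries always contain; it is what makes
#'   the ping-pong overlap histogram's off-signal bins non-empty.
#' @param chrm_degradation_factor multiplier on `degradation_rate` for chrM
#'   tRNA/rRNA (mitochondrial degradation dominates real libraries).
#' @param pingpong_fraction fraction of piRNA reads given an antisense
#'   partner whose 5' end overlaps the read's 5' end by exactly 10 nt.
#' @param stages ordered character vector of stage names.
#' @param replicates_per_stage replicates per stage.
#' @param cluster_patterns matrix of multiplicative stage templates
#'   (clusters x stages); see [default_cluster_patterns()].
#' @param nb_dispersion negative-binomial dispersion alpha.
#' @param mean_count_range baseline locus mean range; the lower bound sits
#'   below the expressed-set threshold so calling is actually exercised.
#' @param gene_fraction_hosting fraction of nuclear piRNA loci planted
#'   inside protein-coding/lncRNA gene bodies in sense orientation.
#' @param n_protein_coding,n_lncrna,gene_length_range gene-model layout.
#' @param n_trna,n_rrna,n_snorna nuclear ncRNA exclusion-layer features.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              contigs = c(chr1 = 300000L, chr2 = 200000L,
                                          chrM = 16000L),
                              n_pirna_loci = 300L,
                              n_chrm_pirna_loci = 6L,
                              pirna_length_range = c(24L, 34L),
                              pirna_locus_length_range = c(30L, 80L),
                              u5_bias = 0.8,
                              n_mirna_loci = 50L,
                              mirna_mean_range = c(50, 500),
                              degradation_rate = 2,
                              chrm_degradation_factor = 25,
                              background_per_kb = 5,
                              pingpong_fraction = 0,
                              stages = c("PSC", "MPC", "CPC"),
                              replicates_per_stage = 3L,
                              cluster_patterns = NULL,
                              nb_dispersion = 0.05,
                              mean_count_range = c(1, 50),
                              gene_fraction_hosting = 0.65,
                              n_protein_coding = 30L,
                              n_lncrna = 10L,
                              gene_length_range = c(1000L, 3000L),
                              n_trna = 15L, n_rrna = 5L, n_snorna = 10L) {
  if (is.null(cluster_patterns))
    cluster_patterns <- default_cluster_patterns(length(stages))
  cfg <- list(seed = as.integer(seed), contigs = contigs,
              n_pirna_loci = n_pirna_loci,
              n_chrm_pirna_loci = n_chrm_pirna_loci,
              pirna_length_range = pirna_length_range,
              pirna_locus_length_range = pirna_locus_length_range,
              u5_bias = u5_bias, n_mirna_loci = n_mirna_loci,
              mirna_mean_range = mirna_mean_range,
              degradation_rate = degradation_rate,
              chrm_degradation_factor = chrm_degradation_factor,
              background_per_kb = background_per_kb,
              pingpong_fraction = pingpong_fraction,
              stages = stages,
              replicates_per_stage = replicates_per_stage,
              cluster_patterns = cluster_patterns,
              nb_dispersion = nb_dispersion,
              mean_count_range = mean_count_range,
              gene_fraction_hosting = gene_fraction_hosting,
              n_protein_coding = n_protein_coding, n_lncrna = n_lncrna,
              gene_length_range = gene_length_range,
              n_trna = n_trna, n_rrna = n_rrna, n_snorna = n_snorna)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$contigs) >= 1, !is.null(names(cfg$contigs)),
            all(cfg$contigs > 0))
  if (!"chrM" %in% names(cfg$contigs))
    stop("contigs must include a chrM-like contig named 'chrM'")
  for (p in c("u5_bias", "pingpong_fraction", "gene_fraction_hosting"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (ncol(cfg$cluster_patterns) != length(cfg$stages))
    stop("cluster_patterns must have one column per stage")
  if (cfg$n_chrm_pirna_loci > cfg$n_pirna_loci)
    stop("n_chrm_pirna_loci exceeds n_pirna_loci")
  if (diff(cfg$pirna_length_range) < 0 || cfg$pirna_length_range[1] < 1)
    stop("bad pirna_length_range")
  if (cfg$pirna_locus_length_range[1] < cfg$pirna_length_range[1])
    stop("piRNA loci must be at least one read long")
  invisible(cfg)
}

# rejection-sample n non-overlapping intervals of the given lengths on one
# contig, avoiding `occupied`; strand sampled unless given
place_intervals <- function(chrom, contig_len, lengths, occupied = NULL,
                            strand = NULL, max_tries = 2000L,
                            seqinfo = NULL) {
  placed <- IRanges()
  occ <- if (is.null(occupied)) IRanges() else occupied
  starts <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    if (len > contig_len) stop("feature length ", len, " exceeds ", chrom)
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(contig_len - len + 1L, 1L)
      cand <- IRanges(s, s + len - 1L)
      if (!any(IRanges::overlapsAny(cand, occ)) &&
          !any(IRanges::overlapsAny(cand, placed))) {
        starts[i] <- s; placed <- c(placed, cand); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place feature of length ", len, " on ", chrom,
                  " after ", max_tries, " tries (contig too crowded)")
  }
  if (is.null(strand))
    strand <- sample(c("+", "-"), length(lengths), replace = TRUE)
  if (length(lengths) == 0)
    return(GRanges(seqinfo = seqinfo))
  GRanges(chrom, IRanges(starts, width = lengths), strand = strand,
          seqinfo = seqinfo)
}

ann_granges <- function(gr, ids, cls, contigs) {
  mcols(gr) <- DataFrame(feature_id = ids,
                         feature_class = factor(cls,
                                                levels = FEATURE_CLASSES))
  names(gr) <- ids
  seqlevels(gr) <- names(contigs)
  seqlengths(gr) <- contigs
  gr
}

#' Build a toy genome with layered annotations and planted truth
#'
#' Generates random contig sequences plus three annotation layers mirroring
#' the databases a real run consumes: a piRNA locus catalog (piRBase-like),
#' a nuclear ncRNA exclusion set (DASHR-like: tRNA/rRNA/snoRNA/miRNA), and
#' gene models with biotypes (GENCODE-like: protein-coding, lncRNA, and the
#' chrM tRNA/rRNA genes). The chrM tRNA/rRNA features are deliberately
#' *absent* from the ncRNA exclusion layer, so piRNA loci planted inside
#' them survive the subtraction filter - the annotation leak-through
#' scenario the pipeline must expose.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (DNAStringSet), `pirna`, `ncrna`, `genes`
#'   (annotation GRanges), `truth_loci` (data.frame with host gene,
#'   orientation, cluster, baseline and per-stage expected means), and
#'   `mirna_means`.
#' @export
build_toy_genome <- function(config) {
  set.seed(config$seed)
  contigs <- config$contigs
  genome <- DNAStringSet(vapply(names(contigs), function(ch)
    paste(sample(c("A", "C", "G", "T"), contigs[ch], replace = TRUE),
          collapse = ""), character(1)))
  names(genome) <- names(contigs)

  si <- Seqinfo(names(contigs), unname(contigs))
  nuc <- setdiff(names(contigs), "chrM")
  # genes and nuclear ncRNAs, spread over nuclear contigs by length share
  gene_cls <- c(rep("protein_coding", config$n_protein_coding),
                rep("lncRNA", config$n_lncrna))
  gene_len <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                     length(gene_cls), replace = TRUE)
  nc_cls <- c(rep("tRNA", config$n_trna), rep("rRNA", config$n_rrna),
              rep("snoRNA", config$n_snorna))
  nc_len <- c(sample(70:90, config$n_trna, TRUE),
              sample(120:1500, config$n_rrna, TRUE),
              sample(60:150, config$n_snorna, TRUE))
  mir_len <- rep(22L, config$n_mirna_loci)

  share <- contigs[nuc] / sum(contigs[nuc])
  assign_contig <- function(n) sample(nuc, n, replace = TRUE, prob = share)
  gene_ch <- assign_contig(length(gene_cls))
  nc_ch <- assign_contig(length(nc_cls))
  mir_ch <- assign_contig(length(mir_len))

  occ <- setNames(lapply(names(contigs), function(x) IRanges()),
                  names(contigs))
  place_on <- function(ch_vec, len_vec, strand = NULL) {
    grs <- list()
    for (ch in unique(ch_vec)) {
      idx <- ch_vec == ch
      g <- place_intervals(ch, contigs[ch], len_vec[idx], occ[[ch]],
                           strand = if (is.null(strand)) NULL
                                    else strand[idx], seqinfo = si)
      occ[[ch]] <<- c(occ[[ch]], IRanges(start(g), end(g)))
      grs[[ch]] <- g
    }
    # features come out grouped by contig, in unique(ch_vec) order
    do.call(c, unname(grs))
  }
  genes_gr <- place_on(gene_ch, gene_len)
  # reorder class labels to match place_on's contig grouping
  gene_cls_g <- unlist(lapply(unique(gene_ch),
                              function(ch) gene_cls[gene_ch == ch]))
  nc_gr <- place_on(nc_ch, nc_len)
  nc_cls_g <- unlist(lapply(unique(nc_ch),
                            function(ch) nc_cls[nc_ch == ch]))
  mir_gr <- place_on(mir_ch, mir_len)

  # chrM tRNA/rRNA genes: present in gene models, absent from ncRNA layer
  chrm_cls <- c(rep("rRNA", 2L), rep("tRNA", 5L))
  chrm_len <- c(sample(800:1200, 2L, TRUE), rep(70L, 5L))
  chrm_gr <- place_intervals("chrM", contigs["chrM"], chrm_len,
                             seqinfo = si)
  occ[["chrM"]] <- c(occ[["chrM"]], IRanges(start(chrm_gr), end(chrm_gr)))

  genes_all <- c(genes_gr, chrm_gr)
  genes_ids <- c(sprintf("GENE%04d", seq_along(genes_gr)),
                 sprintf("MT-%s%d", chrm_cls, seq_along(chrm_cls)))
  genes_cls <- c(gene_cls_g, chrm_cls)
  genes_ann <- ann_granges(genes_all, genes_ids, genes_cls, contigs)

  ncrna_all <- c(nc_gr, mir_gr)
  ncrna_ids <- c(sprintf("NC%04d", seq_along(nc_gr)),
                 sprintf("MIR%04d", seq_along(mir_gr)))
  ncrna_cls <- c(nc_cls_g, rep("miRNA", length(mir_gr)))
  ncrna_ann <- ann_granges(ncrna_all, ncrna_ids, ncrna_cls, contigs)

  # piRNA loci: hosted (inside gene bodies, sense), intergenic, and chrM
  n_chrm <- config$n_chrm_pirna_loci
  n_nuclear <- config$n_pirna_loci - n_chrm
  n_hosted <- round(config$gene_fraction_hosting * n_nuclear)
  llr <- config$pirna_locus_length_range
  pir_list <- list(); host_gene <- character(0); host_class <- character(0)
  host_orient <- character(0)
  placed_pir <- setNames(lapply(names(contigs), function(x) IRanges()),
                         names(contigs))
  host_pool <- which(genes_cls %in% c("protein_coding", "lncRNA"))
  for (i in seq_len(n_hosted)) {
    for (t in seq_len(2000L)) {
      gi <- sample(host_pool, 1L)
      g <- genes_all[gi]
      len <- sample(llr[1]:llr[2], 1L)
      if (len > width(g)) next
      s <- start(g) + sample.int(width(g) - len + 1L, 1L) - 1L
      cand <- IRanges(s, s + len - 1L)
      ch <- as.character(seqnames(g))
      if (any(IRanges::overlapsAny(cand, placed_pir[[ch]]))) next
      pir_list[[length(pir_list) + 1L]] <-
        GRanges(ch, cand, strand = strand(g), seqinfo = si)
      placed_pir[[ch]] <- c(placed_pir[[ch]], cand)
      host_gene <- c(host_gene, genes_ids[gi])
      host_class <- c(host_class, genes_cls[gi])
      host_orient <- c(host_orient, "sense")
      break
    }
  }
  if (length(pir_list) < n_hosted)
    stop("could not place ", n_hosted, " hosted piRNA loci")
  # intergenic loci: avoid every placed feature
  n_inter <- n_nuclear - n_hosted
  inter_ch <- assign_contig(n_inter)
  for (ch in unique(inter_ch)) {
    n <- sum(inter_ch == ch)
    lens <- sample(llr[1]:llr[2], n, replace = TRUE)
    g <- place_intervals(ch, contigs[ch], lens,
                         c(occ[[ch]], placed_pir[[ch]]), seqinfo = si)
    placed_pir[[ch]] <- c(placed_pir[[ch]], IRanges(start(g), end(g)))
    for (k in seq_len(n)) pir_list[[length(pir_list) + 1L]] <- g[k]
    host_gene <- c(host_gene, rep(NA_character_, n))
    host_class <- c(host_class, rep(NA_character_, n))
    host_orient <- c(host_orient, rep(NA_character_, n))
  }
  # chrM loci: inside chrM tRNA/rRNA, sense
  for (i in seq_len(n_chrm)) {
    for (t in seq_len(2000L)) {
      gi <- sample(seq_along(chrm_cls), 1L)
      g <- chrm_gr[gi]
      len <- min(sample(llr[1]:llr[2], 1L), width(g) - 4L)
      s <- start(g) + sample.int(width(g) - len + 1L, 1L) - 1L
      cand <- IRanges(s, s + len - 1L)
      if (any(IRanges::overlapsAny(cand, placed_pir[["chrM"]]))) next
      pir_list[[length(pir_list) + 1L]] <-
        GRanges("chrM", cand, strand = strand(g), seqinfo = si)
      placed_pir[["chrM"]] <- c(placed_pir[["chrM"]], cand)
      host_gene <- c(host_gene, genes_ids[length(genes_gr) + gi])
      host_class <- c(host_class, chrm_cls[gi])
      host_orient <- c(host_orient, "sense")
      break
    }
  }
  pir_gr <- if (length(pir_list)) do.call(c, pir_list)
            else GRanges(seqinfo = si)
  pir_ids <- sprintf("piR-%04d", seq_along(pir_gr))
  pirna_ann <- ann_granges(pir_gr, pir_ids, rep("piRNA", length(pir_gr)),
                           contigs)

  # planted expression structure
  n_clusters <- nrow(config$cluster_patterns)
  cluster <- sample.int(n_clusters, length(pir_gr), replace = TRUE)
  baseline <- runif(length(pir_gr), config$mean_count_range[1],
                    config$mean_count_range[2])
  stage_means <- baseline * config$cluster_patterns[cluster, , drop = FALSE]
  colnames(stage_means) <- paste0("mean_", config$stages)
  truth_loci <- data.frame(feature_id = pir_ids,
                           chrom = as.character(seqnames(pir_gr)),
                           start = start(pir_gr), end = end(pir_gr),
                           strand = as.character(strand(pir_gr)),
                           host_gene = host_gene, host_class = host_class,
                           orientation = host_orient,
                           cluster = cluster, baseline = baseline,
                           stage_means, stringsAsFactors = FALSE)
  mirna_means <- setNames(runif(length(mir_gr), config$mirna_mean_range[1],
                                config$mirna_mean_range[2]),
                          ncrna_ids[length(nc_gr) + seq_along(mir_gr)])
  list(genome = genome, pirna = pirna_ann, ncrna = ncrna_ann,
       genes = genes_ann, truth_loci = truth_loci,
       mirna_means = mirna_means, config = config)
}

# vectorized sequence lookup, read-strand oriented
extract_read_seq <- function(genome, chrom, start, end, strand) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- Biostrings::extractAt(genome[[ch]],
                               IRanges(start[idx], end[idx]))
    s <- as.character(v)
    neg <- strand[idx] == "-"
    if (any(neg))
      s[neg] <- as.character(reverseComplement(DNAStringSet(s[neg])))
    out[idx] <- s
  }
  out
}

#' Simulate per-sample aligned reads with ground truth
#'
#' Draws read counts per piRNA locus and sample from a negative binomial
#' (variance mu + alpha*mu^2) whose mean follows the locus's planted stage
#' template, then materializes reads: piRNA reads of 24-34 nt with the
#' configured 5'U bias; optional antisense ping-pong partners with an exact
#' 10-nt 5'-5' overlap; 20-23 nt miRNA reads; and 18-40 nt degradation
#' fragments scattered sense-strand over ncRNA and gene bodies (chrM
#' tRNA/rRNA boosted). Every read is tagged with its originating component
#' and locus so downstream recovery can be scored exactly.
#'
#' @param config a [simulation_config()].
#' @param geno output of [build_toy_genome()].
#' @return list with `reads` (GRanges; mcols `seq`, `sample_id`,
#'   `component`, `locus_id`) and `samples` (sample sheet data.frame).
#' @export
simulate_reads <- function(config, geno) {
  set.seed(config$seed + 1L)
  contigs <- config$contigs
  sinfo <- Seqinfo(names(contigs), unname(contigs))
  stages <- config$stages
  alpha <- config$nb_dispersion
  size <- if (alpha > 0) 1 / alpha else Inf
  lr <- config$pirna_length_range
  pir <- geno$pirna
  truth <- geno$truth_loci
  samples <- expand.grid(replicate = seq_len(config$replicates_per_stage),
                         stage = stages, stringsAsFactors = FALSE)
  samples <- samples[c("stage", "replicate")]
  samples$sample_id <- paste0(samples$stage, samples$replicate)
  samples$stage <- factor(samples$stage, levels = stages)

  mir <- geno$ncrna[geno$ncrna$feature_class == "miRNA"]
  deg_src <- c(geno$ncrna[geno$ncrna$feature_class != "miRNA"], geno$genes)
  deg_rate <- config$degradation_rate * width(deg_src) / 1000
  is_chrm_nc <- as.character(seqnames(deg_src)) == "chrM" &
    deg_src$feature_class %in% c("tRNA", "rRNA")
  deg_rate[is_chrm_nc] <- deg_rate[is_chrm_nc] * config$chrm_degradation_factor

  all_reads <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    st <- as.character(samples$stage[si])
    mu <- truth[[paste0("mean_", st)]]
    n_i <- if (is.finite(size)) rnbinom(length(pir), mu = mu, size = size)
           else rpois(length(pir), mu)
    li <- rep(seq_along(pir), n_i)
    # piRNA reads
    if (length(li)) {
      lw <- width(pir)[li]
      rl <- pmin(lr[1] + floor(runif(length(li)) * (lr[2] - lr[1] + 1L)),
                 lw)
      rch <- as.character(seqnames(pir))[li]
      rstr <- as.character(strand(pir))[li]
      # piRNA 5' ends are sharply defined: anchor reads at the locus 5'
      # end, with length heterogeneity at the 3' end only
      rs <- ifelse(rstr == "+", start(pir)[li], end(pir)[li] - rl + 1L)
      re <- rs + rl - 1L
      sq <- extract_read_seq(geno$genome, rch, rs, re, rstr)
      # 5' base drawn from the bias distribution: U w.p. u5_bias, else A/C/G
      u <- runif(length(sq)) < config$u5_bias
      b5 <- ifelse(u, "T", sample(c("A", "C", "G"), length(sq),
                                  replace = TRUE))
      substr(sq, 1L, 1L) <- b5
      pr <- GRanges(rch, IRanges(rs, re), strand = rstr, seqinfo = sinfo)
      mcols(pr) <- DataFrame(seq = sq, sample_id = sid,
                             component = "pirna",
                             locus_id = pir$feature_id[li])
      # ping-pong partners: antisense read, 5'-5' overlap exactly 10 nt
      if (config$pingpong_fraction > 0) {
        pp <- which(runif(length(pr)) < config$pingpong_fraction)
        if (length(pp)) {
          p5 <- ifelse(rstr[pp] == "+", rs[pp], re[pp])
          l2 <- lr[1] + floor(runif(length(pp)) * (lr[2] - lr[1] + 1L))
          plus <- rstr[pp] == "+"
          # partner on '-' has its 5' (end) at p5 + 9; on '+' at p5 - 9
          ps <- ifelse(plus, p5 + 9L - l2 + 1L, p5 - 9L)
          pe <- ps + l2 - 1L
          pstr <- ifelse(plus, "-", "+")
          okb <- ps >= 1L & pe <= contigs[rch[pp]]
          if (any(okb)) {
            idx <- pp[okb]
            pg <- GRanges(rch[idx], IRanges(ps[okb], pe[okb]),
                          strand = pstr[okb], seqinfo = sinfo)
            sq2 <- extract_read_seq(geno$genome, rch[idx], ps[okb],
                                    pe[okb], pstr[okb])
            mcols(pg) <- DataFrame(seq = sq2, sample_id = sid,
                                   component = "pingpong",
                                   locus_id = pir$feature_id[li[idx]])
            pr <- c(pr, pg)
          }
        }
      }
      all_reads[[length(all_reads) + 1L]] <- pr
    }
    # miRNA background (20-23 nt)
    if (length(mir)) {
      n_m <- if (is.finite(size))
        rnbinom(length(mir), mu = geno$mirna_means, size = size)
      else rpois(length(mir), geno$mirna_means)
      mi <- rep(seq_along(mir), n_m)
      if (length(mi)) {
        mw <- width(mir)[mi]
        rl <- pmin(20L + floor(runif(length(mi)) * 4L), mw)
        off <- floor(runif(length(mi)) * (mw - rl + 1L))
        rs <- start(mir)[mi] + off
        re <- rs + rl - 1L
        rch <- as.character(seqnames(mir))[mi]
        rstr <- as.character(strand(mir))[mi]
        mg <- GRanges(rch, IRanges(rs, re), strand = rstr, seqinfo = sinfo)
        mcols(mg) <- DataFrame(
          seq = extract_read_seq(geno$genome, rch, rs, re, rstr),
          sample_id = sid, component = "mirna",
          locus_id = mir$feature_id[mi])
        all_reads[[length(all_reads) + 1L]] <- mg
      }
    }
    # degradation fragments (18-40 nt, sense over feature bodies)
    n_d <- rpois(length(deg_src), deg_rate)
    di <- rep(seq_along(deg_src), n_d)
    if (length(di)) {
      dw <- width(deg_src)[di]
      rl <- pmin(18L + floor(runif(length(di)) * 23L), dw)
      off <- floor(runif(length(di)) * (dw - rl + 1L))
      rs <- start(deg_src)[di] + off
      re <- rs + rl - 1L
      rch <- as.character(seqnames(deg_src))[di]
      rstr <- as.character(strand(deg_src))[di]
      dg <- GRanges(rch, IRanges(rs, re), strand = rstr, seqinfo = sinfo)
      mcols(dg) <- DataFrame(
        seq = extract_read_seq(geno$genome, rch, rs, re, rstr),
        sample_id = sid, component = "degradation",
        locus_id = deg_src$feature_id[di])
      all_reads[[length(all_reads) + 1L]] <- dg
    }
    # unannotated genomic background, both strands
    n_b <- rpois(length(contigs), config$background_per_kb * contigs / 1000)
    bi <- rep(seq_along(contigs), n_b)
    if (length(bi)) {
      rl <- 18L + floor(runif(length(bi)) * 23L)
      rs <- 1L + floor(runif(length(bi)) * (contigs[bi] - rl + 1L))
      re <- rs + rl - 1L
      rch <- names(contigs)[bi]
      rstr <- sample(c("+", "-"), length(bi), replace = TRUE)
      bg <- GRanges(rch, IRanges(rs, re), strand = rstr, seqinfo = sinfo)
      mcols(bg) <- DataFrame(
        seq = extract_read_seq(geno$genome, rch, rs, re, rstr),
        sample_id = sid, component = "background",
        locus_id = NA_character_)
      all_reads[[length(all_reads) + 1L]] <- bg
    }
  }
  reads <- do.call(c, all_reads)
  names(reads) <- sprintf("read%07d", seq_along(reads))
  list(reads = reads, samples = samples)
}

#' Generate a full synthetic dataset, optionally writing files
#'
#' Runs [build_toy_genome()] and [simulate_reads()] under one seed and, when
#' `dir` is given, writes everything in standard text formats: `genome.fa`,
#' `pirna.bed`, `ncrna.bed`, `genes.gtf`, one `<sample>.bed` (BED6 + a
#' seventh sequence column) per sample, `sample_sheet.tsv`,
#' `truth_loci.tsv` and `truth_reads.tsv`.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory (created if missing).
#' @return (invisibly when writing) list with the genome bundle, `reads`,
#'   `samples`, and `dir`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  geno <- build_toy_genome(config)
  sim <- simulate_reads(config, geno)
  out <- c(geno, sim, list(dir = dir))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(geno$genome, file.path(dir, "genome.fa"))
    write_annotations_bed(geno$pirna, file.path(dir, "pirna.bed"))
    write_annotations_bed(geno$ncrna, file.path(dir, "ncrna.bed"))
    write_genes_gtf(geno$genes, file.path(dir, "genes.gtf"))
    ss <- sim$samples
    ss$path <- paste0(ss$sample_id, ".bed")  # relative to the sheet
    for (sid in ss$sample_id)
      write_reads_bed(sim$reads[sim$reads$sample_id == sid],
                      file.path(dir, paste0(sid, ".bed")))
    write.table(ss, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_table(geno$truth_loci, file.path(dir, "truth_loci.tsv"),
                key = "feature_id")
    tr <- data.frame(read_id = names(sim$reads),
                     sample_id = sim$reads$sample_id,
                     component = sim$reads$component,
                     locus_id = sim$reads$locus_id)
    write_table(tr, file.path(dir, "truth_reads.tsv"), key = "read_id")
    return(invisible(out))
  }
  out
}

#' Ground-truth expressed sets implied by a simulation
#'
#' For each stage, the loci whose planted expected mean count meets the
#' expressed-set threshold.
#'
#' @param geno output of [build_toy_genome()].
#' @param min_mean threshold on the planted stage mean (default 3).
#' @return named list of feature-id character vectors, one per stage.
#' @export
truth_expressed_sets <- function(geno, min_mean = 3) {
  stages <- geno$config$stages
  setNames(lapply(stages, function(st)
    geno$truth_loci$feature_id[
      geno$truth_loci[[paste0("mean_", st)]] >= min_mean]), stages)
}
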