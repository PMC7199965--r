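#' Build a validated pipeline configuration
#'
#' All analysis parameters at their study defaults: 24-34 nt length
#' window, strand-specific ncRNA subtraction, expressed-set threshold
#' mean >= 3, DE thresholds |log2FC| >= 1 with p < 0.05 and fdr < 0.1,
#' fuzzy c-means with c = 8 and m = 1.15, and 1500 interval shuffles for
#' the gene-origin enrichment null. Unknown keys are rejected.
#'
#' @param sim a [simulation_config()] describing the synthetic inputs.
#' @param min_len,max_len read-length window, nt.
#' @param min_overlap_frac minimum same-strand overlap fraction for ncRNA
#'   subtraction (0 = any overlap).
#' @param min_mean expressed-set threshold on stage-mean raw counts.
#' @param lfc_cut,p_cut,fdr_cut differential-expression thresholds.
#' @param n_clusters,fuzzifier fuzzy c-means parameters.
#' @param n_shuffles shuffles for the enrichment null.
#' @param seed global seed; stage-specific seeds are derived from it.
#' @param ... rejected (guards against typos).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            min_len = 24L, max_len = 34L,
                            min_overlap_frac = 0,
                            min_mean = 3,
                            lfc_cut = 1, p_cut = 0.05, fdr_cut = 0.1,
                            n_clusters = 8L, fuzzifier = 1.15,
                            n_shuffles = 1500L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline_config key(s): ",
         paste(names(extra), collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, min_len = min_len, max_len = max_len,
                 min_overlap_frac = min_overlap_frac, min_mean = min_mean,
                 lfc_cut = lfc_cut, p_cut = p_cut, fdr_cut = fdr_cut,
                 n_clusters = n_clusters, fuzzifier = fuzzifier,
                 n_shuffles = n_shuffles, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full piRNA discovery pipeline on synthetic data
#'
#' simulate -> filter -> count -> expressed sets -> differential
#' expression (all later-vs-earlier stage contrasts) -> soft clustering ->
#' biogenesis signatures -> genomic context, writing every stage's tables
#' under `out_dir` plus a JSON manifest with the configuration digest and
#' per-file checksums. Re-running with the same configuration and seed
#' reproduces a byte-identical output tree.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  sim <- simulate_dataset(config$sim, dir = file.path(out_dir, "sim"))
  res$sim <- sim

  fc <- filter_cascade(sim$reads, sim$ncrna, config$min_len,
                       config$max_len,
                       min_overlap_frac = config$min_overlap_frac)
  write_table(fc$report, file.path(out_dir, "filter_report.tsv"),
              key = "sample_id")
  write_table(length_density(sim$reads),
              file.path(out_dir, "length_density_unfiltered.tsv"),
              key = c("sample_id", "length"))
  res$filtered <- fc

  counts <- count_reads(fc$reads, sim$pirna, sim$samples)
  cnt_df <- data.frame(feature_id = rownames(counts$counts),
                       counts$counts, check.names = FALSE)
  write_table(cnt_df, file.path(out_dir, "counts.tsv"), key = "feature_id")
  res$counts <- counts

  expr <- call_expressed(counts, config$min_mean)
  flags <- data.frame(feature_id = expr$union)
  for (st in names(expr$stage_sets))
    flags[[st]] <- as.integer(flags$feature_id %in% expr$stage_sets[[st]])
  write_table(flags, file.path(out_dir, "expressed_sets.tsv"),
              key = "feature_id")
  write_table(set_overlaps(expr), file.path(out_dir, "set_overlaps.tsv"),
              key = "combination")
  res$expressed <- expr

  norm <- cpm_normalize(counts)
  stages <- levels(sim$samples$stage)
  contrasts <- list(); cors <- list()
  for (i in seq_along(stages)) for (j in seq_along(stages)) {
    if (j <= i) next
    pair <- c(stages[i], stages[j])
    tag <- paste0(pair[2], "_vs_", pair[1])
    de <- classify_de(nb_test(counts, pair), config$lfc_cut,
                      config$p_cut, config$fdr_cut)
    write_table(de, file.path(out_dir, paste0("de_", tag, ".tsv")),
                key = "feature_id")
    contrasts[[tag]] <- de
    if (length(expr$union) >= 3)
      cors[[tag]] <- stage_correlation(norm, sim$samples, pair,
                                       features = expr$union)
  }
  res$de <- contrasts
  if (length(cors)) {
    cor_df <- do.call(rbind, cors)
    write_table(cor_df, file.path(out_dir, "stage_correlations.tsv"),
                key = c("stage_a", "stage_b"))
    res$correlations <- cor_df
  }

  # soft clustering of the expressed catalog
  memb_df <- data.frame(feature_id = character(0))
  if (length(expr$union) >= config$n_clusters) {
    z <- standardize_trajectories(norm, sim$samples, expr$union)
    if (nrow(z) >= config$n_clusters) {
      fit <- fuzzy_cmeans(z, c = config$n_clusters, m = config$fuzzifier,
                          seed = config$seed)
      lab <- assign_clusters(fit)
      memb_df <- data.frame(feature_id = rownames(fit$membership),
                            fit$membership,
                            cluster = ifelse(is.na(lab), 0L, lab),
                            check.names = FALSE)
      write_table(data.frame(cluster = rownames(fit$centers),
                             fit$centers, check.names = FALSE),
                  file.path(out_dir, "cluster_centers.tsv"),
                  key = "cluster")
      res$clustering <- fit
    }
  }
  write_table(memb_df, file.path(out_dir, "cluster_memberships.tsv"),
              key = "feature_id")

  # biogenesis signatures on reads at piRNA loci
  pir_reads <- subsetByOverlaps(fc$reads, sim$pirna, ignore.strand = FALSE)
  if (length(pir_reads)) {
    write_table(base_frequency(pir_reads),
                file.path(out_dir, "base_frequency.tsv"), key = "position")
    pp <- pingpong_profile(fc$reads)
    write_table(pp$histogram, file.path(out_dir, "pingpong_histogram.tsv"),
                key = "overlap")
    write_table(coverage_profile(fc$reads, sim$pirna,
                                 total_reads = length(fc$reads)),
                file.path(out_dir, "coverage_profile.tsv"),
                key = "position")
    res$pingpong <- pp
    res$base_frequency <- base_frequency(pir_reads)
  }

  # genomic context of the expressed catalog
  expressed_loci <- sim$pirna[sim$pirna$feature_id %in% expr$union]
  host_genes <- sim$genes[sim$genes$feature_class %in%
                            c("protein_coding", "lncRNA")]
  if (length(expressed_loci)) {
    hosts <- assign_hosts(expressed_loci, sim$genes)
    write_table(hosts, file.path(out_dir, "host_assignment.tsv"),
                key = "pirna_id")
    res$hosts <- hosts
    sh <- shuffle_null(expressed_loci, config$sim$contigs, host_genes,
                       n_shuffles = config$n_shuffles,
                       seed = config$seed + 2L)
    fe <- fold_enrichment(sh)
    write_table(fe, file.path(out_dir, "enrichment.tsv"),
                key = c("gene_class", "orientation"))
    res$enrichment <- fe
    hosting_ids <- unique(hosts$gene_id[!is.na(hosts$gene_id) &
                                          hosts$orientation == "sense" &
                                          hosts$gene_class %in%
                                            c("protein_coding", "lncRNA")])
    hosting <- sim$genes[sim$genes$feature_id %in% hosting_ids]
    if (length(hosting)) {
      gc_s <- gene_coverage(fc$reads, hosting, "sense")
      gc_a <- gene_coverage(fc$reads, hosting, "antisense")
      gc <- data.frame(gene_id = gc_s$gene_id,
                       pct_sense = gc_s$percent_covered,
                       pct_antisense = gc_a$percent_covered)
      write_table(gc, file.path(out_dir, "gene_coverage.tsv"),
                  key = "gene_id")
      res$gene_coverage <- gc
    }
    ppg <- pirnas_per_gene(hosts)
    write_table(ppg, file.path(out_dir, "pirnas_per_gene.tsv"),
                key = "gene_id")
    res$pirnas_per_gene <- ppg
    write_table(pirnas_per_chromosome(sim$pirna, expr$union),
                file.path(out_dir, "pirnas_per_chromosome.tsv"),
                key = "chrom")
  }

  manifest <- run_manifest(config, out_dir)
  res$manifest <- manifest
  invisible(res)
}

# configuration digest + per-file checksums; no timestamps, so identical
# runs yield identical manifests
run_manifest <- function(config, out_dir) {
  cfg_chr <- jsonlite::serializeJSON(unclass(config))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package = "pirdisco",
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(
                     {tf <- tempfile(); writeLines(cfg_chr, tf); tf})),
                   files = setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
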