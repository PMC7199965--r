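test_that("host assignment resolves orientation and intergenic status", {
  genes <- make_annotations(c("chr1", "chr1"), c(1000, 5000),
                            c(3000, 7000), c("+", "-"),
                            c("G1", "G2"),
                            c("protein_coding", "lncRNA"))
  pir <- make_annotations(c("chr1", "chr1", "chr2"),
                          c(1500, 5500, 100), c(1560, 5560, 160),
                          c("+", "+", "+"),
                          c("piR-1", "piR-2", "piR-3"), rep("piRNA", 3))
  h <- assign_hosts(pir, genes)
  expect_equal(h$orientation[h$pirna_id == "piR-1"], "sense")
  expect_equal(h$orientation[h$pirna_id == "piR-2"], "antisense")
  expect_true(is.na(h$gene_id[h$pirna_id == "piR-3"]))
  expect_equal(attr(h, "pct_genic"), 100 * 2 / 3)
})

test_that("shuffle null demands shuffles and saturates on tiled genes", {
  genes <- make_annotations("chr1", 1, 10000, "+", "G1", "protein_coding")
  pir <- make_annotations("chr1", c(100, 700), c(160, 760), "+",
                          c("piR-1", "piR-2"), rep("piRNA", 2))
  expect_error(shuffle_null(pir, c(chr1 = 10000L), genes, n_shuffles = 0),
               "n_shuffles")
  sh <- shuffle_null(pir, c(chr1 = 10000L), genes, n_shuffles = 50,
                     seed = 1)
  # a gene tiling the whole contig intersects every shuffled piRNA in sense
  expect_true(all(sh$null[, "protein_coding", "sense"] == 2))
})

test_that("null intersection rate matches the binomial placement oracle", {
  # one gene covering fraction f = 0.1 of the contig, same strand as piRNAs
  L <- 100000L
  genes <- make_annotations("chr1", 20001, 30000, "+", "G1",
                            "protein_coding")
  n_pir <- 60
  starts <- seq(50, 90000, length.out = n_pir)
  pir <- make_annotations("chr1", starts, starts + 29, "+",
                          sprintf("piR-%02d", 1:n_pir), rep("piRNA", n_pir))
  sh <- shuffle_null(pir, c(chr1 = L), genes, n_shuffles = 1000, seed = 2)
  nm <- mean(sh$null[, "protein_coding", "sense"])
  # uniform placement: P(hit) ~ (gene + read - 1) / (L - read + 1)
  p_hit <- (10000 + 30 - 1) / (L - 30 + 1)
  se <- sqrt(n_pir * p_hit * (1 - p_hit) / 1000)
  expect_lt(abs(nm - n_pir * p_hit), 3 * se + 0.2)
})

test_that("fold enrichment is 0 at the null mean and -Inf at observed 0", {
  null <- array(5L, dim = c(100, 1, 2),
                dimnames = list(NULL, "protein_coding",
                                c("sense", "antisense")))
  null[, 1, 1] <- rpois(100, 5) + 1L
  obs <- matrix(c(round(mean(null[, 1, 1])), 0L), 1, 2,
                dimnames = dimnames(null)[2:3])
  fe <- fold_enrichment(list(null = null, observed = obs))
  sense <- fe[fe$orientation == "sense", ]
  expect_lt(abs(sense$log2_fold_enrichment), 0.05)
  anti <- fe[fe$orientation == "antisense", ]
  expect_equal(anti$log2_fold_enrichment, -Inf)
  expect_equal(anti$p_emp, 1)
  expect_true(all(fe$p_emp > 0 & fe$p_emp <= 1))
})

test_that("gene coverage uses union semantics", {
  gene <- make_annotations("chr1", 1001, 2000, "+", "G1", "protein_coding")
  r <- make_reads("chr1", 1101, 50, "+")
  gc <- gene_coverage(r, gene, "sense")
  expect_equal(gc$percent_covered, 5.0)
  # duplicate read never changes the percent
  gc2 <- gene_coverage(c(r, r), gene, "sense")
  expect_equal(gc2$percent_covered, 5.0)
  # antisense orientation counts opposite-strand reads
  expect_equal(gene_coverage(r, gene, "antisense")$percent_covered, 0)
  r_anti <- make_reads("chr1", 1101, 50, "-")
  expect_equal(gene_coverage(r_anti, gene, "antisense")$percent_covered, 5.0)
})

test_that("gene coverage equals a per-base bitmap oracle", {
  gene <- make_annotations("chrA", 5001, 15000, "+", "G1", "protein_coding")
  reads <- random_reads(2000, seed = 51, contigs = c(chrA = 20000L))
  gc <- gene_coverage(reads, gene, "sense")
  bitmap <- logical(10000)
  same <- as.character(strand(reads)) == "+"
  for (i in which(same)) {
    a <- max(start(reads)[i], 5001); b <- min(end(reads)[i], 15000)
    if (a <= b) bitmap[(a:b) - 5000] <- TRUE
  }
  expect_equal(gc$percent_covered, 100 * sum(bitmap) / 10000)
})

test_that("sense piRNAs per gene tally and bin correctly", {
  hosts <- data.frame(
    pirna_id = sprintf("piR-%02d", 1:16),
    gene_id = c(rep("MALAT1like", 12), "G2", "G2", "G3", "G4"),
    gene_class = "lncRNA",
    orientation = c(rep("sense", 14), "antisense", "sense"))
  ppg <- pirnas_per_gene(hosts)
  expect_equal(ppg$n_pirnas[ppg$gene_id == "MALAT1like"], 12L)
  expect_false("G3" %in% ppg$gene_id)  # antisense only
  expect_equal(unname(attr(ppg, "histogram")),
               c(1L, 1L, 0L, 1L))  # one single, one pair, one >= 4
  # group-by oracle on random assignments
  set.seed(52)
  h2 <- data.frame(pirna_id = sprintf("p%03d", 1:200),
                   gene_id = sample(sprintf("g%02d", 1:40), 200, TRUE),
                   gene_class = "protein_coding",
                   orientation = sample(c("sense", "antisense"), 200, TRUE))
  ppg2 <- pirnas_per_gene(h2)
  oracle <- table(h2$gene_id[h2$orientation == "sense"])
  expect_equal(sum(ppg2$n_pirnas), sum(oracle))
  expect_equal(sort(ppg2$n_pirnas), sort(as.integer(oracle)))
})

test_that("overrepresentation follows the hypergeometric closed form", {
  universe <- sprintf("g%02d", 1:20)
  query <- universe[1:5]
  sets <- list(hit = universe[1:5], miss = universe[11:15])
  ora <- overrepresentation(query, sets, universe)
  # all 5 of 5 drawn: p = 1 / C(20,5)
  expect_equal(ora$p[ora$gene_set_id == "hit"], 1 / choose(20, 5))
  expect_equal(ora$p[ora$gene_set_id == "miss"], 1)
  # query = universe forces k = K, p = 1 for every set
  ora2 <- overrepresentation(universe, sets, universe)
  expect_true(all(ora2$p == 1))
  expect_error(overrepresentation(character(0), sets, universe), "query")
  expect_error(overrepresentation(c("zz"), sets, universe), "outside")
})

test_that("uniformly placed piRNAs show no enrichment; forced placement
           shows log2(1/f)", {
  set.seed(53)
  L <- 200000L
  # genes all on '+' covering exactly 1/8 of the contig
  gstart <- seq(1, L, by = 16000)
  genes <- make_annotations("chr1", gstart, gstart + 1999, "+",
                            sprintf("G%02d", seq_along(gstart)),
                            rep("protein_coding", length(gstart)))
  # uniform piRNAs
  n <- 100
  ps <- 1L + floor(runif(n) * (L - 30))
  pir_u <- make_annotations("chr1", ps, ps + 29, "+",
                            sprintf("piR-%03d", 1:n), rep("piRNA", n))
  fe_u <- suppressWarnings(fold_enrichment(
    shuffle_null(pir_u, c(chr1 = L), genes, n_shuffles = 300, seed = 3,
                 classes = "protein_coding")))
  v <- fe_u$log2_fold_enrichment[fe_u$gene_class == "protein_coding" &
                                   fe_u$orientation == "sense"]
  expect_lt(abs(v), 0.35)  # single-seed check; 20-seed mean is tighter
  # every piRNA inside a gene, sense
  gi <- sample(length(genes), n, TRUE)
  ps2 <- start(genes)[gi] + floor(runif(n) * (width(genes)[gi] - 30))
  pir_f <- make_annotations("chr1", ps2, ps2 + 29, "+",
                            sprintf("piR-%03d", 1:n), rep("piRNA", n))
  fe_f <- suppressWarnings(fold_enrichment(
    shuffle_null(pir_f, c(chr1 = L), genes, n_shuffles = 300, seed = 4,
                 classes = "protein_coding")))
  v2 <- fe_f$log2_fold_enrichment[fe_f$gene_class == "protein_coding" &
                                    fe_f$orientation == "sense"]
  expect_lt(abs(v2 - 3), 0.3)
})

test_that("per-chromosome tallies sum to the catalog size", {
  out <- simulate_dataset(fast_sim_config(seed = 61))
  ids <- out$truth_loci$feature_id[1:50]
  tab <- pirnas_per_chromosome(out$pirna, ids)
  expect_equal(sum(tab$n), 50L)
})
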