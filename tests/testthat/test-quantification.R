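one_stage_samples <- function() {
  data.frame(sample_id = "s1", stage = factor("PSC"), replicate = 1L)
}

test_that("reads are assigned to the largest same-strand overlap,
           ties to the smallest feature_id", {
  pir <- make_annotations(c("chr1", "chr1"), c(100, 145), c(150, 200),
                          c("+", "+"), c("piR-A", "piR-B"),
                          c("piRNA", "piRNA"))
  samples <- one_stage_samples()
  # inside piR-A only
  cm <- count_reads(make_reads("chr1", 110, 30, "+"), pir, samples)
  expect_equal(cm$counts["piR-A", "s1"], 1L)
  expect_equal(cm$counts["piR-B", "s1"], 0L)
  # overlaps piR-A by 20 bp (131..150) and piR-B by 6 bp (145..150)
  cm2 <- count_reads(make_reads("chr1", 131, 25, "+"), pir, samples)
  expect_equal(cm2$counts["piR-A", "s1"], 1L)
  expect_equal(cm2$counts["piR-B", "s1"], 0L)
  # opposite strand -> unassigned
  cm3 <- count_reads(make_reads("chr1", 110, 30, "-"), pir, samples)
  expect_equal(sum(cm3$counts), 0L)
  expect_equal(unname(cm3$unassigned["s1"]), 1L)
  # exact tie on two loci -> lexicographically smaller id
  pir_tie <- make_annotations(c("chr1", "chr1"), c(100, 100), c(150, 150),
                              c("+", "+"), c("piR-Z", "piR-A"),
                              c("piRNA", "piRNA"))
  cm4 <- count_reads(make_reads("chr1", 110, 30, "+"), pir_tie, samples)
  expect_equal(cm4$counts["piR-A", "s1"], 1L)
  expect_equal(cm4$counts["piR-Z", "s1"], 0L)
})

test_that("ambiguous_drop mode discards multi-locus reads", {
  pir <- make_annotations(c("chr1", "chr1"), c(100, 120), c(150, 170),
                          c("+", "+"), c("piR-A", "piR-B"),
                          c("piRNA", "piRNA"))
  r <- make_reads("chr1", 125, 30, "+")  # overlaps both
  cm <- count_reads(r, pir, one_stage_samples(), mode = "ambiguous_drop")
  expect_equal(sum(cm$counts), 0L)
  cm2 <- count_reads(r, pir, one_stage_samples())
  expect_equal(sum(cm2$counts), 1L)
})

test_that("counts equal the all-pairs overlap-assignment oracle", {
  set.seed(12)
  n_loci <- 80
  starts <- sort(sample(seq(1, 45000, by = 60), n_loci))
  pir <- make_annotations("chrA", starts, starts + sample(30:80, n_loci, TRUE),
                          sample(c("+", "-"), n_loci, TRUE),
                          sprintf("piR-%03d", sample(n_loci)),
                          rep("piRNA", n_loci))
  reads <- random_reads(5000, seed = 13, contigs = c(chrA = 50000L))
  reads <- filter_by_length(reads)
  cm <- count_reads(reads, pir, one_stage_samples())
  # oracle: per read, overlap width with every same-strand locus
  oracle <- setNames(rep(0L, n_loci), sort(pir$feature_id))
  for (i in seq_along(reads)) {
    ov <- pmin(end(reads)[i], end(pir)) - pmax(start(reads)[i], start(pir)) + 1
    ov[as.character(strand(pir)) != as.character(strand(reads))[i]] <- 0
    ov[as.character(seqnames(pir)) != as.character(seqnames(reads))[i]] <- 0
    ov[ov < 0] <- 0
    if (max(ov) > 0) {
      cand <- pir$feature_id[ov == max(ov)]
      best <- sort(cand)[1]
      oracle[best] <- oracle[best] + 1L
    }
  }
  expect_equal(cm$counts[, "s1"], oracle)
  expect_equal(sum(cm$counts) + sum(cm$unassigned), length(reads))
})

test_that("CPM matches the closed formula and rejects empty libraries", {
  counts <- matrix(c(2L, 0L, 8L, 10L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- cpm_normalize(counts)
  expect_equal(cpm["a", "s1"], 2 / 2 * 1e6)
  expect_equal(cpm, sweep(counts, 2, colSums(counts), "/") * 1e6)
  bad <- counts; bad[, 1] <- 0L
  expect_error(cpm_normalize(bad), "s1")
  # rank order within a column is preserved
  set.seed(1)
  m <- matrix(rpois(300, 20), 100, 3,
              dimnames = list(sprintf("f%03d", 1:100), c("x", "y", "z")))
  cp <- cpm_normalize(m)
  for (j in 1:3) expect_equal(order(cp[, j]), order(m[, j]))
})

test_that("post-filter library size includes unassigned reads", {
  pir <- make_annotations("chr1", 100, 150, "+", "piR-A", "piRNA")
  reads <- c(make_reads("chr1", 110, 30, "+"),
             make_reads("chr1", 5000, 30, "+"))  # second is unassigned
  cm <- count_reads(reads, pir, one_stage_samples())
  expect_equal(cpm_normalize(cm)["piR-A", "s1"], 1 / 2 * 1e6)
  expect_equal(cpm_normalize(cm, library = "assigned")["piR-A", "s1"], 1e6)
})

test_that("expressed-set calling applies the stage-mean threshold at >= 3", {
  samples <- make_samples(stages = c("PSC", "MPC"), reps = 3)
  counts <- matrix(0L, 2, 6,
                   dimnames = list(c("piR-A", "piR-B"), samples$sample_id))
  counts["piR-A", c("PSC1", "PSC2", "PSC3")] <- c(2L, 3L, 4L)  # mean 3.0
  counts["piR-B", c("PSC1", "PSC2", "PSC3")] <- c(0L, 0L, 8L)  # mean 2.67
  x <- structure(list(counts = counts, samples = samples,
                      unassigned = setNames(rep(0L, 6), samples$sample_id)),
                 class = "pirna_counts")
  ex <- call_expressed(x)
  expect_true("piR-A" %in% ex$stage_sets$PSC)
  expect_false("piR-B" %in% ex$stage_sets$PSC)
  expect_equal(ex$stage_sets$MPC, character(0))
  expect_equal(ex$union, "piR-A")
})

test_that("raising min_mean never grows any stage set", {
  out <- simulate_dataset(fast_sim_config(seed = 9))
  cm <- count_reads(filter_cascade(out$reads, out$ncrna)$reads,
                    out$pirna, out$samples)
  prev <- call_expressed(cm, 1)
  for (mm in c(3, 10, 30)) {
    cur <- call_expressed(cm, mm)
    for (st in names(cur$stage_sets))
      expect_true(all(cur$stage_sets[[st]] %in% prev$stage_sets[[st]]))
    prev <- cur
  }
})

test_that("set overlaps follow set algebra", {
  a <- sprintf("p%02d", 1:20); b <- sprintf("p%02d", 11:30)
  ov <- set_overlaps(list(A = a, B = b))
  expect_equal(ov$n[ov$combination == "A"], 20L)
  expect_equal(ov$n[ov$combination == "A&B"], 10L)
  same <- set_overlaps(list(A = a, B = a))
  expect_equal(same$n[same$combination == "A&B"], 20L)
  dis <- set_overlaps(list(A = a, B = sprintf("q%02d", 1:5)))
  expect_equal(dis$n[dis$combination == "A&B"], 0L)
  # random sets against a brute-force oracle
  set.seed(4)
  sets <- lapply(1:3, function(i) sample(sprintf("f%03d", 1:100), 40))
  names(sets) <- c("X", "Y", "Z")
  ov3 <- set_overlaps(sets)
  expect_equal(ov3$n[ov3$combination == "X&Y&Z"],
               length(intersect(intersect(sets$X, sets$Y), sets$Z)))
})
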