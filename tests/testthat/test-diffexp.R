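nb_matrix <- function(n, mu, size, seed, samples) {
  set.seed(seed)
  matrix(rnbinom(n * nrow(samples), mu = mu, size = size), n,
         nrow(samples),
         dimnames = list(sprintf("f%04d", seq_len(n)), samples$sample_id))
}

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  sf <- size_factors(m2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  # random matrix against the direct formula
  samples <- make_samples(stages = c("A", "B"), reps = 3)
  m3 <- nb_matrix(500, 50, 20, seed = 5, samples = samples)
  lg <- rowMeans(log(m3)); keep <- is.finite(lg)
  oracle <- apply(m3[keep, ], 2, function(col) median(col / exp(lg[keep])))
  expect_equal(size_factors(m3), oracle)
  expect_error(size_factors(diag(0L, 3)), "nonzero")
})

test_that("identical conditions give log2FC 0 and large p", {
  samples <- make_samples(stages = c("A", "B"), reps = 3)
  m <- nb_matrix(100, 50, 20, seed = 1, samples = samples)
  m[, 4:6] <- m[, 1:3]  # B duplicates A exactly
  res <- nb_test(m, c("A", "B"), samples)
  expect_true(all(res$log2FC == 0))
  expect_true(all(res$p > 0.99))
})

test_that("all-zero features are reported untested", {
  samples <- make_samples(stages = c("A", "B"), reps = 3)
  m <- nb_matrix(50, 30, 20, seed = 2, samples = samples)
  m[7, ] <- 0L
  res <- nb_test(m, c("A", "B"), samples)
  expect_true(is.na(res$p[7]))
  expect_true(is.na(res$padj[7]))
  expect_false(anyNA(res$p[-7]))
  cls <- classify_de(res)
  expect_equal(cls$call[7], "untested")
})

test_that("planted four-fold effects are recovered", {
  # 10% planted effects: median-of-ratios assumes most features are not DE
  samples <- make_samples(stages = c("A", "B"), reps = 3)
  set.seed(3)
  n <- 400; true <- seq_len(40)
  muA <- rep(25, n); muB <- rep(25, n); muB[true] <- 100
  m <- cbind(matrix(rnbinom(n * 3, mu = muA, size = 20), n, 3),
             matrix(rnbinom(n * 3, mu = muB, size = 20), n, 3))
  dimnames(m) <- list(sprintf("f%04d", 1:n), samples$sample_id)
  res <- nb_test(m, c("A", "B"), samples)
  expect_lt(mean(abs(res$log2FC[true] - 2)), 0.35)
  cls <- classify_de(res)
  expect_gt(sum(cls$call[true] == "up"), 15)   # reasonable power
  expect_lt(sum(cls$call[-true] != "ns"), 10)  # few false calls
})

test_that("depth scaling leaves log2FC invariant", {
  samples <- make_samples(stages = c("A", "B"), reps = 3)
  m <- nb_matrix(200, 40, 20, seed = 4, samples = samples)
  res1 <- nb_test(m, c("A", "B"), samples)
  res2 <- nb_test(m * 5L, c("A", "B"), samples)
  # the eps pseudo-count admits a small depth-dependent perturbation at
  # low counts; estimates are otherwise depth-invariant
  expect_lt(max(abs(res1$log2FC - res2$log2FC)), 0.02)
  expect_gt(cor(res1$log2FC, res2$log2FC), 0.9999)
})

test_that("DE classification applies the dual thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    base_mean = 10,
                    log2FC = c(1.2, 0.5, -2, -1.5),
                    p = c(0.001, 0.001, 0.2, 0.01),
                    padj = c(0.01, 0.01, 0.5, 0.2))
  cls <- classify_de(res)
  expect_equal(cls$call, c("up", "ns", "ns", "ns"))
  expect_equal(unname(attr(cls, "summary")[c("up", "down")]), c(1L, 0L))
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
  set.seed(6)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(diff(adj[order(p)]) > -1e-12))
  expect_true(max(adj) <= 1)
})

test_that("stage correlation matches the textbook Pearson formula", {
  samples <- make_samples(stages = c("A", "B"), reps = 2)
  set.seed(7)
  norm <- matrix(runif(100 * 4, 1, 1000), 100, 4,
                 dimnames = list(sprintf("f%03d", 1:100),
                                 samples$sample_id))
  res <- stage_correlation(norm, samples, c("A", "B"))
  la <- log2(norm + 1)
  x <- rowMeans(la[, 1:2]); y <- rowMeans(la[, 3:4])
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$R, r_hand, tolerance = 1e-12)
  # perfect and inverted correlation
  norm2 <- norm; norm2[, 3:4] <- norm2[, 1:2]
  expect_equal(stage_correlation(norm2, samples, c("A", "B"))$R, 1)
  la3 <- -la[, 1:2] + 20
  norm3 <- cbind(norm[, 1:2], pmax(2^la3 - 1, 0))
  colnames(norm3) <- samples$sample_id
  expect_equal(stage_correlation(norm3, samples, c("A", "B"))$R, -1,
               tolerance = 1e-6)
})

test_that("log2FC estimates agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  samples <- make_samples(stages = c("A", "B"), reps = 3)
  set.seed(8)
  n <- 300
  mu <- rep(c(20, 80), length.out = n)
  fc <- sample(c(1, 1, 1, 4), n, TRUE)
  m <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3),
             matrix(rnbinom(n * 3, mu = mu * fc, size = 20), n, 3))
  dimnames(m) <- list(sprintf("f%04d", 1:n), samples$sample_id)
  res <- nb_test(m, c("A", "B"), samples)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(rep(c("A", "B"), each = 3))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  expect_gt(cor(res$log2FC, dres$log2FoldChange, use = "complete.obs"),
            0.97)
  # significance calls largely agree
  both <- !is.na(res$padj) & !is.na(dres$padj)
  agree <- mean((res$padj < 0.1) == (dres$padj < 0.1), na.rm = TRUE)
  expect_gt(agree, 0.85)
})
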