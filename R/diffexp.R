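#' Median-of-ratios size factors
#'
#' The factor for sample j is the median over features (restricted to rows
#' with a finite geometric mean, i.e. no zero in any sample) of
#' count_ij / geometric_mean_i.
#'
#' @param counts integer matrix, features x samples, or `pirna_counts`.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "pirna_counts")) counts <- counts$counts
  lg <- rowMeans(log(counts))
  keep <- is.finite(lg)
  if (!any(keep))
    stop("no feature has nonzero counts in every sample; ",
         "cannot form the median-of-ratios reference")
  sf <- apply(counts[keep, , drop = FALSE], 2, function(col)
    median(col / exp(lg[keep])))
  if (any(sf <= 0)) stop("non-positive size factor estimated")
  sf
}

#' Negative-binomial Wald test between two stages
#'
#' Per-feature test of differential expression in the standard
#' NB count framework: counts are normalized by median-of-ratios size
#' factors; the dispersion alpha of the variance model
#' `var = mu + alpha * mu^2` is estimated per feature by method of moments
#' from the *within-condition* variances pooled across the two conditions
#' (df-weighted); the log2 fold change
#' `log2FC = log2((mean_B + eps) / (mean_A + eps))` is tested with a Wald
#' statistic whose standard error follows the NB variance model via the
#' delta method, referred to a t distribution with nA + nB - 2 degrees of
#' freedom (accounting for the noise of the moment dispersion estimate;
#' alpha = 0 degenerates to Poisson). P-values are BH-adjusted across the
#' tested features; features with all-zero counts in both conditions are
#' reported untested (`NA`).
#'
#' @param x `pirna_counts` object, or a count matrix (then `samples`
#'   required).
#' @param contrast length-2 character vector `c(stageA, stageB)`; the fold
#'   change is B over A.
#' @param samples sample sheet when `x` is a bare matrix.
#' @param eps pseudo-count stabilizing log2FC at zero means.
#' @return data.frame (`feature_id`, `base_mean`, `log2FC`, `p`, `padj`)
#'   with attribute `contrast`.
#' @export
nb_test <- function(x, contrast, samples = NULL, eps = 0.5) {
  if (inherits(x, "pirna_counts")) {
    counts <- x$counts; samples <- x$samples
  } else counts <- x
  stopifnot(length(contrast) == 2, !is.null(samples))
  sel <- samples$stage %in% contrast
  if (sum(samples$stage == contrast[1]) < 2 ||
      sum(samples$stage == contrast[2]) < 2)
    stop("nb_test needs >= 2 replicates per condition")
  counts <- counts[, samples$sample_id[sel], drop = FALSE]
  grp <- as.character(samples$stage[sel])
  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  A <- grp == contrast[1]; B <- grp == contrast[2]
  nA <- sum(A); nB <- sum(B)
  mA <- rowMeans(nc[, A, drop = FALSE])
  mB <- rowMeans(nc[, B, drop = FALSE])
  s2A <- apply(nc[, A, drop = FALSE], 1, var)
  s2B <- apply(nc[, B, drop = FALSE], 1, var)
  s2w <- ((nA - 1) * s2A + (nB - 1) * s2B) / (nA + nB - 2)
  muw <- (mA + mB) / 2
  alpha <- ifelse(muw > 0, pmax(0, (s2w - muw) / muw^2), 0)
  lfc <- log2((mB + eps) / (mA + eps))
  vA <- (mA + alpha * mA^2) / nA
  vB <- (mB + alpha * mB^2) / nB
  se <- sqrt(vA / (mA + eps)^2 + vB / (mB + eps)^2) / log(2)
  tstat <- lfc / se
  p <- 2 * pt(-abs(tstat), df = nA + nB - 2)
  untested <- mA == 0 & mB == 0
  p[untested] <- NA
  lfc[untested] <- NA
  res <- data.frame(feature_id = rownames(counts),
                    base_mean = rowMeans(nc),
                    log2FC = lfc, p = p,
                    padj = bh_adjust(p),
                    row.names = NULL)
  attr(res, "contrast") <- contrast
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control; `NA` p-values (untested
#' features) stay `NA` and do not enter the adjustment.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Classify differential-expression calls
#'
#' Dual thresholding on effect size, raw p and adjusted p:
#' up iff `log2FC >= lfc_cut & p < p_cut & padj < fdr_cut`; down
#' symmetric; otherwise ns.
#'
#' @param results data.frame from [nb_test()].
#' @param lfc_cut,p_cut,fdr_cut thresholds (defaults 1, 0.05, 0.1).
#' @return the input with a `call` column plus a `summary` attribute
#'   (named counts of up/down/ns/untested).
#' @export
classify_de <- function(results, lfc_cut = 1, p_cut = 0.05, fdr_cut = 0.1) {
  call <- rep("ns", nrow(results))
  sig <- !is.na(results$p) & results$p < p_cut & results$padj < fdr_cut
  call[sig & results$log2FC >= lfc_cut] <- "up"
  call[sig & results$log2FC <= -lfc_cut] <- "down"
  call[is.na(results$p)] <- "untested"
  results$call <- call
  attr(results, "summary") <- c(up = sum(call == "up"),
                                down = sum(call == "down"),
                                ns = sum(call == "ns"),
                                untested = sum(call == "untested"))
  results
}

#' Pearson correlation between two stages
#'
#' Per feature, the mean over each stage's replicates of log2(CPM + 1);
#' Pearson R with its two-sided test over the supplied feature set
#' (typically the union expressed set).
#'
#' @param norm CPM matrix (features x samples).
#' @param samples sample sheet.
#' @param pair length-2 character vector of stage names.
#' @param features feature ids to use; default all rows.
#' @return data.frame row: `stage_a`, `stage_b`, `R`, `p`, `n`. `R` is
#'   `NA` with a warning when either stage has zero variance.
#' @export
stage_correlation <- function(norm, samples, pair, features = NULL) {
  if (is.null(features)) features <- rownames(norm)
  stopifnot(length(features) >= 3)
  m <- log2(norm[features, , drop = FALSE] + 1)
  avg <- function(st)
    rowMeans(m[, samples$sample_id[samples$stage == st], drop = FALSE])
  x <- avg(pair[1]); y <- avg(pair[2])
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a stage; correlation undefined")
    return(data.frame(stage_a = pair[1], stage_b = pair[2],
                      R = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  data.frame(stage_a = pair[1], stage_b = pair[2],
             R = unname(ct$estimate), p = ct$p.value, n = length(x))
}
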