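#' Standardize expression trajectories for clustering
#'
#' Collapses replicates to per-stage means of log2(CPM + 1), then z-scores
#' each feature's trajectory (subtract the row mean, divide by the row
#' standard deviation, n-1 denominator). Rows with negligible spread
#' (sd < 1e-8) are dropped and listed in the `dropped` attribute.
#'
#' @param norm CPM matrix (features x samples).
#' @param samples sample sheet with `sample_id` and ordered `stage`.
#' @param features optional feature subset.
#' @return numeric matrix, features x stages, rows standardized; attribute
#'   `dropped` holds the removed feature ids.
#' @export
standardize_trajectories <- function(norm, samples, features = NULL) {
  stages <- levels(samples$stage)
  stopifnot(length(stages) >= 2)
  if (!is.null(features)) norm <- norm[features, , drop = FALSE]
  m <- log2(norm + 1)
  traj <- vapply(stages, function(st)
    rowMeans(m[, samples$sample_id[samples$stage == st], drop = FALSE]),
    numeric(nrow(m)))
  if (nrow(m) == 1) traj <- matrix(traj, nrow = 1,
                                   dimnames = list(rownames(m), stages))
  sds <- apply(traj, 1, sd)
  dropped <- rownames(traj)[sds < 1e-8]
  traj <- traj[sds >= 1e-8, , drop = FALSE]
  z <- (traj - rowMeans(traj)) / apply(traj, 1, sd)
  attr(z, "dropped") <- dropped
  z
}

# one seeded fuzzy c-means run; centers initialized from c distinct rows
fcm_once <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, c), , drop = FALSE]
  u <- NULL
  obj <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, c)) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * x %*% t(centers)
    d2 <- pmax(d2, 0)
    # membership: u_ik = 1 / sum_j (d_ik/d_ij)^(2/(m-1)); zero distance
    # pins the feature to that center
    pw <- d2^(-1 / (m - 1))
    u <- pw / rowSums(pw)
    # zero / numerically tiny distance: the power overflows; pin the
    # feature to its nearest center
    zr <- which(!is.finite(rowSums(pw)) | rowSums(d2 < 1e-300) > 0)
    if (length(zr)) {
      u[zr, ] <- 0
      u[cbind(zr, max.col(-d2[zr, , drop = FALSE]))] <- 1
    }
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    obj <- sum(um * d2)
    trace <- c(trace, obj)
    if (shift < tol) break
  }
  rownames(centers) <- paste0("cluster", seq_len(c))
  dimnames(u) <- list(rownames(x), rownames(centers))
  list(membership = u, centers = centers, objective = obj,
       objective_trace = trace, iterations = it)
}

#' Fuzzy c-means clustering of standardized trajectories
#'
#' Classic alternating-optimization fuzzy c-means with Euclidean distance:
#' memberships u_ik = 1 / sum_j (d_ik/d_ij)^(2/(m-1)), centers the
#' u^m-weighted means; iterated until the largest center shift drops below
#' `tol`. Initialization samples `c` distinct data rows as centers; the
#' best of `restarts` seeded restarts (lowest objective
#' sum u^m d^2) is returned, making the fit reproducible under `seed`.
#'
#' @param x standardized trajectory matrix ([standardize_trajectories()]).
#' @param c number of clusters.
#' @param m fuzzifier (> 1); the small default 1.15 keeps memberships
#'   nearly crisp, suitable for well-separated temporal patterns.
#' @param seed integer seed.
#' @param tol convergence tolerance on the center shift.
#' @param max_iter iteration cap per restart.
#' @param restarts random restarts, best objective kept.
#' @return object of class `fcm_fit`: `membership` (rows sum to 1),
#'   `centers`, `objective`, `m`, `seed`.
#' @export
fuzzy_cmeans <- function(x, c = 8L, m = 1.15, seed = 1L, tol = 1e-6,
                         max_iter = 1000L, restarts = 5L) {
  stopifnot(is.matrix(x), m > 1)
  if (c > nrow(x)) stop("more clusters (", c, ") than features (",
                        nrow(x), ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- fcm_once(x, c, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(c(best, list(m = m, seed = seed)), class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("fuzzy c-means fit:", nrow(x$membership), "features,",
      ncol(x$membership), "clusters, m =", x$m,
      ", objective =", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Hard cluster labels from fuzzy memberships
#'
#' @param fit an `fcm_fit` (or a membership matrix).
#' @param min_membership minimum top membership to assign; below it the
#'   feature is `NA` (unassigned). Ties go to the smallest cluster index.
#' @return named integer vector of cluster labels (NA = unassigned).
#' @export
assign_clusters <- function(fit, min_membership = 0.5) {
  u <- if (inherits(fit, "fcm_fit")) fit$membership else fit
  top <- max.col(u, ties.method = "first")
  val <- u[cbind(seq_len(nrow(u)), top)]
  out <- ifelse(val >= min_membership, top, NA_integer_)
  setNames(as.integer(out), rownames(u))
}

#' Optimal cluster-to-template matching
#'
#' Exact assignment (bitmask dynamic program, equivalent to the Hungarian
#' algorithm for the sizes used here) maximizing the total Pearson
#' correlation between matched cluster centers and template trajectories.
#'
#' @param centers clusters x stages matrix.
#' @param templates templates x stages matrix (same column count).
#' @return list: `assignment` (for each center, the matched template row),
#'   `correlations` (the matched correlation per center), `total`.
#' @export
match_clusters <- function(centers, templates) {
  k <- nrow(centers)
  stopifnot(nrow(templates) == k, ncol(centers) == ncol(templates))
  cc <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cc[i, j] <- stats::cor(centers[i, ], templates[j, ])
  # dp over subsets of templates; centers taken in order
  nmask <- bitwShiftL(1L, k)
  dp <- rep(-Inf, nmask); dp[1] <- 0
  choice <- matrix(NA_integer_, nmask, 1)
  from <- rep(NA_integer_, nmask)
  for (mask in 0:(nmask - 1)) {
    if (!is.finite(dp[mask + 1])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0) + 1L
    if (i > k) next
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0) next
      nm <- bitwOr(mask, bit)
      v <- dp[mask + 1] + cc[i, j]
      if (v > dp[nm + 1]) { dp[nm + 1] <- v; from[nm + 1] <- mask
                            choice[nm + 1, 1] <- j }
    }
  }
  assignment <- integer(k)
  mask <- nmask - 1L
  while (mask > 0) {
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0)
    assignment[i] <- choice[mask + 1, 1]
    mask <- from[mask + 1]
  }
  list(assignment = assignment,
       correlations = cc[cbind(seq_len(k), assignment)],
       total = dp[nmask])
}

#' Minimum-centroid-distance diagnostic over candidate cluster counts
#'
#' Fits fuzzy c-means for each candidate c and reports the minimum pairwise
#' distance between cluster centers - a drop indicates redundant clusters
#' and helps justify the chosen c.
#'
#' @param x standardized trajectory matrix.
#' @param c_range candidate cluster counts.
#' @inheritParams fuzzy_cmeans
#' @return data.frame `c`, `min_center_distance`.
#' @export
centroid_distance_diagnostic <- function(x, c_range = 2:12, m = 1.15,
                                         seed = 1L) {
  c_range <- c_range[c_range <= nrow(x)]
  data.frame(c = c_range, min_center_distance = vapply(c_range, function(cc) {
    fit <- fuzzy_cmeans(x, c = cc, m = m, seed = seed)
    min(stats::dist(fit$centers))
  }, numeric(1)))
}
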