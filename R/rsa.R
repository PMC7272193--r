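## Representational-similarity statistics: cross-validated Mahalanobis
## (crossnobis) distances, robust subject aggregation, semantic cosine
## dissimilarity, bootstrap RSA correlations and partial correlations.

#' Cross-validated Mahalanobis (crossnobis) distances
#'
#' For every condition pair (a, b) and leave-one-run-out fold m, computes
#' `(x_a,m - x_b,m)' W (xbar_a,-m - xbar_b,-m)` — the inner product of the
#' pattern difference in the held-out run with the mean difference across
#' the remaining runs — and averages across folds. Because the two
#' factors carry independent noise, the estimator is unbiased: its
#' expectation is zero for identical condition means (and can therefore
#' be negative), and with no noise it equals the squared (whitened)
#' Euclidean distance between the condition means. `W` is the identity by
#' default (Euclidean crossnobis); supplying a noise covariance gives the
#' full Mahalanobis form.
#'
#' @param patterns 3-d array `[run, condition, voxel]` with >= 2 runs
#'   (e.g. from [simulate_voxel_patterns()]).
#' @param covariance Optional positive-definite voxel noise covariance;
#'   its inverse is used as `W`.
#' @return A [dissimilarity_table()] over condition pairs (negative
#'   values permitted, stored in `d`), with the full symmetric matrix in
#'   attribute `matrix`.
#' @export
crossnobis <- function(patterns, covariance = NULL) {
  dm <- dim(patterns)
  if (length(dm) != 3L) stop_input("patterns must be a run x condition x voxel array")
  n_runs <- dm[1L]
  n_cond <- dm[2L]
  if (n_runs < 2L) stop_input("crossnobis needs >= 2 runs")
  if (any(!is.finite(patterns))) stop_input("patterns contain non-finite values")
  conds <- dimnames(patterns)[[2L]]
  if (is.null(conds)) conds <- paste0("cond", seq_len(n_cond))
  W <- if (is.null(covariance)) NULL else {
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_input("covariance is not positive definite (rank %d of %d)",
                 sum(ev > max(ev) * 1e-12), nrow(covariance))
    solve(covariance)
  }
  acc <- matrix(0, n_cond, n_cond)
  for (m in seq_len(n_runs)) {
    x_m <- patterns[m, , , drop = TRUE]
    if (!is.matrix(x_m)) x_m <- matrix(x_m, nrow = n_cond)
    x_rest <- apply(patterns[-m, , , drop = FALSE], c(2L, 3L), mean)
    cross <- if (is.null(W)) tcrossprod(x_m, x_rest) else
      x_m %*% W %*% t(x_rest)
    # d_ab = (x_a,m - x_b,m)' W (xbar_a - xbar_b)
    #      = C[a,a] + C[b,b] - C[a,b] - C[b,a] with C = x_m W x_rest'
    dg <- diag(cross)
    acc <- acc + outer(dg, dg, "+") - cross - t(cross)
  }
  dmat <- acc / n_runs
  dmat <- (dmat + t(dmat)) / 2  # numerically symmetric
  diag(dmat) <- 0
  dimnames(dmat) <- list(conds, conds)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  out <- data.frame(item_a = conds[ut[, 1L]], item_b = conds[ut[, 2L]],
                    d = dmat[ut], stringsAsFactors = FALSE)
  cp <- canonical_pairs(out$item_a, out$item_b)
  out$item_a <- cp$item_a
  out$item_b <- cp$item_b
  class(out) <- c("dissimilarity_table", "data.frame")
  attr(out, "matrix") <- dmat
  out
}

#' Aggregate per-subject dissimilarities robustly
#'
#' For each pair, values more than `outlier_k` scaled median absolute
#' deviations from the across-subject median are removed (the same rule
#' as [filter_outliers()]), and the median of the remaining subjects is
#' reported.
#'
#' @param per_subject List of dissimilarity tables sharing one pair set.
#' @param outlier_k Threshold in scaled-MAD units (default 3).
#' @return A single dissimilarity-table data frame of pair medians.
#' @export
aggregate_subjects <- function(per_subject, outlier_k = 3) {
  keys <- lapply(per_subject, function(d) pair_key(d$item_a, d$item_b))
  ref <- keys[[1L]]
  for (i in seq_along(keys)) {
    if (!setequal(keys[[i]], ref))
      stop_input("subject %d lacks pair(s): %s", i,
                 paste(sub("\r", "-", setdiff(ref, keys[[i]])), collapse = ", "))
  }
  vals <- vapply(seq_along(per_subject),
                 function(i) per_subject[[i]]$d[match(ref, keys[[i]])],
                 numeric(length(ref)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(ref))
  med <- apply(vals, 1L, function(v) {
    m <- median(v)
    smad <- mad(v, constant = 1.4826)
    keep <- abs(v - m) <= outlier_k * smad
    median(v[keep])
  })
  out <- per_subject[[1L]][, c("item_a", "item_b")]
  out$d <- med
  class(out) <- c("dissimilarity_table", "data.frame")
  out
}

#' Cosine (semantic) dissimilarity between two word embeddings
#'
#' `1 - cos(v1, v2)`: 0 for identical directions, 1 for orthogonal
#' vectors, 2 for opposite vectors. Applied to co-occurrence-based word
#' embeddings this indexes semantic rather than visual similarity.
#'
#' @param emb Numeric matrix, words x dims, with word row names.
#' @param w1,w2 Words present in `emb`.
#' @return A value in [0, 2].
#' @export
semantic_dissimilarity <- function(emb, w1, w2) {
  for (w in c(w1, w2))
    if (!w %in% rownames(emb)) stop_input("word '%s' missing from embeddings", w)
  v1 <- emb[w1, ]
  v2 <- emb[w2, ]
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop_input("zero embedding vector")
  1 - sum(v1 * v2) / (n1 * n2)
}

#' All pairwise semantic dissimilarities
#'
#' @param emb Numeric matrix, words x dims, with word row names.
#' @return A [dissimilarity_table()] over all word pairs. Tiny negative
#'   cosine distances from floating-point rounding are clipped to 0.
#' @export
semantic_dissimilarities <- function(emb) {
  pairs <- all_pairs(rownames(emb))
  d <- vapply(seq_len(nrow(pairs)),
              function(i) semantic_dissimilarity(emb, pairs$item_a[i],
                                                 pairs$item_b[i]),
              numeric(1L))
  dissimilarity_table(pairs$item_a, pairs$item_b, pmax(d, 0))
}

#' RSA correlation with bootstrap error bars
#'
#' Pearson correlation between two dissimilarity structures over their
#' shared pairs, with a bootstrap over pairs (resampling dissimilarity
#' values with replacement) for the standard deviation, and a one-sided
#' bootstrap p-value for r > 0 (`p` = fraction of bootstrap r <= 0).
#'
#' @param neural,model Dissimilarity tables sharing >= 3 pairs.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List: `r`, `sd`, `p`, `n_pairs`, `boot_r`.
#' @export
rsa_correlation <- function(neural, model, n_boot = 1000, seed = NULL) {
  kn <- pair_key(neural$item_a, neural$item_b)
  km <- pair_key(model$item_a, model$item_b)
  shared <- intersect(kn, km)
  if (length(shared) < 3L)
    stop_input("only %d shared pair(s); need >= 3", length(shared))
  x <- neural$d[match(shared, kn)]
  y <- model$d[match(shared, km)]
  r <- cor(x, y)
  boot_r <- local_seed(seed, vapply(seq_len(n_boot), function(b) {
    ix <- sample(length(shared), replace = TRUE)
    if (sd(x[ix]) == 0 || sd(y[ix]) == 0) return(NA_real_)
    cor(x[ix], y[ix])
  }, numeric(1L)))
  list(r = r, sd = sd(boot_r, na.rm = TRUE),
       p = mean(boot_r <= 0, na.rm = TRUE),
       n_pairs = length(shared), boot_r = boot_r)
}

#' Partial correlation of two dissimilarity vectors given a third
#'
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`: the correlation
#' between x and y after factoring out their linear dependence on z.
#' Equals the correlation of the residuals of x|z and y|z.
#'
#' @param x,y,z Aligned numeric vectors of equal length >= 4.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop_input("vectors must be aligned")
  if (n < 4L) stop_input("need >= 4 observations")
  r_xy <- cor(x, y)
  r_xz <- cor(x, z)
  r_yz <- cor(y, z)
  if (abs(r_xz) >= 1 - 1e-15 || abs(r_yz) >= 1 - 1e-15)
    stop_input("degenerate conditioning: |cor with z| = 1")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}
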