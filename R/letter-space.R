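## Embedding single-letter dissimilarities into artificial neurons by
## multidimensional scaling, with variance-explained diagnostics.

#' Embed letter dissimilarities into a letter code by MDS
#'
#' Classical (Torgerson) multidimensional scaling places letters in
#' `n_dims` dimensions so that pairwise Euclidean distances approximate
#' the observed dissimilarities. The coordinate of every letter along one
#' dimension is read as the response of one artificial neuron, so the
#' returned code has `n_dims` neurons. The classical solution is
#' deterministic; setting `refine = TRUE` additionally minimizes metric
#' stress (sum of squared distance errors) by BFGS starting from the
#' classical configuration.
#'
#' Because any rigid rotation of the configuration preserves all
#' distances, individual neuron responses are identified only up to an
#' orthogonal transform; analyses should compare distances, not raw
#' coordinates. Negative eigenvalues (1/RT data need not be exactly
#' Euclidean) are clipped to zero and their magnitude reported in the
#' `diagnostics` field.
#'
#' @param D A [dissimilarity_table()] complete over all letter pairs, or a
#'   symmetric matrix.
#' @param n_dims Number of dimensions/neurons (default 10, which for the
#'   single-letter search data captures about 95% of the variance);
#'   must be <= letters - 1.
#' @param refine Optional metric-stress refinement (default off).
#' @return A [letter_code()] with `eigenvalues` and a `diagnostics`
#'   attribute (negative-eigenvalue mass, stress).
#' @export
embed_mds <- function(D, n_dims = 10, refine = FALSE) {
  m <- if (is.matrix(D)) D else dissim_matrix(D)
  n <- nrow(m)
  if (n_dims > n - 1L)
    stop_input("n_dims (%d) must be at most letters - 1 (%d)", n_dims, n - 1L)
  sol <- cmdscale(m, k = n_dims, eig = TRUE)
  pts <- sol$points
  if (ncol(pts) < n_dims) {
    # fewer positive eigenvalues than requested: pad constant-zero neurons
    pts <- cbind(pts, matrix(0, n, n_dims - ncol(pts)))
  }
  eig <- pmax(sol$eig[seq_len(n_dims)], 0)
  code <- letter_code(t(pts), rownames(m), eigenvalues = eig)
  if (refine) {
    dv <- m[upper.tri(m)]
    stress <- function(x) {
      p <- matrix(x, n, n_dims)
      sum((dist(p) - dv)^2)
    }
    opt <- optim(as.numeric(pts), stress, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    pts <- matrix(opt$par, n, n_dims)
    code <- letter_code(t(pts), rownames(m), eigenvalues = eig)
  }
  dhat <- dist(pts)
  attr(code, "diagnostics") <- list(
    negative_eigenvalue_mass = sum(abs(pmin(sol$eig, 0))),
    total_eigenvalue_mass = sum(abs(sol$eig)),
    stress = sum((dhat - as.dist(m))^2),
    distance_correlation = cor(as.numeric(dhat), as.numeric(as.dist(m))))
  code
}

#' Fit quality of MDS embeddings as a function of dimensionality
#'
#' For each dimensionality from 1 to `max_dims`, the correlation between
#' embedded and observed distances (non-decreasing in the dimension up to
#' numerical tolerance), plus the cumulative share of (positive)
#' eigenvalue variance. "Variance explained" is reported both ways since
#' they answer slightly different questions: eigenvalue share is variance
#' of the configuration, distance correlation is fit to the data.
#'
#' @inheritParams embed_mds
#' @param max_dims Largest dimensionality to evaluate.
#' @return Data frame: `dims`, `r` (distance correlation),
#'   `eigenvalue_share` (cumulative).
#' @export
variance_explained_curve <- function(D, max_dims) {
  m <- if (is.matrix(D)) D else dissim_matrix(D)
  n <- nrow(m)
  if (max_dims > n - 1L)
    stop_input("max_dims (%d) must be at most letters - 1 (%d)", max_dims,
               n - 1L)
  sol <- cmdscale(m, k = max_dims, eig = TRUE)
  pts <- sol$points
  if (ncol(pts) < max_dims)
    pts <- cbind(pts, matrix(0, n, max_dims - ncol(pts)))
  dv <- as.numeric(as.dist(m))
  r <- vapply(seq_len(max_dims), function(k) {
    cor(as.numeric(dist(pts[, seq_len(k), drop = FALSE])), dv)
  }, numeric(1L))
  pos <- pmax(sol$eig, 0)
  share <- cumsum(pos[seq_len(max_dims)]) / sum(pos)
  data.frame(dims = seq_len(max_dims), r = r, eigenvalue_share = share)
}

#' Tuning curve of one artificial neuron
#'
#' @param code A [letter_code()].
#' @param neuron Neuron index (1-based, <= `code$n_dims`).
#' @return Named response vector over letters, with attributes `best`
#'   (argmax letter) and `worst` (argmin letter).
#' @export
neuron_tuning <- function(code, neuron) {
  if (neuron < 1L || neuron > code$n_dims)
    stop_input("neuron index %d out of range 1..%d", neuron, code$n_dims)
  resp <- code$responses[neuron, ]
  names(resp) <- code$letters
  attr(resp, "best") <- code$letters[which.max(resp)]
  attr(resp, "worst") <- code$letters[which.min(resp)]
  resp
}
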