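## The compositional letter model: string responses as weighted sums of
## single-letter responses, string-string dissimilarities, weight fitting,
## and positional-asymmetry summaries.

#' Construct spatial summation weights
#'
#' Per-neuron, per-position multipliers (w1, w2, ...) used when summing
#' single-letter responses into a string response. Asymmetry across
#' positions is what makes transposed strings (AB vs BA) discriminable.
#'
#' @param w Numeric matrix, neurons x positions.
#' @param fit_meta Optional list of fitting metadata (loss, restarts, seed).
#' @return An object of class `spatial_weights`.
#' @export
spatial_weights <- function(w, fit_meta = NULL) {
  w <- as.matrix(w)
  if (any(!is.finite(w))) stop_input("weights must be finite")
  rownames(w) <- paste0("neuron", seq_len(nrow(w)))
  colnames(w) <- paste0("pos", seq_len(ncol(w)))
  structure(list(w = w, string_length = ncol(w), fit_meta = fit_meta),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial summation weights: %d neurons x %d positions\n",
              nrow(x$w), x$string_length))
  if (!is.null(x$fit_meta$loss))
    cat(sprintf("  fitted, loss = %.6g (%d restart(s))\n",
                x$fit_meta$loss, x$fit_meta$restarts))
  invisible(x)
}

# Letter-response matrix for a string: neurons x positions, column p holding
# each neuron's response to the letter at position p.
string_letter_matrix <- function(code, s) {
  cs <- chars(s)
  idx <- match(cs, code$letters)
  if (anyNA(idx))
    stop_input("string '%s' contains letters outside the code: %s", s,
               paste(unique(cs[is.na(idx)]), collapse = ", "))
  code$responses[, idx, drop = FALSE]
}

#' Response of every neuron to a letter string
#'
#' The response of neuron k to string s is the weighted sum
#' `sum_p w[k, p] * r_k(s[p])` of its single-letter responses, i.e. the
#' code is compositional: there are no string-specific detectors.
#'
#' @param code A [letter_code()].
#' @param weights A [spatial_weights()] whose positions match `nchar(s)`.
#' @param s A single string.
#' @return Numeric vector of per-neuron responses.
#' @examples
#' code <- make_letter_code(3, c("A", "B"), seed = 1)
#' string_response(code, spatial_weights(matrix(1, 3, 2)), "AB")
#' @export
string_response <- function(code, weights, s) {
  if (nchar(s) != weights$string_length)
    stop_input("string '%s' has length %d but weights cover %d positions",
               s, nchar(s), weights$string_length)
  rowSums(weights$w * string_letter_matrix(code, s))
}

#' Model dissimilarity between two strings
#'
#' Distance between the per-neuron response vectors of two equal-length
#' strings. `metric = "euclidean"` is the Euclidean distance between the
#' response vectors; `metric = "mean_abs"` averages the per-neuron absolute
#' response differences. With equal weights at all positions, transposed
#' strings (AB vs BA) receive identical responses and d = 0.
#'
#' @inheritParams string_response
#' @param s1,s2 Strings of the length the weights cover.
#' @param metric `"euclidean"` (default) or `"mean_abs"`.
#' @return A nonnegative scalar; 0 iff the response vectors coincide.
#' @export
model_dissimilarity <- function(code, weights, s1, s2,
                                metric = c("euclidean", "mean_abs")) {
  metric <- match.arg(metric)
  dr <- string_response(code, weights, s1) - string_response(code, weights, s2)
  if (metric == "euclidean") sqrt(sum(dr^2)) else mean(abs(dr))
}

# Vectorized model dissimilarities for a table of string pairs.
# Returns the per-pair distances for a w matrix, given precomputed
# per-neuron difference matrices (list over neurons of pairs x positions).
pair_delta_list <- function(code, item_a, item_b) {
  L <- nchar(item_a[1L])
  if (any(nchar(c(item_a, item_b)) != L))
    stop_input("all strings must share one length (found lengths: %s)",
               paste(sort(unique(nchar(c(item_a, item_b)))), collapse = ", "))
  strings <- unique(c(item_a, item_b))
  mats <- lapply(strings, function(s) string_letter_matrix(code, s))
  names(mats) <- strings
  ia <- match(item_a, strings)
  ib <- match(item_b, strings)
  n_neu <- code$n_dims
  lapply(seq_len(n_neu), function(k) {
    V <- vapply(mats, function(m) m[k, ], numeric(L))
    A <- if (L == 1L) matrix(V, ncol = 1L) else t(V)  # strings x positions
    A[ia, , drop = FALSE] - A[ib, , drop = FALSE]     # pairs x positions
  })
}

model_dissim_from_delta <- function(delta, w, metric) {
  U <- vapply(seq_along(delta),
              function(k) drop(delta[[k]] %*% w[k, ]),
              numeric(nrow(delta[[1L]])))  # pairs x neurons
  if (!is.matrix(U)) U <- matrix(U, nrow = nrow(delta[[1L]]))
  if (metric == "euclidean") sqrt(rowSums(U^2)) else rowMeans(abs(U))
}

#' Predict model dissimilarities for many string pairs
#'
#' @inheritParams string_response
#' @param pairs Data frame with columns `item_a`, `item_b`.
#' @param metric See [model_dissimilarity()].
#' @return Numeric vector of distances, one per row of `pairs`.
#' @export
predict_dissimilarities <- function(code, weights, pairs,
                                    metric = c("euclidean", "mean_abs")) {
  metric <- match.arg(metric)
  delta <- pair_delta_list(code, pairs$item_a, pairs$item_b)
  model_dissim_from_delta(delta, weights$w, metric)
}

#' Fit spatial summation weights to observed dissimilarities
#'
#' Least-squares estimation of the per-neuron, per-position summation
#' weights: the squared error between observed and model-predicted
#' dissimilarities is minimized by gradient-based optimization (BFGS) from
#' several random starting points, and the best solution by final loss is
#' kept. The free-parameter count is neurons x string length (20 for
#' bigrams with a 10-neuron code). Weights are unconstrained reals; note
#' that jointly flipping the sign of one neuron's weights (with the
#' euclidean metric) leaves all distances unchanged, so recovered weights
#' are identified only up to per-neuron sign.
#'
#' @param code A [letter_code()].
#' @param observed A [dissimilarity_table()] over equal-length strings.
#' @param metric See [model_dissimilarity()].
#' @param n_restarts Number of random initializations (default 10).
#' @param seed Integer seed for the initializations.
#' @param maxit Maximum BFGS iterations per restart.
#' @return A list of class `model_fit` with elements `weights`
#'   (a [spatial_weights()]), `r` (Pearson correlation of predictions with
#'   observations), `predicted`, `residuals`, `loss` and `n_pairs`.
#' @export
fit_weights <- function(code, observed, metric = c("euclidean", "mean_abs"),
                        n_restarts = 10, seed = NULL, maxit = 1000) {
  metric <- match.arg(metric)
  if (any(!is.finite(observed$d))) stop_input("observations must be finite")
  delta <- pair_delta_list(code, observed$item_a, observed$item_b)
  L <- ncol(delta[[1L]])
  n_neu <- code$n_dims
  n_par <- n_neu * L
  d_obs <- observed$d
  if (nrow(observed) < n_par)
    warning(sprintf("only %d pairs for %d free parameters; fit underdetermined",
                    nrow(observed), n_par))

  obj <- function(par) {
    w <- matrix(par, n_neu, L)
    sum((model_dissim_from_delta(delta, w, metric) - d_obs)^2)
  }
  grad <- function(par) {
    w <- matrix(par, n_neu, L)
    U <- vapply(seq_len(n_neu), function(k) drop(delta[[k]] %*% w[k, ]),
                numeric(length(d_obs)))
    if (!is.matrix(U)) U <- matrix(U, nrow = length(d_obs))
    if (metric == "euclidean") {
      d_pred <- sqrt(rowSums(U^2))
      resid2 <- 2 * (d_pred - d_obs) / pmax(d_pred, 1e-12)
      g <- vapply(seq_len(n_neu),
                  function(k) crossprod(delta[[k]], resid2 * U[, k])[, 1L],
                  numeric(L))
    } else {
      d_pred <- rowMeans(abs(U))
      resid2 <- 2 * (d_pred - d_obs) / n_neu
      g <- vapply(seq_len(n_neu),
                  function(k) crossprod(delta[[k]], resid2 * sign(U[, k]))[, 1L],
                  numeric(L))
    }
    as.numeric(t(g))  # vapply gives L x n_neu; transpose to matrix layout
  }

  runs <- local_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      init <- rnorm(n_par, sd = 1)
      optim(init, obj, grad, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-14))
    })
  })
  losses <- vapply(runs, `[[`, numeric(1L), "value")
  best <- runs[[which.min(losses)]]
  w <- matrix(best$par, n_neu, L)
  pred <- model_dissim_from_delta(delta, w, metric)
  fit <- list(
    weights = spatial_weights(w, fit_meta = list(loss = best$value,
                                                 restarts = n_restarts,
                                                 seed = seed, metric = metric)),
    r = if (sd(pred) > 0 && sd(d_obs) > 0) cor(pred, d_obs) else NA_real_,
    predicted = pred, residuals = d_obs - pred,
    loss = best$value, n_pairs = nrow(observed))
  class(fit) <- "model_fit"
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Letter-model fit: r = %.3f over %d pairs (loss %.4g)\n",
              x$r, x$n_pairs, x$loss))
  invisible(x)
}

#' Modulation index of bigram summation weights
#'
#' Positional asymmetry of summation for a two-position weight set,
#' `|w1 - w2| / |w1 + w2|` per neuron: 0 for perfectly symmetric summation
#' (transposed bigrams indistinguishable), 1 for winner-take-all.
#'
#' @param weights A [spatial_weights()] with exactly two positions.
#' @return List with `per_neuron` values and their `mean`.
#' @export
modulation_index <- function(weights) {
  if (weights$string_length != 2L)
    stop_input("modulation index is defined for two-position weights")
  w1 <- weights$w[, 1L]
  w2 <- weights$w[, 2L]
  if (any(w1 + w2 == 0))
    stop_input("w1 + w2 = 0 for neuron(s) %s; modulation index undefined",
               paste(which(w1 + w2 == 0), collapse = ", "))
  mi <- abs(w1 - w2) / abs(w1 + w2)
  list(per_neuron = mi, mean = mean(mi))
}

#' Rank jumbled versions of a word by model dissimilarity
#'
#' Sorts candidate strings by their compositional-model distance to a word,
#' i.e. by predicted reading difficulty of the jumbled versions (nearer =
#' easier to recognize as the word). Ties are broken lexicographically.
#'
#' @inheritParams string_response
#' @param word The reference word.
#' @param candidates Character vector of equal-length candidates, or
#'   `"all"` for every permutation of the word's letters.
#' @param metric See [model_dissimilarity()].
#' @return Data frame with columns `candidate` and `d`, ascending in `d`.
#' @export
rank_jumbles <- function(code, weights, word, candidates = "all",
                         metric = c("euclidean", "mean_abs")) {
  metric <- match.arg(metric)
  if (identical(candidates, "all")) {
    perms <- string_permutations(word)
    candidates <- unique(perms)
  }
  if (any(nchar(candidates) != nchar(word)))
    stop_input("all candidates must have the word's length (%d)", nchar(word))
  d <- vapply(candidates,
              function(s) model_dissimilarity(code, weights, word, s, metric),
              numeric(1L))
  ord <- order(d, candidates)
  out <- data.frame(candidate = candidates[ord], d = unname(d[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# All permutations of a word's letters (including duplicates collapsed).
string_permutations <- function(word) {
  cs <- chars(word)
  perm_idx <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (sub in perm_idx(n - 1L))
      for (pos in seq_len(n))
        out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    out
  }
  unique(vapply(perm_idx(length(cs)),
                function(ix) paste(cs[ix], collapse = ""), character(1L)))
}
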