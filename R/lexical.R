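## Lexical-decision modelling: orthographic edit distance, lexical
## features, distance-to-nearest-word, RT regressions, cross-validated
## bootstrap model comparison, and transposition/substitution summaries.

#' Orthographic Levenshtein distance
#'
#' Edit distance between strings with insertion/deletion cost
#' `indel_cost` and substitution cost `sub_cost` (default 2, so that a
#' substitution is never cheaper than a delete-insert pair; with that
#' default the distance equals `|s| + |t| - 2 * LCS(s, t)`).
#'
#' @param s,t Character vectors (recycled to a common length).
#' @param sub_cost Substitution cost (default 2).
#' @param indel_cost Insertion/deletion cost (default 1).
#' @return Numeric vector of distances; symmetric, zero iff `s == t`.
#' @examples
#' old_distance("FORGET", "FOGRET")
#' @export
old_distance <- function(s, t, sub_cost = 2, indel_cost = 1) {
  if (sub_cost < 0 || indel_cost < 0) stop_input("costs must be nonnegative")
  n <- max(length(s), length(t))
  s <- rep_len(as.character(s), n)
  t <- rep_len(as.character(t), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- adist(s[i], t[i],
                    costs = list(insertions = indel_cost,
                                 deletions = indel_cost,
                                 substitutions = sub_cost))[1L, 1L]
  }
  out
}

#' Count orthographic neighbors (Coltheart's N)
#'
#' Number of lexicon words of the same length differing from `word` in
#' exactly one letter position (substitution-only neighborhood), the word
#' itself excluded. An OLD-radius alternative counts words within
#' `radius` orthographic Levenshtein distance instead.
#'
#' @param word A string.
#' @param lexicon Character vector of words (or a `lexicon` object).
#' @param method `"substitution"` (default) or `"old_radius"`.
#' @param radius Radius for `method = "old_radius"` (default 2, i.e. one
#'   substitution at the default costs).
#' @return Integer count.
#' @export
orthographic_neighbors <- function(word, lexicon,
                                   method = c("substitution", "old_radius"),
                                   radius = 2) {
  method <- match.arg(method)
  words <- if (inherits(lexicon, "lexicon")) lexicon$words else
    as.character(lexicon)
  words <- setdiff(words, word)
  if (length(words) == 0L) return(0L)
  if (method == "substitution") {
    same_len <- words[nchar(words) == nchar(word)]
    if (length(same_len) == 0L) return(0L)
    wc <- chars(word)
    sum(vapply(same_len, function(x) {
      sum(chars(x) != wc) == 1L
    }, logical(1L)))
  } else {
    sum(old_distance(rep(word, length(words)), words) <= radius)
  }
}

# Floor zero (or missing) frequencies at half the minimum positive value.
floor_freqs <- function(freq) {
  pos <- freq[is.finite(freq) & freq > 0]
  if (length(pos) == 0L) stop_input("no positive frequencies in norms")
  fl <- min(pos) / 2
  freq[!is.finite(freq) | freq <= 0] <- fl
  freq
}

#' Assemble lexical norms
#'
#' @param word_freq Named numeric vector, word -> frequency.
#' @param bigram_freq Named numeric vector, bigram -> frequency.
#' @param letter_freq Named numeric vector, letter -> frequency.
#' @param lexicon Character vector of words (defaults to
#'   `names(word_freq)`).
#' @return A list of class `lexical_norms`, all frequencies floored to be
#'   strictly positive.
#' @export
lexical_norms <- function(word_freq, bigram_freq, letter_freq,
                          lexicon = names(word_freq)) {
  if (anyDuplicated(lexicon)) stop_input("lexicon words must be unique")
  structure(list(word_freq = floor_freqs(word_freq),
                 bigram_freq = floor_freqs(bigram_freq),
                 letter_freq = floor_freqs(letter_freq),
                 lexicon = lexicon),
            class = "lexical_norms")
}

string_bigrams <- function(s) {
  cs <- chars(s)
  if (length(cs) < 2L) return(character(0))
  paste0(cs[-length(cs)], cs[-1L])
}

#' Lexical feature table for a set of strings
#'
#' Per string: log word frequency (words only; `NA` for nonwords), mean
#' log bigram frequency, mean log letter frequency, and orthographic
#' neighbor count. Frequencies absent from the norms are floored at half
#' the smallest positive norm frequency before the log.
#'
#' @param strings Character vector.
#' @param norms A [lexical_norms()].
#' @param log_base Base of the logarithm (default natural).
#' @return Data frame: `string`, `is_word`, `log_word_freq`,
#'   `mean_log_bigram_freq`, `mean_log_letter_freq`, `n_neighbors`.
#' @export
lexical_features <- function(strings, norms, log_base = exp(1)) {
  if (any(nchar(strings) == 0L)) stop_input("empty string in input")
  lg <- function(x) log(x, base = log_base)
  bigram_floor <- min(norms$bigram_freq) / 2
  letter_floor <- min(norms$letter_freq) / 2
  get_freq <- function(tokens, table, floor_val) {
    f <- table[tokens]
    f[is.na(f)] <- floor_val
    f
  }
  rows <- lapply(strings, function(s) {
    bgs <- string_bigrams(s)
    data.frame(
      string = s,
      is_word = as.integer(s %in% norms$lexicon),
      log_word_freq = if (s %in% names(norms$word_freq))
        lg(norms$word_freq[[s]]) else NA_real_,
      mean_log_bigram_freq = if (length(bgs) == 0L) NA_real_ else
        mean(lg(get_freq(bgs, norms$bigram_freq, bigram_floor))),
      mean_log_letter_freq =
        mean(lg(get_freq(chars(s), norms$letter_freq, letter_floor))),
      n_neighbors = orthographic_neighbors(s, norms$lexicon),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance from a nonword to its nearest word
#'
#' Minimum compositional-model dissimilarity between the nonword and any
#' same-length lexicon word (the letter model requires equal lengths;
#' use [old_distance()] for cross-length checks). Ties are broken by
#' lexicographic word order.
#'
#' @param nonword A string.
#' @param lexicon Character vector of words or a `lexicon` object.
#' @param code A [letter_code()].
#' @param weights A [spatial_weights()] for the nonword's length, or a
#'   list of weight sets named by length.
#' @param metric See [model_dissimilarity()].
#' @return List: `d` (the minimum distance) and `nearest_word`.
#' @export
nonword_distance <- function(nonword, lexicon, code, weights,
                             metric = c("euclidean", "mean_abs")) {
  metric <- match.arg(metric)
  words <- if (inherits(lexicon, "lexicon")) lexicon$words else
    as.character(lexicon)
  len <- nchar(nonword)
  cands <- sort(words[nchar(words) == len])
  if (length(cands) == 0L)
    stop_input("no length-%d word in the lexicon for '%s'", len, nonword)
  w <- if (inherits(weights, "spatial_weights")) weights else {
    out <- weights[[as.character(len)]]
    if (is.null(out)) stop_input("no weights supplied for length %d", len)
    out
  }
  d <- vapply(cands,
              function(x) model_dissimilarity(code, w, nonword, x, metric),
              numeric(1L))
  i <- which.min(d)  # which.min takes the first, i.e. lexicographic tie-break
  list(d = unname(d[i]), nearest_word = cands[i])
}

#' Fit a linear reaction-time model
#'
#' Ordinary least squares of the target (`rt` or `reciprocal_rt`) on the
#' named predictor columns. For the classic nonword model, regress
#' `reciprocal_rt` on the model distance: RT = 1/(alpha d + beta) is
#' linear on the reciprocal scale.
#'
#' @param data Data frame with an `rt` column plus predictor columns.
#' @param predictors Character vector of predictor column names; empty
#'   for an intercept-only model.
#' @param target `"rt"` (default) or `"reciprocal_rt"`.
#' @return List of class `rt_model_fit`: `coefficients`, `r` (correlation
#'   of fitted vs observed target; 0 for intercept-only),
#'   `condition_number` of the design, `predicted` (on the target scale),
#'   `target`, `predictors`.
#' @export
fit_rt_model <- function(data, predictors, target = c("rt", "reciprocal_rt")) {
  target <- match.arg(target)
  y <- if (target == "rt") data$rt else 1 / data$rt
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  for (p in predictors) {
    if (!p %in% names(data)) stop_input("predictor '%s' missing from data", p)
    if (anyNA(data[[p]]))
      stop_input("predictor '%s' has missing values; apply a feature policy first", p)
    X <- cbind(X, data[[p]])
  }
  colnames(X) <- c("(Intercept)", predictors)
  sv <- svd(X)$d
  kappa <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  fit <- lm.fit(X, y)
  if (anyNA(fit$coefficients))
    stop_input("singular RT-model fit; collinear predictors (condition number %.3g)",
               kappa)
  pred <- as.numeric(X %*% fit$coefficients)
  r <- if (length(predictors) == 0L || sd(pred) == 0) 0 else cor(pred, y)
  structure(list(coefficients = fit$coefficients, r = r,
                 condition_number = kappa, predicted = pred,
                 target = target, predictors = predictors),
            class = "rt_model_fit")
}

#' @export
print.rt_model_fit <- function(x, ...) {
  cat(sprintf("RT model (%s ~ %s): r = %.3f\n", x$target,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$r))
  invisible(x)
}

#' Exclude low-accuracy strings from a lexical trial table
#'
#' Strings whose mean accuracy across trials falls below `threshold`
#' (conventionally 20%) are removed before modelling: near-floor
#' accuracy marks items subjects could not classify at all, whose RTs
#' are uninterpretable.
#'
#' @param trials Lexical trial table (`string`, `rt_s`, `correct`, ...).
#' @param threshold Minimum mean accuracy to keep a string (default 0.2).
#' @return The filtered table, with attribute `excluded_strings`.
#' @export
exclude_low_accuracy <- function(trials, threshold = 0.2) {
  acc <- vapply(split(trials$correct, trials$string), mean, numeric(1L))
  bad <- names(acc)[acc < threshold]
  out <- trials[!trials$string %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_strings") <- bad
  out
}

# Per-string mean RT for a subject subset of a lexical trial table.
mean_rt_by_string <- function(trials, subjects) {
  sub <- trials[trials$subject_id %in% subjects & trials$correct == 1, ,
                drop = FALSE]
  vapply(split(sub$rt_s, sub$string), mean, numeric(1L))
}

#' Cross-validated bootstrap comparison of RT models
#'
#' On each of `n_boot` random splits, subjects are halved; every model is
#' fitted to the train-half per-string mean RTs and its predictions are
#' correlated with the test-half mean RTs. Returns per-model mean and sd
#' of the cross-validated correlation, and for every model pair the
#' exceedance probability `p(A < B)`: the fraction of splits in which
#' model A's correlation fell below model B's, with exact ties counted
#' half so that equivalent models calibrate to p = 0.5.
#'
#' @param models Named list; each element is a list with `predictors`
#'   (character vector of feature columns) and optionally `target`.
#' @param trials Lexical trial table with >= 4 subjects.
#' @param features Data frame keyed by `string` carrying the predictor
#'   columns.
#' @param n_boot Number of random splits (default 1000).
#' @param seed Integer seed.
#' @return List of class `model_comparison`: `summary` (model, mean_r,
#'   sd_r), `exceedance` (matrix of p(row < col)), `r_matrix` (splits x
#'   models).
#' @export
crossval_compare <- function(models, trials, features, n_boot = 1000,
                             seed = NULL) {
  subjects <- sort(unique(trials$subject_id))
  if (length(subjects) < 4L) stop_input("need >= 4 subjects")
  if (is.null(names(models)) || any(names(models) == ""))
    stop_input("models must be a named list")
  feat <- features[match(sort(unique(trials$string)), features$string), ,
                   drop = FALSE]
  if (anyNA(feat$string)) stop_input("features missing for some strings")
  n_models <- length(models)
  failures <- integer(n_models)
  r_mat <- local_seed(seed, {
    out <- matrix(NA_real_, n_boot, n_models,
                  dimnames = list(NULL, names(models)))
    for (b in seq_len(n_boot)) {
      h1 <- sample(subjects, floor(length(subjects) / 2))
      tr <- mean_rt_by_string(trials, h1)
      te <- mean_rt_by_string(trials, setdiff(subjects, h1))
      shared <- intersect(names(tr), names(te))
      df <- feat[match(shared, feat$string), , drop = FALSE]
      df$rt <- tr[shared]
      for (mi in seq_len(n_models)) {
        spec <- models[[mi]]
        target <- if (is.null(spec$target)) "rt" else spec$target
        ok <- tryCatch({
          fit <- fit_rt_model(df, spec$predictors, target)
          pred <- fit$predicted
          obs <- if (target == "rt") te[shared] else 1 / te[shared]
          out[b, mi] <- if (sd(pred) == 0) 0 else cor(pred, obs)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) failures[mi] <- failures[mi] + 1L
      }
    }
    out
  })
  if (any(failures > 0.1 * n_boot))
    stop_input("model(s) failed to fit on >10%% of splits: %s",
               paste(names(models)[failures > 0.1 * n_boot], collapse = ", "))
  exceed <- matrix(NA_real_, n_models, n_models,
                   dimnames = list(names(models), names(models)))
  for (i in seq_len(n_models))
    for (j in seq_len(n_models))
      if (i != j)
        # ties split evenly so equivalent models calibrate to p = 0.5
        exceed[i, j] <- mean(r_mat[, i] < r_mat[, j], na.rm = TRUE) +
          0.5 * mean(r_mat[, i] == r_mat[, j], na.rm = TRUE)
  structure(list(
    summary = data.frame(model = names(models),
                         mean_r = colMeans(r_mat, na.rm = TRUE),
                         sd_r = apply(r_mat, 2L, sd, na.rm = TRUE),
                         row.names = NULL),
    exceedance = exceed, r_matrix = r_mat, n_boot = n_boot),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Cross-validated model comparison (%d splits):\n", x$n_boot))
  print(transform(x$summary, mean_r = round(mean_r, 3),
                  sd_r = round(sd_r, 3)))
  invisible(x)
}

#' Percent RT change of nonwords relative to their source words
#'
#' For every nonword category, the mean and standard error of
#' `100 * (RT_nonword - RT_sourceword) / RT_sourceword`, plus pairwise
#' rank-sum comparisons between categories. Transposition nonwords
#' (visually close to their source) typically show larger percent changes
#' than substitution nonwords, and middle manipulations larger than edge
#' manipulations.
#'
#' @param word_rts Named numeric vector of per-word mean RTs.
#' @param nonword_rts Named numeric vector of per-nonword mean RTs.
#' @param categories Data frame linking `nonword`, `source`, `category`
#'   (as from [make_nonwords()]).
#' @return List: `by_category` (category, n, mean_pct, sem_pct) and
#'   `pairwise` (category pair, rank-sum p).
#' @export
transposition_substitution_summary <- function(word_rts, nonword_rts,
                                               categories) {
  pct <- 100 * (nonword_rts[categories$nonword] -
                  word_rts[categories$source]) /
    word_rts[categories$source]
  keep <- !is.na(pct)
  pct <- pct[keep]
  cats <- categories$category[keep]
  sizes <- table(cats)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning(sprintf("excluding category(ies) with < 2 items: %s",
                    paste(small, collapse = ", ")))
    pct <- pct[!cats %in% small]
    cats <- cats[!cats %in% small]
  }
  groups <- split(unname(pct), cats)
  by_cat <- data.frame(
    category = names(groups),
    n = vapply(groups, length, integer(1L)),
    mean_pct = vapply(groups, mean, numeric(1L)),
    sem_pct = vapply(groups, function(g) sd(g) / sqrt(length(g)),
                     numeric(1L)),
    row.names = NULL)
  cats_u <- names(groups)
  pw <- if (length(cats_u) >= 2L) {
    cmb <- combn(cats_u, 2L)
    data.frame(
      category_a = cmb[1L, ], category_b = cmb[2L, ],
      p = apply(cmb, 2L, function(cc) {
        suppressWarnings(
          wilcox.test(groups[[cc[1L]]], groups[[cc[2L]]])$p.value)
      }),
      row.names = NULL)
  } else NULL
  list(by_category = by_cat, pairwise = pw)
}
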