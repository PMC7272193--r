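## Synthetic-data generators: every input the pipeline consumes can be
## produced here with the statistical structure the analyses assume, so
## all downstream stages are testable without any external data.

#' Generate a random letter code
#'
#' Draws per-neuron letter responses uniformly on [0, 1] and mean-centers
#' each neuron, giving every neuron nonzero variance across letters. Used
#' as ground truth for simulations; real codes come from [embed_mds()].
#'
#' @param n_neurons Number of artificial neurons (>= 1).
#' @param alphabet Character vector of at least two distinct letters.
#' @param seed Integer seed; output is a pure function of the inputs.
#' @return A [letter_code()].
#' @examples
#' make_letter_code(10, LETTERS, seed = 1)
#' @export
make_letter_code <- function(n_neurons, alphabet, seed) {
  if (length(alphabet) == 0L) stop_input("alphabet must be non-empty")
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet)) stop_input("alphabet letters must be distinct")
  if (length(alphabet) < 2L)
    stop_input("at least two letters are needed for nonzero tuning variance")
  if (n_neurons < 1L) stop_input("n_neurons must be >= 1")
  resp <- local_seed(seed,
                     matrix(runif(n_neurons * length(alphabet)),
                            n_neurons, length(alphabet)))
  resp <- resp - rowMeans(resp)
  # runif ties have probability zero, but guard the invariant anyway
  if (any(apply(resp, 1L, var) == 0))
    stop_input("degenerate draw: a neuron has zero variance across letters")
  letter_code(resp, alphabet)
}

#' Bundle a ground-truth generative model for search simulations
#'
#' @param code A [letter_code()] (the true single-letter responses).
#' @param weights A [spatial_weights()], or a list of them named by string
#'   length (e.g. `list("4" = w4, "5" = w5)`) when stimuli mix lengths.
#' @param rt_scale Seconds x dissimilarity: RT = rt_scale / dissimilarity.
#' @param noise_sigma Lognormal sd of multiplicative trial noise (>= 0).
#' @param baseline Optional additive rate baseline t0 in 1/RT = d/rt_scale + t0.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(code, weights, rt_scale = 1, noise_sigma = 0,
                         baseline = 0) {
  stopifnot(inherits(code, "letter_code"))
  if (rt_scale <= 0) stop_input("rt_scale must be positive")
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  structure(list(code = code, weights = weights, rt_scale = rt_scale,
                 noise_sigma = noise_sigma, baseline = baseline),
            class = "ground_truth")
}

weights_for_length <- function(gt, len) {
  w <- gt$weights
  if (inherits(w, "spatial_weights")) {
    if (w$string_length != len)
      stop_input("ground-truth weights cover %d positions, not %d",
                 w$string_length, len)
    return(w)
  }
  out <- w[[as.character(len)]]
  if (is.null(out)) stop_input("no ground-truth weights for length %d", len)
  out
}

#' Simulate oddball-search trials
#'
#' Each subject sees every unordered stimulus pair `n_reps` times, with
#' either member serving as the oddball target equally often. Trial RTs
#' follow the reciprocal law the analysis assumes: the evidence-
#' accumulation rate is `1/RT = d/rt_scale + baseline`, where `d` is the
#' ground-truth model dissimilarity of the pair, with multiplicative
#' lognormal noise of sd `noise_sigma`. With `noise_sigma = 0`, reciprocal
#' mean RTs are exactly proportional to the ground-truth dissimilarities.
#'
#' @param gt A [ground_truth()].
#' @param pairs Data frame with columns `item_a`, `item_b` (equal-length
#'   strings over the code's alphabet).
#' @param n_subjects,n_reps Counts (default one subject, two repetitions).
#' @param seed Integer seed.
#' @return A trial table: `subject_id`, `item_a`, `item_b`, `target_is_a`
#'   (0/1), `rt_s`, `correct` (all 1; accuracy is at ceiling by design),
#'   `block`.
#' @export
simulate_search_trials <- function(gt, pairs, n_subjects = 1, n_reps = 2,
                                   seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  pairs <- canonical_pairs(pairs$item_a, pairs$item_b)
  len <- nchar(pairs$item_a[1L])
  w <- weights_for_length(gt, len)
  d <- predict_dissimilarities(gt$code, w, pairs)
  zero <- d <= 0
  if (any(zero))
    stop_input("pair(s) with zero model dissimilarity (infinite RT): %s",
               paste(pairs$item_a[zero], pairs$item_b[zero], sep = "-",
                     collapse = ", "))
  rate <- d / gt$rt_scale + gt$baseline
  n_pairs <- nrow(pairs)
  grid <- expand.grid(rep = seq_len(n_reps), pair = seq_len(n_pairs),
                      subject = seq_len(n_subjects))
  rt_mean <- 1 / rate[grid$pair]
  rts <- local_seed(seed,
                    rt_mean * exp(rnorm(nrow(grid), 0, gt$noise_sigma)))
  data.frame(subject_id = grid$subject,
             item_a = pairs$item_a[grid$pair],
             item_b = pairs$item_b[grid$pair],
             target_is_a = as.integer(grid$rep %% 2L == 1L),
             rt_s = rts,
             correct = 1L,
             block = grid$rep,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic lexicon with Zipf-distributed frequencies
#'
#' @param n_words Number of distinct words.
#' @param length Word length in letters.
#' @param alphabet Character vector of available letters.
#' @param zipf_exponent Frequencies are proportional to rank^(-exponent);
#'   0 gives a flat frequency profile.
#' @param seed Integer seed.
#' @return An object of class `lexicon`: `words`, `frequencies` (aligned,
#'   strictly positive, non-increasing), `alphabet`, `length`.
#' @export
make_lexicon <- function(n_words, length, alphabet, zipf_exponent = 1,
                         seed = NULL) {
  alphabet <- as.character(alphabet)
  K <- base::length(alphabet)
  if (K < 1L) stop_input("alphabet must be non-empty")
  total <- K^length
  if (total < n_words)
    stop_input("alphabet of %d letters yields only %g distinct strings of length %d (need %d)",
               K, total, length, n_words)
  words <- local_seed(seed, {
    if (total <= 1e6) {
      idx <- sample.int(total, n_words) - 1L
      vapply(idx, function(i) {
        digits <- integer(length)
        for (p in seq_len(length)) {
          digits[p] <- i %% K
          i <- i %/% K
        }
        paste(alphabet[digits + 1L], collapse = "")
      }, character(1L))
    } else {
      out <- character(0)
      while (base::length(out) < n_words) {
        cand <- vapply(seq_len(n_words),
                       function(i) paste(sample(alphabet, length, replace = TRUE),
                                         collapse = ""),
                       character(1L))
        out <- unique(c(out, cand))
      }
      out[seq_len(n_words)]
    }
  })
  freq <- seq_len(n_words)^(-zipf_exponent)
  structure(list(words = words, frequencies = freq, alphabet = alphabet,
                 length = length), class = "lexicon")
}

#' The nonword-generation scheme of the lexical-decision study
#'
#' Counts of nonwords per manipulation category and word length: edge and
#' middle transpositions (adjacent swaps), two-step transpositions (swaps
#' across one intervening letter; impossible for four-letter words),
#' random transpositions (arbitrary reshuffles), edge and middle
#' substitutions (two adjacent letters replaced), and combined random
#' substitution-plus-permutation.
#'
#' @return Data frame with columns `category`, `len4`, `len5`, `len6`.
#' @export
nonword_scheme <- function() {
  data.frame(
    category = c("edge_transposition", "middle_transposition",
                 "two_step_edge_transposition", "two_step_middle_transposition",
                 "random_transposition", "edge_substitution",
                 "middle_substitution", "random_substitution_permutation"),
    len4 = c(15L, 15L, 0L, 0L, 25L, 15L, 15L, 15L),
    len5 = c(15L, 15L, 20L, 20L, 35L, 15L, 15L, 15L),
    len6 = c(20L, 20L, 30L, 30L, 40L, 20L, 20L, 20L),
    stringsAsFactors = FALSE)
}

swap_at <- function(s, i, j) {
  cs <- chars(s)
  tmp <- cs[i]
  cs[i] <- cs[j]
  cs[j] <- tmp
  paste(cs, collapse = "")
}

# One nonword from `word` under `category`; `alphabet` supplies substitution
# letters. Pure given the RNG state.
apply_category <- function(word, category, alphabet) {
  n <- nchar(word)
  cs <- chars(word)
  sub_pool <- setdiff(alphabet, cs)
  pick <- function(k) sample(sub_pool, k)
  switch(category,
    edge_transposition = {
      i <- if (sample(2L, 1L) == 1L) 1L else n - 1L
      swap_at(word, i, i + 1L)
    },
    middle_transposition = {
      if (n < 4L) stop_input("middle transposition needs length >= 4")
      i <- sample(2:(n - 2L), 1L)
      swap_at(word, i, i + 1L)
    },
    two_step_edge_transposition = {
      if (n < 5L)
        stop_input("two-step edge transposition impossible for length %d", n)
      i <- if (sample(2L, 1L) == 1L) 1L else n - 2L
      swap_at(word, i, i + 2L)
    },
    two_step_middle_transposition = {
      if (n < 5L)
        stop_input("two-step middle transposition impossible for length %d", n)
      i <- sample(2:(n - 3L), 1L)
      swap_at(word, i, i + 2L)
    },
    random_transposition = {
      for (attempt in 1:50) {
        cand <- paste(sample(cs), collapse = "")
        if (cand != word) return(cand)
      }
      stop_input("could not reshuffle '%s' into a different string", word)
    },
    edge_substitution = {
      if (length(sub_pool) < 2L)
        stop_input("alphabet too small to substitute letters absent from '%s'",
                   word)
      i <- if (sample(2L, 1L) == 1L) 1L else n - 1L
      cs[c(i, i + 1L)] <- pick(2L)
      paste(cs, collapse = "")
    },
    middle_substitution = {
      if (n < 4L) stop_input("middle substitution needs length >= 4")
      if (length(sub_pool) < 2L)
        stop_input("alphabet too small to substitute letters absent from '%s'",
                   word)
      i <- sample(2:(n - 2L), 1L)
      cs[c(i, i + 1L)] <- pick(2L)
      paste(cs, collapse = "")
    },
    random_substitution_permutation = {
      if (length(sub_pool) < 2L)
        stop_input("alphabet too small to substitute letters absent from '%s'",
                   word)
      cs2 <- sample(cs)
      cs2[sample(n, 2L)] <- pick(2L)
      paste(cs2, collapse = "")
    },
    stop_input("unknown nonword category '%s'", category))
}

#' Generate nonwords from a lexicon under a category scheme
#'
#' Each selected word yields one nonword whose difference from its source
#' is exactly what its category prescribes (a transposition swaps two
#' letters at the stated offsets; a substitution replaces letters by
#' letters absent from the word). Nonwords never collide with lexicon
#' words.
#'
#' @param lexicon A [make_lexicon()] result, or a list of them (one per
#'   word length). Word lengths must cover the scheme's nonzero counts.
#' @param scheme Data frame like [nonword_scheme()]: `category` plus
#'   `len<k>` count columns.
#' @param seed Integer seed.
#' @return Data frame: `nonword`, `source`, `category`, `length`.
#' @export
make_nonwords <- function(lexicon, scheme = nonword_scheme(), seed = NULL) {
  lexica <- if (inherits(lexicon, "lexicon")) list(lexicon) else lexicon
  by_len <- setNames(lexica,
                     vapply(lexica, function(l) as.character(l$length),
                            character(1L)))
  all_words <- unlist(lapply(lexica, `[[`, "words"), use.names = FALSE)
  len_cols <- grep("^len", names(scheme), value = TRUE)
  local_seed(seed, {
    rows <- list()
    for (col in len_cols) {
      len <- as.integer(sub("len", "", col))
      counts <- scheme[[col]]
      if (sum(counts) == 0L) next
      impossible <- counts > 0L & len < 5L &
        grepl("two_step", scheme$category)
      if (any(impossible))
        stop_input("category '%s' impossible for length %d (count must be 0)",
                   scheme$category[which(impossible)[1L]], len)
      lex <- by_len[[as.character(len)]]
      if (is.null(lex))
        stop_input("no lexicon of length-%d words supplied", len)
      if (sum(counts) > length(lex$words))
        stop_input("scheme needs %d length-%d words but lexicon has %d",
                   sum(counts), len, length(lex$words))
      # words that cannot realize a category (e.g. a transposition across
      # identical letters) are skipped and another pool word is tried
      available <- sample(lex$words)
      for (ci in seq_along(scheme$category)) {
        if (counts[ci] == 0L) next
        for (j in seq_len(counts[ci])) {
          nw <- NULL
          for (wi in seq_along(available)) {
            word <- available[wi]
            for (attempt in 1:50) {
              cand <- tryCatch(
                apply_category(word, scheme$category[ci], lex$alphabet),
                error = function(e) word)
              if (cand != word && !(cand %in% all_words)) {
                nw <- cand
                break
              }
            }
            if (!is.null(nw)) {
              available <- available[-wi]
              break
            }
          }
          if (is.null(nw))
            stop_input("no remaining length-%d word can yield a '%s' nonword outside the lexicon",
                       len, scheme$category[ci])
          rows[[length(rows) + 1L]] <-
            data.frame(nonword = nw, source = word,
                       category = scheme$category[ci], length = len,
                       stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate lexical-decision trials
#'
#' Word RTs decrease with log frequency (`a - b * log(f)`); nonword RTs
#' are inversely related to the model distance from the nonword to its
#' nearest word (`c / (alpha * d + beta)`): a nonword close to a stored
#' word is hard to reject. Gaussian trial noise is added and RTs truncated
#' to stay positive.
#'
#' @param gt A [ground_truth()] whose code/weights cover the word lengths.
#' @param lexicon A `lexicon` or list of lexica (per length).
#' @param nonwords Output of [make_nonwords()].
#' @param rt_params List: `word_intercept` (a), `word_slope` (b),
#'   `nonword_scale` (c), `alpha`, `beta`, `noise_sd`.
#' @param n_subjects Number of simulated subjects (one trial per string
#'   per subject).
#' @param seed Integer seed.
#' @return Trial table: `subject_id`, `string`, `is_word` (0/1), `rt_s`,
#'   `correct` (all 1).
#' @export
simulate_lexical_trials <- function(gt, lexicon, nonwords, rt_params,
                                    n_subjects = 16, seed = NULL) {
  p <- rt_params
  needed <- c("word_intercept", "word_slope", "nonword_scale", "alpha",
              "beta", "noise_sd")
  if (!all(needed %in% names(p)))
    stop_input("rt_params must supply: %s", paste(needed, collapse = ", "))
  if (p$noise_sd < 0) stop_input("noise_sd must be >= 0")
  lexica <- if (inherits(lexicon, "lexicon")) list(lexicon) else lexicon
  words <- unlist(lapply(lexica, `[[`, "words"), use.names = FALSE)
  freqs <- unlist(lapply(lexica, `[[`, "frequencies"), use.names = FALSE)

  word_mu <- p$word_intercept - p$word_slope * log(freqs)
  d_near <- vapply(seq_len(nrow(nonwords)), function(i) {
    len <- nonwords$length[i]
    w <- weights_for_length(gt, len)
    cands <- words[nchar(words) == len]
    nonword_distance(nonwords$nonword[i], cands, gt$code, w)$d
  }, numeric(1L))
  if (any(d_near <= 0))
    stop_input("nonword(s) at zero distance to a word: %s",
               paste(nonwords$nonword[d_near <= 0], collapse = ", "))
  nw_mu <- p$nonword_scale / (p$alpha * d_near + p$beta)

  strings <- c(words, nonwords$nonword)
  mus <- c(word_mu, nw_mu)
  is_word <- rep(c(1L, 0L), c(length(words), nrow(nonwords)))
  grid <- expand.grid(string = seq_along(strings),
                      subject = seq_len(n_subjects))
  rts <- local_seed(seed,
                    pmax(mus[grid$string] + rnorm(nrow(grid), 0, p$noise_sd),
                         1e-3))
  data.frame(subject_id = grid$subject,
             string = strings[grid$string],
             is_word = is_word[grid$string],
             rt_s = rts,
             correct = 1L,
             stringsAsFactors = FALSE)
}

#' Simulate multi-run voxel patterns
#'
#' Independent Gaussian noise around condition means, one pattern per run
#' and condition; the multi-run structure is what cross-validated distance
#' estimators ([crossnobis()]) need.
#'
#' @param condition_means Numeric matrix, conditions x voxels, with row
#'   names naming the conditions.
#' @param n_runs Number of runs (>= 2; cross-validation needs two).
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return A 3-d array `[run, condition, voxel]` with condition dimnames.
#' @export
simulate_voxel_patterns <- function(condition_means, n_runs, noise_sd = 1,
                                    seed = NULL) {
  condition_means <- as.matrix(condition_means)
  if (n_runs < 2L) stop_input("n_runs must be >= 2 for cross-validation")
  if (is.null(rownames(condition_means)))
    rownames(condition_means) <- paste0("cond", seq_len(nrow(condition_means)))
  n_cond <- nrow(condition_means)
  n_vox <- ncol(condition_means)
  arr <- local_seed(seed, {
    noise <- array(rnorm(n_runs * n_cond * n_vox, 0, noise_sd),
                   dim = c(n_runs, n_cond, n_vox))
    base <- aperm(array(condition_means, dim = c(n_cond, n_vox, n_runs)),
                  c(3L, 1L, 2L))
    base + noise
  })
  dimnames(arr) <- list(paste0("run", seq_len(n_runs)),
                        rownames(condition_means), NULL)
  arr
}

#' Generate clustered word embeddings
#'
#' Words are assigned to clusters with exactly orthonormal centers (so
#' with zero noise, across-cluster cosine dissimilarity is exactly 1 and
#' within-cluster dissimilarity exactly 0) plus Gaussian jitter.
#'
#' @param words Character vector.
#' @param n_dims Embedding dimension (>= 2, and >= n_clusters).
#' @param n_clusters Number of semantic clusters (<= number of words).
#' @param noise_sd Jitter sd (default 0.1).
#' @param seed Integer seed.
#' @return Numeric matrix, words x dims, with word row names.
#' @export
make_embeddings <- function(words, n_dims, n_clusters = 1, noise_sd = 0.1,
                            seed = NULL) {
  if (n_dims < 2L) stop_input("n_dims must be >= 2")
  if (n_clusters > length(words))
    stop_input("more clusters (%d) than words (%d)", n_clusters, length(words))
  if (n_clusters > n_dims)
    stop_input("orthogonal cluster centers need n_clusters <= n_dims")
  local_seed(seed, {
    centers <- qr.Q(qr(matrix(rnorm(n_dims * n_clusters), n_dims, n_clusters)))
    assign <- rep_len(seq_len(n_clusters), length(words))
    emb <- t(centers[, assign, drop = FALSE]) +
      matrix(rnorm(length(words) * n_dims, 0, noise_sd), length(words), n_dims)
    rownames(emb) <- words
    attr(emb, "cluster") <- assign
    emb
  })
}
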