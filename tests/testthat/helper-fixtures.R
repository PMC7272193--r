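# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

all_pairs_of <- function(items) lettercode:::all_pairs(items)

# All 2-letter strings over a letter set.
bigrams_of <- function(letters) as.vector(outer(letters, letters, paste0))

# A small noiseless bigram study generated from known code and weights.
noiseless_bigram_study <- function(n_neurons = 3, letters = LETTERS[1:5],
                                   code_seed = 7, weight_seed = 8,
                                   metric = "euclidean") {
  code <- make_letter_code(n_neurons, letters, seed = code_seed)
  w <- withr::with_seed(weight_seed,
                        spatial_weights(matrix(runif(n_neurons * 2, 0.3, 1),
                                               n_neurons, 2)))
  pairs <- all_pairs_of(bigrams_of(letters))
  d <- predict_dissimilarities(code, w, pairs, metric = metric)
  list(code = code, weights = w, pairs = pairs,
       observed = dissimilarity_table(pairs$item_a, pairs$item_b, d))
}

# A one-neuron code with prescribed responses, for hand arithmetic.
hand_code <- function(responses) {
  letter_code(matrix(responses, nrow = 1,
                     dimnames = list(NULL, names(responses))),
              names(responses))
}

# Independent dynamic-programming LCS oracle (longest common subsequence).
lcs_length <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

random_string <- function(len, alphabet = LETTERS[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# The sparse-lexicon study used for end-to-end lexical-decision checks:
# edge-weighted summation profile over five positions.
edge_weighted_study <- function(n_per_category = 10, n_subjects = 16,
                                noise_sd = 0.04, seed = 5) {
  alpha <- LETTERS[1:20]
  code <- make_letter_code(10, alpha, seed = seed)
  prof <- c(1.0, 0.55, 0.40, 0.55, 1.0)
  w5 <- spatial_weights(matrix(rep(prof, each = 10), 10, 5))
  lex <- make_lexicon(40, 5, alpha, 1, seed = seed + 1)
  sch <- data.frame(
    category = c("edge_transposition", "middle_transposition",
                 "edge_substitution", "middle_substitution"),
    len5 = rep(as.integer(n_per_category), 4))
  nw <- make_nonwords(lex, sch, seed = seed + 2)
  gt <- ground_truth(code, w5)
  trials <- simulate_lexical_trials(
    gt, lex, nw,
    list(word_intercept = 0.65, word_slope = 0.03, nonword_scale = 0.8,
         alpha = 1, beta = 0.6, noise_sd = noise_sd),
    n_subjects = n_subjects, seed = seed + 3)
  list(code = code, weights = w5, lexicon = lex, nonwords = nw,
       trials = trials)
}
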