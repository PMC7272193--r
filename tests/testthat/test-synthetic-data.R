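# Synthetic generators: determinism, degenerate inputs, and the
# statistical structure downstream stages assume.

test_that("letter-code generation is a pure function of its seed", {
  a <- make_letter_code(10, LETTERS, seed = 1)
  b <- make_letter_code(10, LETTERS, seed = 1)
  c <- make_letter_code(10, LETTERS, seed = 2)
  expect_identical(a$responses, b$responses)
  expect_false(all(a$responses == c$responses))
  expect_true(all(is.finite(a$responses)))
  expect_true(all(apply(a$responses, 1, var) > 0))
  expect_error(make_letter_code(10, character(0), seed = 1), "non-empty")
  expect_error(make_letter_code(1, "A", seed = 1), "two letters")
})

test_that("search scheduler balances targets and repetitions", {
  lets <- LETTERS[1:5]
  code <- make_letter_code(4, lets, seed = 2)
  gt <- ground_truth(code, spatial_weights(matrix(1, 4, 1)),
                     noise_sigma = 0.2)
  tr <- simulate_search_trials(gt, all_pairs_of(lets), n_subjects = 3,
                               n_reps = 4, seed = 9)
  expect_equal(nrow(tr), choose(5, 2) * 4 * 3)
  counts <- table(paste(tr$item_a, tr$item_b), tr$subject_id)
  expect_true(all(counts == 4))
  # either member is target equally often
  bal <- tapply(tr$target_is_a, paste(tr$item_a, tr$item_b), mean)
  expect_true(all(bal == 0.5))
  expect_true(all(tr$rt_s > 0))
  expect_identical(tr, simulate_search_trials(gt, all_pairs_of(lets),
                                              n_subjects = 3, n_reps = 4,
                                              seed = 9))
})

test_that("noiseless search RTs are exactly reciprocal in the model dissimilarity", {
  study <- noiseless_bigram_study()
  gt <- ground_truth(study$code, study$weights, rt_scale = 2,
                     noise_sigma = 0)
  tr <- simulate_search_trials(gt, study$pairs, n_subjects = 2, n_reps = 2,
                               seed = 1)
  D <- dissimilarity_from_trials(tr)
  truth <- predict_dissimilarities(study$code, study$weights,
                                   D[, c("item_a", "item_b")])
  # single global scale factor (rt_scale), tight tolerance
  expect_lt(max(abs(D$d * 2 / truth - 1)), 1e-10)
})

test_that("zero-dissimilarity pairs are rejected with the pair named", {
  # duplicate letter columns make AB vs BA indistinguishable under equal weights
  code <- letter_code(matrix(c(0, 1, 0, 1), 2, 2,
                             dimnames = list(NULL, c("A", "B"))))
  gt <- ground_truth(code, spatial_weights(matrix(1, 2, 2)))
  pairs <- data.frame(item_a = "AB", item_b = "BA")
  expect_error(simulate_search_trials(gt, pairs, seed = 1),
               "zero model dissimilarity.*AB-BA")
})

test_that("lexicon generation gives unique Zipf-weighted words", {
  lex <- make_lexicon(32, 5, LETTERS[1:10], 1.0, seed = 3)
  expect_length(unique(lex$words), 32)
  expect_true(all(nchar(lex$words) == 5))
  expect_true(all(strsplit(paste(lex$words, collapse = ""), "")[[1]] %in%
                    LETTERS[1:10]))
  expect_equal(lex$frequencies, (1:32)^(-1))
  flat <- make_lexicon(10, 3, LETTERS[1:4], 0, seed = 4)
  expect_true(all(flat$frequencies == 1))
  # exhaustive two-word case: the words must be exactly {A, B}
  tiny <- make_lexicon(2, 1, c("A", "B"), 1, seed = 5)
  expect_setequal(tiny$words, c("A", "B"))
  expect_error(make_lexicon(5, 1, c("A", "B"), 1, seed = 1), "distinct")
})

test_that("nonword categories prescribe the difference from the source exactly", {
  lex <- make_lexicon(60, 5, LETTERS[1:12], 1, seed = 6)
  sch <- data.frame(category = c("edge_transposition", "middle_transposition",
                                 "two_step_edge_transposition",
                                 "two_step_middle_transposition",
                                 "random_transposition",
                                 "edge_substitution", "middle_substitution",
                                 "random_substitution_permutation"),
                    len5 = c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L))
  nw <- make_nonwords(lex, sch, seed = 7)
  expect_equal(nrow(nw), 40)
  expect_true(all(!nw$nonword %in% lex$words))
  expect_true(all(nw$nonword != nw$source))
  for (i in seq_len(nrow(nw))) {
    s <- strsplit(nw$source[i], "")[[1]]
    n <- strsplit(nw$nonword[i], "")[[1]]
    diffs <- which(s != n)
    cat_i <- nw$category[i]
    if (cat_i %in% c("edge_transposition", "middle_transposition")) {
      expect_length(diffs, 2)
      expect_equal(diff(diffs), 1)           # adjacent swap
      expect_equal(s[diffs], rev(n[diffs]))  # a true transposition
      if (cat_i == "edge_transposition")
        expect_true(1 %in% diffs || 5 %in% diffs)
      else expect_true(all(diffs %in% 2:4))
    }
    if (cat_i %in% c("two_step_edge_transposition",
                     "two_step_middle_transposition")) {
      expect_length(diffs, 2)
      expect_equal(diff(diffs), 2)
      expect_equal(s[diffs], rev(n[diffs]))
    }
    if (cat_i == "random_transposition")
      expect_equal(sort(s), sort(n))         # same multiset of letters
    if (cat_i %in% c("edge_substitution", "middle_substitution")) {
      expect_length(diffs, 2)
      expect_equal(diff(diffs), 1)
      expect_true(all(!n[diffs] %in% s))     # letters absent from the word
      if (cat_i == "edge_substitution")
        expect_true(1 %in% diffs || 5 %in% diffs)
      else expect_true(all(diffs %in% 2:4))
    }
  }
})

test_that("edge transposition of PENCIL yields EPNCIL or PENCLI only", {
  lex <- structure(list(words = "PENCIL", frequencies = 1,
                        alphabet = LETTERS, length = 6L), class = "lexicon")
  sch <- data.frame(category = "edge_transposition", len6 = 1L)
  seen <- vapply(1:20, function(s) make_nonwords(lex, sch, seed = s)$nonword,
                 character(1))
  expect_true(all(seen %in% c("EPNCIL", "PENCLI")))
  expect_setequal(unique(seen), c("EPNCIL", "PENCLI"))
})

test_that("impossible category counts raise input errors", {
  lex4 <- make_lexicon(30, 4, LETTERS[1:10], 1, seed = 8)
  sch <- data.frame(category = "two_step_middle_transposition", len4 = 1L)
  expect_error(make_nonwords(lex4, sch, seed = 1), "impossible")
  sch2 <- data.frame(category = "edge_transposition", len4 = 99L)
  expect_error(make_nonwords(lex4, sch2, seed = 1), "lexicon has")
})

test_that("lexical RT generator is monotone in frequency and distance at zero noise", {
  study <- edge_weighted_study(n_per_category = 5, n_subjects = 2,
                               noise_sd = 0)
  tr <- study$trials
  words <- tr[tr$is_word == 1 & tr$subject_id == 1, ]
  f <- study$lexicon$frequencies[match(words$string, study$lexicon$words)]
  expect_true(all(diff(words$rt_s[order(f)]) <= 0))
  nw <- tr[tr$is_word == 0 & tr$subject_id == 1, ]
  d <- vapply(nw$string, function(s)
    nonword_distance(s, study$lexicon$words, study$code, study$weights)$d,
    numeric(1))
  expect_true(all(diff(nw$rt_s[order(d)]) <= 0))
  # determinism
  again <- edge_weighted_study(n_per_category = 5, n_subjects = 2,
                               noise_sd = 0)
  expect_identical(tr, again$trials)
})

test_that("voxel-pattern generator has the run x condition x voxel layout", {
  mu <- matrix(rnorm(74 * 12), 74, 12,
               dimnames = list(sprintf("s%02d", 1:74), NULL))
  p <- simulate_voxel_patterns(mu, n_runs = 8, noise_sd = 1, seed = 4)
  expect_equal(dim(p), c(8, 74, 12))
  expect_equal(dimnames(p)[[2]], rownames(mu))
  p0 <- simulate_voxel_patterns(mu, n_runs = 3, noise_sd = 0, seed = 4)
  for (r in 1:3) expect_equal(unname(p0[r, , ]), unname(mu))
  expect_error(simulate_voxel_patterns(mu, n_runs = 1, seed = 1), ">= 2")
})

test_that("embedding clusters control cosine structure", {
  words <- sprintf("W%02d", 1:8)
  one <- make_embeddings(words, 5, 1, noise_sd = 0, seed = 2)
  d1 <- semantic_dissimilarities(one)
  expect_true(all(abs(d1$d) < 1e-12))
  two <- make_embeddings(words, 5, 2, noise_sd = 0, seed = 3)
  cl <- attr(two, "cluster")
  d2 <- semantic_dissimilarities(two)
  across <- cl[match(d2$item_a, words)] != cl[match(d2$item_b, words)]
  expect_true(all(abs(d2$d[across] - 1) < 1e-12))
  expect_true(all(abs(d2$d[!across]) < 1e-12))
  expect_identical(two, make_embeddings(words, 5, 2, noise_sd = 0, seed = 3))
  expect_error(make_embeddings(words, 5, 9, seed = 1), "clusters")
})
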