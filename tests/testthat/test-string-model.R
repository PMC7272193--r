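# The compositional string model: responses, dissimilarities, weight
# fitting, modulation index, and jumble ranking.

test_that("string responses are weighted sums of letter responses", {
  code <- make_letter_code(3, LETTERS[1:4], seed = 1)
  ones <- spatial_weights(matrix(1, 3, 2))
  expect_equal(string_response(code, ones, "AA"),
               2 * code$responses[, "A"])
  # zero second-position weight ignores the second letter
  w10 <- spatial_weights(cbind(rep(1, 3), rep(0, 3)))
  expect_equal(string_response(code, w10, "AB"),
               string_response(code, w10, "AD"))
  # direct arithmetic oracle
  w <- spatial_weights(matrix(c(0.2, -1, 3, 0.5, 2, -0.3), 3, 2))
  got <- string_response(code, w, "AC")
  want <- w$w[, 1] * code$responses[, "A"] + w$w[, 2] * code$responses[, "C"]
  expect_equal(got, want)
  expect_error(string_response(code, w, "AZ"), "Z")
  expect_error(string_response(code, w, "ABC"), "length")
})

test_that("model dissimilarity honors both metrics and transposition blindness", {
  code <- make_letter_code(4, LETTERS[1:5], seed = 2)
  sym <- spatial_weights(matrix(0.5, 4, 2))
  expect_equal(model_dissimilarity(code, sym, "AB", "BA"), 0)
  asym <- spatial_weights(cbind(rep(1, 4), rep(0.4, 4)))
  expect_gt(model_dissimilarity(code, asym, "AB", "BA"), 0)
  # one-neuron hand case: rA=0, rB=1, rC=2, w=(1,1): |1 - 4| = 3
  hc <- hand_code(c(A = 0, B = 1, C = 2))
  w11 <- spatial_weights(matrix(1, 1, 2))
  expect_equal(model_dissimilarity(hc, w11, "AB", "CC"), 3)
  expect_equal(model_dissimilarity(hc, w11, "AB", "CC", "mean_abs"), 3)
  # identity, symmetry
  expect_equal(model_dissimilarity(code, asym, "AB", "AB"), 0)
  expect_equal(model_dissimilarity(code, asym, "AB", "CD"),
               model_dissimilarity(code, asym, "CD", "AB"))
})

test_that("euclidean model dissimilarity satisfies the triangle inequality", {
  code <- make_letter_code(5, LETTERS[1:6], seed = 3)
  w <- withr::with_seed(4, spatial_weights(matrix(rnorm(10), 5, 2)))
  bigs <- bigrams_of(LETTERS[1:6])
  withr::with_seed(5, for (i in 1:200) {
    tri <- sample(bigs, 3)
    dab <- model_dissimilarity(code, w, tri[1], tri[2])
    dbc <- model_dissimilarity(code, w, tri[2], tri[3])
    dac <- model_dissimilarity(code, w, tri[1], tri[3])
    expect_lte(dac, dab + dbc + 1e-12)
  })
})

test_that("scaling all weights scales every dissimilarity", {
  code <- make_letter_code(3, LETTERS[1:5], seed = 6)
  w <- withr::with_seed(7, matrix(runif(6), 3, 2))
  pairs <- all_pairs_of(bigrams_of(LETTERS[1:3]))
  for (metric in c("euclidean", "mean_abs")) {
    d1 <- predict_dissimilarities(code, spatial_weights(w), pairs, metric)
    d3 <- predict_dissimilarities(code, spatial_weights(3 * w), pairs, metric)
    expect_equal(d3, 3 * d1, tolerance = 1e-12)
  }
})

test_that("weight fitting recovers ground truth up to per-neuron sign", {
  for (metric in c("euclidean", "mean_abs")) {
    study <- noiseless_bigram_study(metric = metric)
    fit <- fit_weights(study$code, study$observed, metric = metric,
                       n_restarts = 4, seed = 11)
    # per-neuron sign is unidentified under the euclidean metric
    err <- pmin(abs(fit$weights$w - study$weights$w),
                abs(fit$weights$w + study$weights$w))
    expect_lt(max(err), 1e-3)
    expect_gt(fit$r, 0.999)
  }
})

test_that("more restarts never worsen the selected loss", {
  study <- noiseless_bigram_study()
  noisy <- study$observed
  noisy$d <- noisy$d * withr::with_seed(3, exp(rnorm(nrow(noisy), 0, 0.3)))
  f1 <- fit_weights(study$code, noisy, n_restarts = 1, seed = 5)
  f10 <- fit_weights(study$code, noisy, n_restarts = 10, seed = 5)
  expect_lte(f10$loss, f1$loss + 1e-10)
  expect_error(fit_weights(study$code,
                           dissimilarity_table("AB", "ABC", 1)), "length")
})

test_that("modulation index measures positional asymmetry on [0, 1]", {
  mk <- function(w1, w2) spatial_weights(matrix(c(w1, w2), 1, 2))
  expect_equal(unname(modulation_index(mk(1, 1))$per_neuron), 0)
  expect_equal(unname(modulation_index(mk(1, 0))$per_neuron), 1)
  expect_equal(unname(modulation_index(mk(3, 1))$per_neuron), 0.5)
  expect_error(modulation_index(mk(1, -1)), "undefined")
  expect_error(modulation_index(spatial_weights(matrix(1, 2, 3))),
               "two-position")
})

test_that("jumble ranking sorts by distance with the word itself first", {
  code <- make_letter_code(4, LETTERS[1:6], seed = 8)
  w <- withr::with_seed(9,
                        spatial_weights(matrix(runif(8, 0.2, 1), 4, 2)))
  rk <- rank_jumbles(code, w, "AB", candidates = "all")
  expect_equal(rk$candidate[1], "AB")
  expect_equal(rk$d[1], 0)
  expect_true(all(diff(rk$d) >= 0))
  # symmetric weights: the transposition ties with the word at d = 0
  sym <- spatial_weights(matrix(1, 4, 2))
  rk2 <- rank_jumbles(code, sym, "AB", candidates = "all")
  expect_true(all(rk2$d[rk2$candidate %in% c("AB", "BA")] == 0))
  # lexicographic tie-break puts AB before BA
  expect_equal(rk2$candidate[1:2], c("AB", "BA"))
  expect_error(rank_jumbles(code, w, "AB", candidates = "ABC"),
               "length")
})

test_that("edge-heavy weights make edge transpositions bigger changes than middle ones", {
  code <- make_letter_code(6, LETTERS[1:10], seed = 10)
  prof <- c(1.0, 0.6, 0.45, 0.35, 0.6, 1.0)
  w6 <- spatial_weights(matrix(rep(prof, each = 6), 6, 6))
  word <- "ABCDEF"
  edge <- "BACDEF"    # swap positions 1-2
  middle <- "ABDCEF"  # swap positions 3-4
  d_edge <- model_dissimilarity(code, w6, word, edge)
  d_middle <- model_dissimilarity(code, w6, word, middle)
  expect_gt(d_edge, d_middle)
  rk <- rank_jumbles(code, w6, word, candidates = c(edge, middle, word))
  expect_equal(rk$candidate, c(word, middle, edge))
})
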