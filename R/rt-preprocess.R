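## From raw per-trial reaction times to pairwise dissimilarities:
## outlier handling, 1/RT conversion, and split-half reliability.

# Grouping key for a trial table: unordered pair for search tables,
# string for lexical-decision tables.
trial_group_key <- function(trials) {
  if (all(c("item_a", "item_b") %in% names(trials)))
    pair_key(trials$item_a, trials$item_b)
  else if ("string" %in% names(trials))
    trials$string
  else stop_input("trial table needs item_a/item_b or string columns")
}

#' Remove reaction-time outliers per search pair
#'
#' Within each group (search pair, or string for lexical tables), trials
#' whose RT lies more than `k` scaled median absolute deviations from the
#' group median are removed. The scaled MAD uses the Gaussian-consistency
#' constant 1.4826 (the default of MATLAB's `isoutlier`, which this
#' mirrors). Size-one groups are retained unchanged.
#'
#' @param trials A trial table (search or lexical).
#' @param k Threshold in scaled-MAD units (default 3).
#' @return The filtered table, with attributes `removed_fraction` and
#'   `removed_rows` (row indices of `trials` that were dropped).
#' @export
filter_outliers <- function(trials, k = 3) {
  if (k < 0) stop_input("k must be >= 0")
  if (nrow(trials) == 0L) return(trials)
  key <- trial_group_key(trials)
  keep <- unlist(lapply(split(seq_len(nrow(trials)), key), function(ix) {
    if (length(ix) == 1L) return(ix)
    rt <- trials$rt_s[ix]
    med <- median(rt)
    smad <- mad(rt, constant = 1.4826)
    ix[abs(rt - med) <= k * smad]
  }), use.names = FALSE)
  keep <- sort(keep)
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_fraction") <- 1 - length(keep) / nrow(trials)
  attr(out, "removed_rows") <- setdiff(seq_len(nrow(trials)), keep)
  out
}

#' Pairwise dissimilarities from search trials
#'
#' Averages the RT of all retained correct trials of each unordered pair
#' (both target assignments pooled, all subjects pooled) and takes the
#' reciprocal: `d = 1 / mean(RT)`, in 1/seconds. The reciprocal of search
#' time behaves as a perceptual distance (it indexes the rate of evidence
#' accumulation). The reciprocal-of-mean convention is the default;
#' `statistic = "mean_reciprocal"` gives mean(1/RT) for sensitivity
#' analysis.
#'
#' @param trials A search trial table.
#' @param statistic `"reciprocal_mean"` (default) or `"mean_reciprocal"`.
#' @return A [dissimilarity_table()] with `n_trials` per pair.
#' @export
dissimilarity_from_trials <- function(trials,
                                      statistic = c("reciprocal_mean",
                                                    "mean_reciprocal")) {
  statistic <- match.arg(statistic)
  trials <- trials[trials$correct == 1, , drop = FALSE]
  if (nrow(trials) == 0L) stop_input("no correct trials left")
  key <- pair_key(trials$item_a, trials$item_b)
  agg <- split(trials$rt_s, key)
  d <- vapply(agg, function(rt) {
    if (statistic == "reciprocal_mean") 1 / mean(rt) else mean(1 / rt)
  }, numeric(1L))
  n <- vapply(agg, length, integer(1L))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  dissimilarity_table(vapply(parts, `[[`, character(1L), 1L),
                      vapply(parts, `[[`, character(1L), 2L),
                      unname(d), unname(n))
}

# Per-pair statistic for a subset of subjects.
half_statistic <- function(trials, subjects, statistic) {
  sub <- trials[trials$subject_id %in% subjects & trials$correct == 1, ,
                drop = FALSE]
  key <- pair_key(sub$item_a, sub$item_b)
  vapply(split(sub$rt_s, key), function(rt) {
    if (statistic == "mean_rt") mean(rt) else mean(1 / rt)
  }, numeric(1L))
}

#' Split-half consistency of search data
#'
#' Subjects are split into two halves; the correlation across pairs of the
#' per-half statistic (mean RT by default) measures data reliability. Both
#' `n_splits` random partitions (mean and sd of r reported) and the
#' deterministic odd/even-subject split are returned.
#'
#' @param trials A search trial table with >= 2 subjects.
#' @param n_splits Number of random splits (default 100).
#' @param seed Integer seed for the random partitions.
#' @param statistic `"mean_rt"` (default) or `"mean_reciprocal_rt"`.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return List of class `consistency_stats`: `r_sh` (mean split-half r),
#'   `r_sh_sd`, `r_odd_even`, `r_data` (Spearman-Brown corrected `r_sh`),
#'   `n_splits`, `splits` (per-split r values).
#' @export
split_half_consistency <- function(trials, n_splits = 100, seed = NULL,
                                   statistic = c("mean_rt",
                                                 "mean_reciprocal_rt"),
                                   method = c("pearson", "spearman")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  subjects <- sort(unique(trials$subject_id))
  n_sub <- length(subjects)
  if (n_sub < 2L) stop_input("split-half consistency needs >= 2 subjects")
  corr_for <- function(h1, h2) {
    s1 <- half_statistic(trials, h1, statistic)
    s2 <- half_statistic(trials, h2, statistic)
    shared <- intersect(names(s1), names(s2))
    cor(s1[shared], s2[shared], method = method)
  }
  rs <- local_seed(seed, vapply(seq_len(n_splits), function(i) {
    h1 <- sample(subjects, floor(n_sub / 2))
    corr_for(h1, setdiff(subjects, h1))
  }, numeric(1L)))
  odd <- subjects[seq_along(subjects) %% 2L == 1L]
  r_sh <- mean(rs)
  out <- list(r_sh = r_sh, r_sh_sd = sd(rs),
              r_odd_even = corr_for(odd, setdiff(subjects, odd)),
              r_data = spearman_brown(r_sh), n_splits = n_splits, splits = rs)
  class(out) <- "consistency_stats"
  out
}

#' @export
print.consistency_stats <- function(x, ...) {
  cat(sprintf("Split-half consistency: r_sh = %.3f +/- %.3f (%d splits), odd/even r = %.3f, r_data = %.3f\n",
              x$r_sh, x$r_sh_sd, x$n_splits, x$r_odd_even, x$r_data))
  invisible(x)
}

#' Spearman-Brown correction of a split-half correlation
#'
#' Reliability of the full data set predicted from the reliability of a
#' half: `r_data = 2 * r_sh / (r_sh + 1)`. This is the upper bound on how
#' well any model fitted to all the data can correlate with it.
#'
#' @param r_sh Split-half correlation, strictly greater than -1.
#' @return The corrected reliability estimate.
#' @examples
#' spearman_brown(0.9)
#' @export
spearman_brown <- function(r_sh) {
  if (any(r_sh <= -1)) stop_input("r_sh must be > -1")
  2 * r_sh / (r_sh + 1)
}
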