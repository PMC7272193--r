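## Part-sum model: string-pair dissimilarity as a weighted sum of
## single-letter dissimilarities across location pairs. Linear in its
## coefficients, hence estimable uniquely by ordinary least squares —
## unlike the letter model, which is nonlinear in its weights.

#' Build the part-sum design matrix
#'
#' For equal-length strings s and t, the predictor for location pair
#' (i, j) is the single-letter dissimilarity between `s[i]` and `t[j]`
#' (zero for identical letters). One row per string pair, one column per
#' location pair, named `c_i_j`.
#'
#' @param letter_D A [dissimilarity_table()] over single letters (or a
#'   symmetric letter-distance matrix).
#' @param string_pairs Data frame with columns `item_a`, `item_b` of
#'   equal-length strings.
#' @return Numeric matrix, pairs x location-pairs, with attribute
#'   `locations` (data frame of i, j per column).
#' @export
build_design <- function(letter_D, string_pairs) {
  m <- if (is.matrix(letter_D)) letter_D else
    dissim_matrix(letter_D, require_complete = FALSE)
  a <- string_pairs$item_a
  b <- string_pairs$item_b
  L <- nchar(a[1L])
  if (any(nchar(c(a, b)) != L))
    stop_input("all strings must share one length")
  lookup <- function(x, y) {
    same <- x == y
    ix <- match(x, rownames(m))
    iy <- match(y, colnames(m))
    if (anyNA(ix) || anyNA(iy))
      stop_input("letters missing from letter_D: %s",
                 paste(unique(c(x[is.na(ix)], y[is.na(iy)])), collapse = ", "))
    out <- m[cbind(ix, iy)]
    out[same] <- 0
    if (anyNA(out))
      stop_input("letter pair(s) missing from letter_D: %s",
                 paste(unique(paste0(x, "-", y)[is.na(out)]), collapse = ", "))
    out
  }
  ca <- do.call(rbind, strsplit(a, ""))
  cb <- do.call(rbind, strsplit(b, ""))
  locs <- expand.grid(i = seq_len(L), j = seq_len(L))
  X <- vapply(seq_len(nrow(locs)),
              function(r) lookup(ca[, locs$i[r]], cb[, locs$j[r]]),
              numeric(length(a)))
  if (!is.matrix(X)) X <- matrix(X, nrow = length(a))
  colnames(X) <- paste0("c_", locs$i, "_", locs$j)
  attr(X, "locations") <- locs
  X
}

#' Fit the part-sum model by ordinary least squares
#'
#' @param design Output of [build_design()].
#' @param observed_d Numeric vector of observed string-pair
#'   dissimilarities, one per design row.
#' @param intercept Include an intercept (default TRUE).
#' @return A list of class `part_sum_model`: `coeffs` (named, location
#'   pairs), `intercept`, `r`, `predicted`, `residuals`, `n_params`, plus
#'   the design and observations for refitting reduced variants.
#' @export
fit_part_sum <- function(design, observed_d, intercept = TRUE) {
  if (nrow(design) != length(observed_d))
    stop_input("design rows (%d) and observations (%d) differ",
               nrow(design), length(observed_d))
  if (any(!is.finite(observed_d))) stop_input("observations must be finite")
  X <- if (intercept) cbind(`(Intercept)` = 1, design) else design
  if (nrow(X) < ncol(X))
    stop_input("fewer pairs (%d) than free parameters (%d); supply more pairs or fit a reduced model",
               nrow(X), ncol(X))
  fit <- lm.fit(X, observed_d)
  if (fit$rank < ncol(X)) {
    null_cols <- colnames(X)[is.na(fit$coefficients)]
    stop_input("rank-deficient part-sum design; aliased columns: %s",
               paste(null_cols, collapse = ", "))
  }
  pred <- X %*% fit$coefficients
  cf <- fit$coefficients
  out <- list(
    coeffs = cf[setdiff(names(cf), "(Intercept)")],
    intercept = if (intercept) cf[["(Intercept)"]] else 0,
    r = if (sd(pred) > 0 && sd(observed_d) > 0)
      cor(as.numeric(pred), observed_d) else NA_real_,
    predicted = as.numeric(pred),
    residuals = observed_d - as.numeric(pred),
    n_params = ncol(X),
    reduced = FALSE,
    design = design, observed = observed_d,
    has_intercept = intercept,
    locations = attr(design, "locations"))
  class(out) <- "part_sum_model"
  out
}

#' @export
print.part_sum_model <- function(x, ...) {
  cat(sprintf("Part-sum model (%s): %d parameter(s), r = %.3f over %d pairs\n",
              if (x$reduced) "reduced" else "full", x$n_params, x$r,
              length(x$observed)))
  invisible(x)
}

#' Reduce a part-sum model by tying coefficients
#'
#' Ties location-pair coefficients into classes and refits by least
#' squares on the pooled design. The default `"separation"` rule ties by
#' the absolute location offset |i - j| (for bigrams: corresponding
#' locations |i-j| = 0 vs cross locations |i-j| = 1, i.e. two classes).
#' Any alternative tying can be supplied as a function mapping the
#' (i, j) location table to class labels. Being a constrained version of
#' the full model, the reduced in-sample fit can never exceed the full
#' fit.
#'
#' @param model A fitted [fit_part_sum()] model.
#' @param tying `"separation"` or a function `(locations) -> labels`.
#' @return A `part_sum_model` with `reduced = TRUE`, tied-class `coeffs`
#'   named by class, and a `classes` field mapping columns to classes.
#' @export
reduce_model <- function(model, tying = "separation") {
  locs <- model$locations
  labels <- if (is.function(tying)) tying(locs) else
    switch(tying,
           separation = paste0("sep", abs(locs$i - locs$j)),
           stop_input("unknown tying rule '%s'", tying))
  labels <- as.character(labels)
  if (length(unique(labels)) == 0L) stop_input("tying yields zero classes")
  classes <- sort(unique(labels))
  Xt <- vapply(classes,
               function(cl) rowSums(model$design[, labels == cl, drop = FALSE]),
               numeric(nrow(model$design)))
  if (!is.matrix(Xt)) Xt <- matrix(Xt, nrow = nrow(model$design))
  colnames(Xt) <- classes
  out <- fit_part_sum(Xt, model$observed, intercept = model$has_intercept)
  out$reduced <- TRUE
  out$classes <- setNames(labels, colnames(model$design))
  out$locations <- locs
  out
}
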