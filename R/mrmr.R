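#' Relevance of a feature for a continuous target
#'
#' Absolute Pearson correlation between the feature and the target. A
#' constant feature has undefined correlation and is assigned relevance 0
#' with a warning.
#'
#' @param feature,target Numeric vectors of equal length (>= 3 subjects).
#' @return Non-negative real in \[0, 1\].
#' @export
mrmr_relevance <- function(feature, target) {
  stopifnot(length(feature) == length(target), length(feature) >= 3L)
  if (stats::sd(feature) < 1e-12 || stats::sd(target) < 1e-12) {
    warning("constant feature or target: relevance set to 0", call. = FALSE)
    return(0)
  }
  abs(stats::cor(feature, target))
}

#' Redundancy of a feature against an already-selected set
#'
#' Mean absolute Pearson correlation between the feature and each selected
#' feature; 0 for an empty selected set.
#'
#' @param feature Numeric vector.
#' @param selected Numeric matrix with the selected features as columns
#'   (or NULL / zero columns for the empty set).
#' @return Non-negative real.
#' @export
mrmr_redundancy <- function(feature, selected) {
  if (is.null(selected)) return(0)
  selected <- as.matrix(selected)
  if (ncol(selected) == 0L) return(0)
  if (stats::sd(feature) < 1e-12) {
    warning("constant feature: redundancy set to 0", call. = FALSE)
    return(0)
  }
  r <- vapply(seq_len(ncol(selected)), function(j) {
    s <- selected[, j]
    if (stats::sd(s) < 1e-12) 0 else abs(stats::cor(feature, s))
  }, numeric(1))
  mean(r)
}

#' Greedy MRMR feature ranking for a continuous target
#'
#' Step 1 selects the feature with maximal relevance (absolute Pearson
#' correlation with the target); step t selects the candidate maximizing
#' the MRMR criterion against the already-selected set — relevance minus
#' mean absolute correlation (difference scheme, default) or their
#' quotient. The greedy pass ranks all `p` features; `k` marks the selected
#' prefix used downstream (default 15). Ties are broken toward the lower
#' feature index.
#'
#' @param features Numeric matrix, subjects x p.
#' @param target Numeric vector of length `nrow(features)`.
#' @param k Selection size (<= p).
#' @param scheme `"difference"` (default) or `"quotient"`.
#' @return Object of class `mrmr_ranking`: list with `order` (a permutation
#'   of `1:p`, greedy order), `scores` (criterion value at selection time),
#'   `relevance` (per-feature), `k`, `scheme`, `selected` (= `order[1:k]`).
#' @export
mrmr_rank <- function(features, target, k = 15L,
                      scheme = c("difference", "quotient")) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  p <- ncol(features)
  n <- nrow(features)
  stopifnot(length(target) == n, n >= 3L)
  if (k > p) stopf("k = %d exceeds the number of features (%d)", k, p)

  sds <- apply(features, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant feature(s): relevance/redundancy set to 0",
                    sum(const)), call. = FALSE)
  }
  rel <- numeric(p)
  ok <- !const & stats::sd(target) > 1e-12
  if (any(ok)) rel[ok] <- abs(suppressWarnings(
    stats::cor(features[, ok, drop = FALSE], target)))[, 1]

  order_out <- integer(p)
  scores <- numeric(p)
  remaining <- rep(TRUE, p)
  red_sum <- numeric(p)  # running sum of |r| against selected features

  for (t in seq_len(p)) {
    cand <- which(remaining)
    crit <- if (t == 1L) {
      rel[cand]
    } else {
      red_mean <- red_sum[cand] / (t - 1)
      if (scheme == "difference") rel[cand] - red_mean
      else rel[cand] / pmax(red_mean, .Machine$double.eps)
    }
    pick <- cand[which.max(crit)]  # which.max -> first max: lowest index wins
    order_out[t] <- pick
    scores[t] <- max(crit)
    remaining[pick] <- FALSE
    if (t < p) {
      r_new <- numeric(p)
      if (!const[pick]) {
        idx <- which(remaining & !const)
        if (length(idx)) r_new[idx] <- abs(suppressWarnings(
          stats::cor(features[, idx, drop = FALSE], features[, pick])))[, 1]
      }
      red_sum <- red_sum + r_new
    }
  }
  structure(list(order = order_out, scores = scores, relevance = rel,
                 k = as.integer(k), scheme = scheme,
                 selected = order_out[seq_len(k)]),
            class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat(sprintf("mrmr_ranking (%s scheme): top %d of %d features: %s\n",
              x$scheme, x$k, length(x$order),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Cumulative variance explained by the top-k principal components
#'
#' Diagnostic companion to the fixed top-15 MRMR cap: the fraction of total
#' feature variance captured by the first `k` principal components of the
#' (centered) feature matrix. Never gates selection.
#'
#' @param features Numeric matrix, subjects x p.
#' @param k Number of components.
#' @return Fraction in \[0, 1\].
#' @export
variance_explained_check <- function(features, k) {
  features <- as.matrix(features)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  k <- min(k, length(v))
  sum(v[seq_len(k)]) / sum(v)
}
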