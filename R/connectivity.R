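#' Canonical pair labels for the FC feature vector
#'
#' Row-major upper triangle (including the diagonal) of the network grid in
#' the fixed parcellation order: (1,1), (1,2), ..., (1,n), (2,2), ... For 15
#' networks this yields 15 within-network and 105 between-network slots, 120
#' features in all. Labels are `"AxB"`, e.g. `"SMDxSMD"`, `"SMDxSMI"`.
#'
#' @param networks Character vector of network names in canonical order.
#' @return Data frame with columns `i`, `j` (network indices, i <= j) and
#'   `label`.
#' @export
fc_pair_labels <- local({
  cache <- new.env(parent = emptyenv())
  function(networks = rsn_networks()) {
    key <- paste(networks, collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n <- length(networks)
    i <- rep(seq_len(n), times = n - seq_len(n) + 1L)
    j <- unlist(lapply(seq_len(n), function(a) a:n))
    out <- data.frame(i = i, j = j,
                      label = paste0(networks[i], "x", networks[j]),
                      stringsAsFactors = FALSE)
    cache[[key]] <- out
    out
  }
})

#' Impute non-finite time-series values with the ROI-wise mean
#'
#' Missing or non-finite entries of a voxels x timepoints block are replaced
#' by the grand mean of all finite entries of the same ROI block. Finite
#' entries are untouched; the operation is idempotent.
#'
#' @param block Numeric matrix, voxels x timepoints.
#' @param roi Label used in error messages.
#' @return The imputed block.
#' @export
impute_nonfinite <- function(block, roi = "ROI") {
  stopifnot(is.matrix(block))
  bad <- !is.finite(block)
  if (!any(bad)) return(block)
  fin <- block[!bad]
  if (length(fin) == 0L) stopf("all time-series values non-finite in %s", roi)
  block[bad] <- mean(fin)
  block
}

# Drop zero-variance voxel rows (Pearson r undefined) with a warning.
drop_constant_voxels <- function(block, roi = "ROI") {
  ctr <- block - rowMeans(block)
  nrm <- sqrt(rowSums(ctr^2))
  keep <- nrm > 1e-12
  if (!all(keep)) {
    warning(sprintf("%s: %d zero-variance voxel series excluded from similarity averages",
                    roi, sum(!keep)), call. = FALSE)
  }
  block[keep, , drop = FALSE]
}

#' Within-network similarity of a voxel block
#'
#' Mean of the strictly lower triangle of the voxel-by-voxel Pearson
#' correlation matrix of all voxels in the network (the self-correlation
#' diagonal is excluded). Zero-variance voxel series are excluded from the
#' average with a warning.
#'
#' @param block Numeric matrix, voxels x timepoints (finite values).
#' @param roi Label used in messages.
#' @return A real in \[-1, 1\].
#' @export
within_network_similarity <- function(block, roi = "ROI") {
  stopifnot(is.matrix(block), ncol(block) >= 2L)
  if (nrow(block) < 2L) stopf("%s: within-network similarity needs >= 2 voxels", roi)
  block <- drop_constant_voxels(block, roi)
  if (nrow(block) < 2L) stopf("%s: fewer than 2 non-constant voxels", roi)
  cc <- stats::cor(t(block))
  mean(cc[lower.tri(cc)])
}

#' Between-network similarity of two voxel blocks
#'
#' Mean over all voxel pairs (one from each network) of the pairwise Pearson
#' correlation computed over time. Symmetric in its arguments.
#'
#' @param block_a,block_b Numeric matrices, voxels x timepoints, same
#'   timepoint count.
#' @param roi_a,roi_b Labels used in messages.
#' @return A real in \[-1, 1\].
#' @export
between_network_similarity <- function(block_a, block_b,
                                       roi_a = "A", roi_b = "B") {
  stopifnot(is.matrix(block_a), is.matrix(block_b),
            ncol(block_a) == ncol(block_b), ncol(block_a) >= 2L)
  block_a <- drop_constant_voxels(block_a, roi_a)
  block_b <- drop_constant_voxels(block_b, roi_b)
  if (nrow(block_a) < 1L || nrow(block_b) < 1L) {
    stopf("between-network similarity: empty block after removing constant voxels")
  }
  cc <- stats::cor(t(block_a), t(block_b))
  mean(cc)
}

#' Construct a subject's time-series container
#'
#' @param blocks Named list of voxels x timepoints matrices, one per network,
#'   in canonical network order.
#' @param subject_id Subject label.
#' @return Object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(blocks, subject_id = "subject") {
  stopifnot(is.list(blocks), !is.null(names(blocks)),
            all(vapply(blocks, is.matrix, logical(1))))
  nt <- vapply(blocks, ncol, integer(1))
  if (length(unique(nt)) != 1L) stopf("all networks must share the timepoint count")
  if (nt[1] < 2L) stopf("need >= 2 timepoints")
  structure(list(blocks = blocks, subject_id = subject_id),
            class = "subject_timeseries")
}

# Standardize voxel rows to zero mean / unit L2 norm over time; rows with
# (near) zero variance are dropped. Returns list(S, n) or NULL if empty.
standardize_rows <- function(block) {
  ctr <- block - rowMeans(block)
  nrm <- sqrt(rowSums(ctr^2))
  keep <- nrm > 1e-12
  S <- ctr[keep, , drop = FALSE] / nrm[keep]
  list(S = S, n = nrow(S), dropped = sum(!keep))
}

# Fast path for the full feature vector. With unit-norm centered voxel rows
# s_i, r_ij = s_i . s_j, so sums of pairwise correlations reduce to column
# sums u = colSums(S):  sum_ij r_ij = sum_t u_t^2 (within, diag = n), and
# sum_{i in A, j in B} r_ij = u_A . u_B (between). O(voxels x T) per subject.
fc_features_from_blocks <- function(blocks, impute = TRUE) {
  nets <- names(blocks)
  n_net <- length(blocks)
  us <- vector("list", n_net)
  ns <- integer(n_net)
  n_dropped <- 0L
  for (g in seq_len(n_net)) {
    b <- blocks[[g]]
    if (impute) b <- impute_nonfinite(b, roi = nets[g])
    st <- standardize_rows(b)
    n_dropped <- n_dropped + st$dropped
    if (st$n < 2L) stopf("%s: fewer than 2 usable voxels", nets[g])
    us[[g]] <- colSums(st$S)
    ns[g] <- st$n
  }
  if (n_dropped > 0L) {
    warning(sprintf("%d zero-variance voxel series excluded from similarity averages",
                    n_dropped), call. = FALSE)
  }
  pl <- fc_pair_labels(nets)
  U <- do.call(rbind, us)          # n_net x T matrix of column sums
  G <- tcrossprod(U)               # G[i,j] = sum of all cross correlations
  num <- G[cbind(pl$i, pl$j)]
  within <- pl$i == pl$j
  vals <- numeric(nrow(pl))
  ni <- ns[pl$i]; nj <- ns[pl$j]
  vals[within] <- (num[within] - ni[within]) / (ni[within] * (ni[within] - 1))
  vals[!within] <- num[!within] / (ni[!within] * nj[!within])
  names(vals) <- pl$label
  vals
}

#' Compute the FC feature vector for one subject
#'
#' Applies the ROI-mean imputation rule, then fills the canonical feature
#' vector: diagonal slots carry within-network similarity, off-diagonal
#' slots between-network similarity, ordered row-major over the upper
#' triangle of the network grid. For 15 networks the vector has
#' 15 + 105 = 120 entries, all in \[-1, 1\].
#'
#' @param subject A [subject_timeseries()] object.
#' @return Named numeric vector of length n(n+1)/2 with pair labels.
#' @export
fc_feature_vector <- function(subject) {
  stopifnot(inherits(subject, "subject_timeseries"))
  fc_features_from_blocks(subject$blocks, impute = TRUE)
}
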