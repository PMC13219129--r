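#' Cohort-level tumor frequency map
#'
#' Voxelwise mean of the binary tumor segmentation masks.
#'
#' @param masks List of logical/0-1 voxel vectors on a common grid.
#' @return Numeric voxel vector with values in \[0, 1\].
#' @export
tumor_frequency_map <- function(masks) {
  stopifnot(length(masks) >= 1L)
  M <- vapply(masks, as.numeric, numeric(length(masks[[1]])))
  rowMeans(M)
}

#' Voxelwise association between tumor presence and PFS
#'
#' Per voxel, the Pearson correlation across subjects between binary tumor
#' presence and PFS (the point-biserial correlation). Voxels touched by
#' fewer than 2 tumor or fewer than 2 tumor-free subjects have no defined
#' contrast and are set to `NA`.
#'
#' @param masks List of logical voxel vectors, one per subject.
#' @param pfs_months PFS per subject.
#' @return Numeric voxel vector (correlations, `NA` where undefined).
#' @export
voxelwise_pfs_association <- function(masks, pfs_months) {
  stopifnot(length(masks) == length(pfs_months), length(masks) >= 4L)
  P <- vapply(masks, as.numeric, numeric(length(masks[[1]])))  # voxels x subjects
  n <- length(pfs_months)
  hits <- rowSums(P)
  ok <- hits >= 2 & (n - hits) >= 2
  out <- rep(NA_real_, nrow(P))
  if (any(ok)) {
    y <- pfs_months - mean(pfs_months)
    sy <- sqrt(sum(y^2))
    Pc <- P[ok, , drop = FALSE] - hits[ok] / n
    num <- as.numeric(Pc %*% y)
    den <- sqrt(rowSums(Pc^2)) * sy
    out[ok] <- num / den
  }
  out
}

#' Average a voxel map per network
#'
#' Parcellation mode: the mean of the map over each network's voxels.
#' Probability mode: the probability-weighted mean over the whole grid
#' using each network's probability map. `NA` (sentinel) voxels are
#' excluded.
#'
#' @param map Numeric voxel vector.
#' @param parcellation An `rsn_parcellation`, or NULL when
#'   `probability_maps` is given.
#' @param probability_maps Named list of probability voxel vectors (one per
#'   network), for probability-weighted averaging.
#' @return Named numeric vector, one value per network.
#' @export
average_map_per_network <- function(map, parcellation = NULL,
                                    probability_maps = NULL) {
  if (!is.null(parcellation)) {
    validate_parcellation(parcellation)
    vapply(parcellation$voxel_ids,
           function(ids) mean(map[ids], na.rm = TRUE), numeric(1))
  } else if (!is.null(probability_maps)) {
    vapply(probability_maps, function(w) {
      ok <- !is.na(map)
      sum(w[ok] * map[ok]) / sum(w[ok])
    }, numeric(1))
  } else {
    stopf("provide a parcellation or probability maps")
  }
}

#' Cliff's delta effect size
#'
#' `(#\{a > b\} - #\{a < b\}) / (|A| |B|)` over all cross pairs; ties
#' contribute 0. Computed by a rank-based O((m+n) log(m+n)) routine that
#' agrees exactly with exhaustive pair enumeration.
#'
#' @param a,b Numeric samples.
#' @return Real in \[-1, 1\].
#' @export
cliffs_delta <- function(a, b) {
  m <- length(a); n <- length(b)
  stopifnot(m >= 1L, n >= 1L)
  r <- rank(c(a, b))                       # midranks handle ties
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # #{a>b} + 0.5 #{a==b}
  2 * u / (m * n) - 1
}

cliffs_magnitude <- function(d) {
  ad <- abs(d)
  ifelse(ad >= 0.47, "large", ifelse(ad >= 0.33, "moderate", "negligible/small"))
}

#' Per-network Cliff's delta between control and patient probability maps
#'
#' For each network, Cliff's delta between the control map's and the
#' patient map's voxel values over that network's own support voxels.
#' Positive delta means higher control probabilities (reduced network
#' expression in patients). Magnitudes: |d| < 0.33 negligible/small,
#' 0.33-0.47 moderate, >= 0.47 large.
#'
#' @param control,patient Named lists of probability voxel vectors, one
#'   per network.
#' @param parcellation An `rsn_parcellation` giving each network's support.
#' @return Data frame: `network`, `delta`, `magnitude`.
#' @export
network_effect_sizes <- function(control, patient, parcellation) {
  validate_parcellation(parcellation)
  nets <- parcellation$network_names
  stopifnot(all(nets %in% names(control)), all(nets %in% names(patient)))
  delta <- vapply(nets, function(g) {
    ids <- parcellation$voxel_ids[[g]]
    cliffs_delta(control[[g]][ids], patient[[g]][ids])
  }, numeric(1))
  data.frame(network = nets, delta = unname(delta),
             magnitude = cliffs_magnitude(unname(delta)),
             stringsAsFactors = FALSE)
}

#' Average per-pair feature weights onto networks
#'
#' For each network g, the mean of the 15 pair weights whose label involves
#' g: its within-network pair plus the 14 between-network pairs.
#'
#' @param feature_weights Numeric vector of length n(n+1)/2, in canonical
#'   pair order (named or not).
#' @param networks Network names in canonical order.
#' @return Named numeric vector, one average per network.
#' @export
average_network_feature_weights <- function(feature_weights,
                                            networks = rsn_networks()) {
  pl <- fc_pair_labels(networks)
  stopifnot(length(feature_weights) == nrow(pl))
  vapply(seq_along(networks), function(g) {
    mean(feature_weights[pl$i == g | pl$j == g])
  }, numeric(1)) -> out
  names(out) <- networks
  out
}

#' Project network weights to a voxel map
#'
#' Per voxel, the dot product of the network weight vector with the
#' networks' probability maps: `sum_g w_g * P_g(voxel)`. Linear in the
#' weights.
#'
#' @param network_weights Numeric vector, one weight per network.
#' @param probability_maps Named list of probability voxel vectors in the
#'   same network order.
#' @return Numeric voxel vector.
#' @export
project_weights_to_voxels <- function(network_weights, probability_maps) {
  stopifnot(length(network_weights) == length(probability_maps))
  out <- numeric(length(probability_maps[[1]]))
  for (g in seq_along(network_weights)) {
    out <- out + network_weights[g] * probability_maps[[g]]
  }
  out
}
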