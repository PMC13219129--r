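# Shared fixtures: everything is built in code at test time.

# Small 15-network parcellation for fast full-pipeline tests
tiny_parcellation <- function(voxels = 6L, grid = c(10L, 10L, 10L), seed = 11L) {
  make_parcellation(15L, voxels, grid, seed = seed)
}

# A fast full-size-feature cohort: 15 networks so the FC vector has 120
# entries, but few voxels/timepoints.
tiny_cohort <- function(n_subjects = 10L, seed = 21L, n_timepoints = 40L) {
  simulate_cohort(n_subjects = n_subjects, n_timepoints = n_timepoints,
                  voxels_per_network = 6L, grid_shape = c(10L, 10L, 10L),
                  seed = seed)
}

# Subject with named blocks built directly from matrices
toy_subject <- function(blocks, id = "toy") subject_timeseries(blocks, id)

# Exhaustive greedy MRMR oracle: re-evaluates the criterion for every
# candidate at every step with direct correlation calls.
greedy_mrmr_oracle <- function(X, y, scheme = "difference") {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) {
    if (stats::sd(X[, j]) < 1e-12) 0 else abs(stats::cor(X[, j], y))
  }, numeric(1))
  sel <- integer(0)
  rem <- seq_len(p)
  for (t in seq_len(p)) {
    crit <- vapply(rem, function(j) {
      red <- if (length(sel) == 0L) 0 else {
        mean(vapply(sel, function(s) abs(stats::cor(X[, j], X[, s])),
                    numeric(1)))
      }
      if (scheme == "difference") rel[j] - red
      else rel[j] / max(red, .Machine$double.eps)
    }, numeric(1))
    pick <- rem[which.max(crit)]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  sel
}

# Exhaustive O(mn) Cliff's delta enumeration oracle
cliffs_delta_oracle <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) {
    gt <- gt + sum(x > b)
    lt <- lt + sum(x < b)
  }
  (gt - lt) / (length(a) * length(b))
}
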