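#' Covariance specification for synthetic voxel time series
#'
#' A latent-signal model: each network g has one latent signal; its voxel
#' series are `sqrt(rho_within_g) * latent_g + sqrt(1 - rho_within_g) *
#' noise_sd * eps`. Latent signals across networks are drawn with
#' correlation matrix `rho_between`. With the default `noise_sd = 1` the
#' expected within-network voxel-pair correlation is exactly `rho_within`
#' and the expected between-network voxel-pair correlation is
#' `sqrt(rho_within_i * rho_within_j) * rho_between[i, j]`, which makes the
#' simulated FC analytically checkable.
#'
#' @param rho_within Within-network correlation(s) in \[0, 1\]; scalar or one
#'   per network.
#' @param rho_between Symmetric positive semi-definite correlation matrix
#'   (unit diagonal) of the latent network signals.
#' @param noise_sd SD of the independent voxel noise (default 1).
#' @param n_timepoints Number of timepoints T.
#' @return Object of class `covariance_spec`.
#' @export
covariance_spec <- function(rho_within, rho_between, noise_sd = 1,
                            n_timepoints = 160L) {
  rho_between <- as.matrix(rho_between)
  if (!isSymmetric(unname(rho_between), tol = 1e-8)) {
    stopf("rho_between must be symmetric")
  }
  if (max(abs(diag(rho_between) - 1)) > 1e-8) {
    stopf("rho_between must have unit diagonal")
  }
  ev <- eigen(rho_between, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("rho_between is not positive semi-definite")
  if (any(rho_within < 0) || any(rho_within >= 1 + 1e-12)) {
    stopf("rho_within must lie in [0, 1]")
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (n_timepoints < 2L) stopf("need >= 2 timepoints")
  structure(list(rho_within = rho_within, rho_between = rho_between,
                 noise_sd = noise_sd, n_timepoints = as.integer(n_timepoints)),
            class = "covariance_spec")
}

# PSD square root via eigendecomposition (tolerates semi-definite input)
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate one subject's voxelwise time series
#'
#' Draws latent network signals with correlation `spec$rho_between`, then
#' builds each network's voxel series from the shared latent plus
#' independent voxel noise (see [covariance_spec()]).
#'
#' @param parcellation An `rsn_parcellation`.
#' @param spec A [covariance_spec()].
#' @param seed Integer seed.
#' @param subject_id Subject label.
#' @return A [subject_timeseries()] object.
#' @export
simulate_timeseries <- function(parcellation, spec, seed = 1L,
                                subject_id = "sim") {
  validate_parcellation(parcellation)
  stopifnot(inherits(spec, "covariance_spec"))
  n_net <- length(parcellation$network_names)
  stopifnot(nrow(spec$rho_between) == n_net)
  rw <- rep(spec$rho_within, length.out = n_net)
  Tn <- spec$n_timepoints
  with_seed(seed, {
    L <- psd_sqrt(spec$rho_between) %*%
      matrix(stats::rnorm(n_net * Tn), n_net, Tn)
    blocks <- vector("list", n_net)
    for (g in seq_len(n_net)) {
      v <- length(parcellation$voxel_ids[[g]])
      eps <- matrix(stats::rnorm(v * Tn, sd = spec$noise_sd), v, Tn)
      blocks[[g]] <- sqrt(rw[g]) * matrix(L[g, ], v, Tn, byrow = TRUE) +
        sqrt(1 - rw[g]) * eps
    }
    names(blocks) <- parcellation$network_names
    subject_timeseries(blocks, subject_id)
  })
}

#' Outcome specification: couple PFS to chosen FC features
#'
#' PFS is generated from a weighted sum of the active FC features passed
#' through a link, plus Gaussian noise, floored at a small positive value.
#' The `"sigmoid"` link is `base + span * plogis(gain * z)` where `z` is the
#' cohort-standardized weighted sum — a smooth saturating (hence nonlinear)
#' dose-response. With `noise_sd = "auto"` the noise SD is set to
#' `sd(signal) / 3`, i.e. a 9:1 signal-to-noise variance ratio (generative
#' R-squared of 0.9).
#'
#' @param active_features Indices into the 120-element FC vector. The
#'   default is the five thalamus-involving pairs SMIxTHA, DMNxTHA,
#'   PMNxTHA, VANxTHA and MTLxTHA, which ride the generator's
#'   subject-level thalamocortical hub modulation and therefore form a
#'   dominant, consistently selectable predictor axis.
#' @param weights Signed weights, one per active feature.
#' @param link `"sigmoid"` (saturating, default) or `"identity"`.
#' @param gain Steepness of the sigmoid link on the standardized score.
#' @param base,span Months: link output ranges over (base, base + span).
#' @param noise_sd Months, or `"auto"` for the 9:1 variance ratio.
#' @param floor Minimum PFS in months (default 0.5).
#' @param event_rate Fraction of subjects with an observed PFS event.
#' @param os_gap_mean Mean of the exponential OS - PFS gap (months).
#' @param os_event_rate Fraction with an observed OS event.
#' @return Object of class `outcome_spec`.
#' @export
outcome_spec <- function(active_features = NULL,
                         weights = c(1.0, 0.9, 0.85, 0.8, 0.7),
                         link = c("sigmoid", "identity"),
                         gain = 4, base = 2, span = 20,
                         noise_sd = "auto", floor = 0.5,
                         event_rate = 1, os_gap_mean = 6,
                         os_event_rate = 0.8) {
  link <- match.arg(link)
  if (is.null(active_features)) {
    lab <- fc_pair_labels(rsn_networks())$label
    active_features <- match(c("SMIxTHA", "DMNxTHA", "PMNxTHA",
                               "VANxTHA", "MTLxTHA"), lab)
  }
  active_features <- as.integer(active_features)
  if (length(active_features) == 0L) stopf("active feature set must be non-empty")
  if (any(active_features < 1L)) stopf("active feature indices must be >= 1")
  if (length(weights) != length(active_features)) {
    stopf("weights and active_features must have equal length")
  }
  if (floor <= 0) stopf("PFS floor must be positive")
  if (event_rate <= 0 || event_rate > 1) stopf("event_rate must be in (0, 1]")
  structure(list(active_features = active_features, weights = weights,
                 link = link, gain = gain, base = base, span = span,
                 noise_sd = noise_sd, floor = floor, event_rate = event_rate,
                 os_gap_mean = os_gap_mean, os_event_rate = os_event_rate),
            class = "outcome_spec")
}

# Noise-free link value per subject from an FC matrix (n x p)
outcome_signal <- function(fc, spec) {
  stopifnot(max(spec$active_features) <= ncol(fc))
  s <- as.numeric(fc[, spec$active_features, drop = FALSE] %*% spec$weights)
  if (spec$link == "identity") return(spec$base + s)
  sdv <- stats::sd(s)
  z <- if (sdv > 0) (s - mean(s)) / sdv else s * 0
  spec$base + spec$span * stats::plogis(spec$gain * z)
}

#' Plant a PFS/OS outcome on a cohort's FC features
#'
#' @param fc Numeric matrix, subjects x features (the 120 FC features).
#' @param spec An [outcome_spec()].
#' @param seed Integer seed.
#' @return List with `pfs_months`, `os_months`, `pfs_event`, `os_event`,
#'   `signal` (the noise-free link values) and `noise_sd` (the value used).
#' @export
plant_outcome <- function(fc, spec, seed = 1L) {
  stopifnot(is.matrix(fc), inherits(spec, "outcome_spec"))
  signal <- outcome_signal(fc, spec)
  n <- nrow(fc)
  noise_sd <- if (identical(spec$noise_sd, "auto")) stats::sd(signal) / 3
              else spec$noise_sd
  with_seed(seed, {
    pfs <- pmax(spec$floor, signal + stats::rnorm(n, sd = noise_sd))
    os <- pfs + stats::rexp(n, rate = 1 / spec$os_gap_mean)
    pfs_event <- as.integer(stats::runif(n) < spec$event_rate)
    os_event <- as.integer(stats::runif(n) < spec$os_event_rate)
    list(pfs_months = pfs, os_months = os, pfs_event = pfs_event,
         os_event = os_event, signal = signal, noise_sd = noise_sd)
  })
}

# Project a symmetric matrix to the nearest unit-diagonal PSD correlation
# matrix by eigenvalue clipping + diagonal rescaling.
make_correlation_psd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  M2 <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
  d <- sqrt(diag(M2))
  M2 <- M2 / tcrossprod(d)
  diag(M2) <- 1
  M2
}

#' Draw one subject's covariance specification from the population model
#'
#' Base between-network correlation plus (1) a symmetric uniform
#' entry-level perturbation (PSD-projected; the amplitude is kept small so
#' the projection is a mild correction and per-pair variation stays
#' near-independent across subjects) and (2) a subject-level hub
#' modulation: one scalar `U(-hub_modulation, hub_modulation)` added to
#' the hub network's whole row of latent correlations, emulating global
#' thalamocortical connectivity differences across subjects. The hub term
#' makes all hub-involving FC features co-vary across subjects, giving
#' the cohort a dominant, consistently selectable predictor axis.
#'
#' @param n_networks Number of networks.
#' @param seed Integer seed.
#' @param base_between Baseline off-diagonal latent correlation.
#' @param between_jitter Half-width of the entry-level perturbation.
#' @param hub_network Index of the hub network (14 = THA), or NULL.
#' @param hub_modulation Half-width of the hub row shift.
#' @param rho_within_range Range of per-network within correlations.
#' @param n_timepoints Timepoints T.
#' @return A [covariance_spec()].
#' @export
subject_covariance_spec <- function(n_networks, seed,
                                    base_between = 0.10,
                                    between_jitter = 0.18,
                                    hub_network = 14L,
                                    hub_modulation = 0.20,
                                    rho_within_range = c(0.25, 0.60),
                                    n_timepoints = 160L) {
  with_seed(seed, {
    B <- matrix(base_between, n_networks, n_networks)
    jit <- matrix(stats::runif(n_networks^2, -between_jitter, between_jitter),
                  n_networks, n_networks)
    jit <- (jit + t(jit)) / 2
    B <- B + jit
    if (!is.null(hub_network) && hub_modulation > 0 &&
        hub_network <= n_networks) {
      u <- stats::runif(1, -hub_modulation, hub_modulation)
      B[hub_network, ] <- B[hub_network, ] + u
      B[, hub_network] <- B[, hub_network] + u
    }
    B <- pmin(pmax(B, -0.9), 0.9)
    diag(B) <- 1
    B <- make_correlation_psd(B)
    rw <- stats::runif(n_networks, rho_within_range[1], rho_within_range[2])
    covariance_spec(rho_within = rw, rho_between = B,
                    n_timepoints = n_timepoints)
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates a parcellation, per-subject voxel time series with
#' subject-varying network covariance, the 120 FC features, and planted
#' PFS/OS outcomes coupled to the active features. These defaults define
#' the study conditions for all downstream analyses: 45 subjects, 15
#' networks of 40 voxels on a 20x20x20 grid, 160 timepoints, 5 active
#' features under a saturating link at a 9:1 signal-to-noise ratio.
#'
#' @param n_subjects Cohort size.
#' @param parcellation Optional pre-built `rsn_parcellation`.
#' @param n_timepoints Timepoints per subject.
#' @param voxels_per_network,grid_shape Parcellation geometry (used when
#'   `parcellation` is NULL).
#' @param outcome An [outcome_spec()].
#' @param seed Integer seed.
#' @return Object of class `fc_cohort`: list with `subjects` (list of
#'   [subject_timeseries()]), `fc` (n x 120 matrix), `pfs_months`,
#'   `os_months`, `pfs_event`, `os_event`, `signal`, `parcellation`,
#'   `outcome_spec`.
#' @export
simulate_cohort <- function(n_subjects = 45L, parcellation = NULL,
                            n_timepoints = 160L, voxels_per_network = 40L,
                            grid_shape = c(20L, 20L, 20L),
                            outcome = outcome_spec(), seed = 1L) {
  if (is.null(parcellation)) {
    parcellation <- make_parcellation(15L, voxels_per_network, grid_shape,
                                      seed = derive_seed(seed, 1L))
  }
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cs <- subject_covariance_spec(length(parcellation$network_names),
                                  seed = derive_seed(seed, 2L, s),
                                  n_timepoints = n_timepoints)
    subjects[[s]] <- simulate_timeseries(parcellation, cs,
                                         seed = derive_seed(seed, 3L, s),
                                         subject_id = sprintf("sub-%03d", s))
  }
  fc <- t(vapply(subjects, fc_feature_vector,
                 numeric(length(fc_pair_labels(parcellation$network_names)$label))))
  out <- plant_outcome(fc, outcome, seed = derive_seed(seed, 4L))
  structure(list(subjects = subjects, fc = fc,
                 pfs_months = out$pfs_months, os_months = out$os_months,
                 pfs_event = out$pfs_event, os_event = out$os_event,
                 signal = out$signal, parcellation = parcellation,
                 outcome_spec = outcome),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("fc_cohort: %d subjects, %d FC features, median PFS %.1f months\n",
              nrow(x$fc), ncol(x$fc), stats::median(x$pfs_months)))
  invisible(x)
}

#' Simulate control and patient RSN probability maps
#'
#' Control maps carry high probabilities on each network's own voxels and
#' low values elsewhere; patient maps are `attenuation * control + noise`,
#' clipped to \[0, 1\]. Attenuation below 1 emulates the reduced network
#' probability observed in tumor patients.
#'
#' @param parcellation An `rsn_parcellation`.
#' @param attenuation Per-network factor in (0, 1\] (recycled).
#' @param noise_sd SD of the additive patient-map noise.
#' @param seed Integer seed.
#' @return List with `control` and `patient`, each a list of numeric voxel
#'   vectors (length `prod(grid_shape)`) named by network, plus
#'   `grid_shape`.
#' @export
simulate_probability_maps <- function(parcellation, attenuation = 1,
                                      noise_sd = 0.02, seed = 1L) {
  validate_parcellation(parcellation)
  nets <- parcellation$network_names
  att <- rep(attenuation, length.out = length(nets))
  if (any(att <= 0 | att > 1)) stopf("attenuation must lie in (0, 1]")
  n_vox <- prod(parcellation$grid_shape)
  with_seed(seed, {
    control <- patient <- stats::setNames(vector("list", length(nets)), nets)
    for (g in seq_along(nets)) {
      m <- stats::runif(n_vox, 0.01, 0.10)
      own <- parcellation$voxel_ids[[g]]
      m[own] <- stats::runif(length(own), 0.75, 0.95)
      control[[g]] <- m
      p <- att[g] * m
      if (noise_sd > 0) p <- p + stats::rnorm(n_vox, sd = noise_sd)
      patient[[g]] <- pmin(1, pmax(0, p))
    }
    list(control = control, patient = patient,
         grid_shape = parcellation$grid_shape)
  })
}

#' Simulate spatially clustered tumor segmentations with PFS coupling
#'
#' Each subject's tumor is a connected voxel cluster grown from a random
#' seed. Subjects whose tumor overlaps the designated short-PFS networks
#' receive a negative PFS shift proportional to the overlap fraction.
#'
#' @param n_subjects Number of masks.
#' @param parcellation An `rsn_parcellation`.
#' @param location_pfs_coupling Months of PFS lost per unit overlap
#'   fraction with the short-PFS networks.
#' @param short_pfs_networks Networks whose involvement shortens PFS.
#' @param size_range Tumor size range in voxels.
#' @param seed Integer seed.
#' @return List with `masks` (list of logical voxel vectors), `pfs_shift`
#'   (numeric, <= 0), `overlap_fraction`.
#' @export
simulate_segmentations <- function(n_subjects, parcellation,
                                   location_pfs_coupling = 6,
                                   short_pfs_networks = c("DAN", "VIS", "FPN", "DMN"),
                                   size_range = c(30L, 80L), seed = 1L) {
  validate_parcellation(parcellation)
  n_vox <- prod(parcellation$grid_shape)
  short_ids <- unlist(parcellation$voxel_ids[
    intersect(short_pfs_networks, parcellation$network_names)],
    use.names = FALSE)
  with_seed(seed, {
    masks <- vector("list", n_subjects)
    overlap <- numeric(n_subjects)
    for (s in seq_len(n_subjects)) {
      size <- sample(size_range[1]:size_range[2], 1L)
      start <- sample.int(n_vox, 1L)
      res <- grow_region(start, size, logical(n_vox), parcellation$grid_shape)
      mask <- logical(n_vox)
      mask[res$region] <- TRUE
      masks[[s]] <- mask
      overlap[s] <- if (length(short_ids)) sum(mask[short_ids]) / size else 0
    }
    list(masks = masks, pfs_shift = -location_pfs_coupling * overlap,
         overlap_fraction = overlap)
  })
}

#' Build a synthetic lesion measurement table
#'
#' Fixture generator for the RANO progression stage: one row per lesion and
#' timepoint, carrying the two perpendicular diameters (mm), the axial
#' slice count and the enhancing flag.
#'
#' @param case_spec Data frame (or list coercible to one) with columns
#'   `lesion_id`, `timepoint`, `d1_mm`, `d2_mm`, `axial_slices`, and
#'   optionally `enhancing` (default TRUE).
#' @return Data frame of lesion measurements.
#' @export
make_lesion_records <- function(case_spec) {
  df <- as.data.frame(case_spec, stringsAsFactors = FALSE)
  needed <- c("lesion_id", "timepoint", "d1_mm", "d2_mm", "axial_slices")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) stopf("lesion table missing columns: %s",
                                  paste(missing_cols, collapse = ", "))
  if (is.null(df$enhancing)) df$enhancing <- TRUE
  if (any(df$d1_mm <= 0 | df$d2_mm <= 0)) stopf("diameters must be positive")
  if (any(df$axial_slices < 1)) stopf("axial slice count must be >= 1")
  df[, c(needed, "enhancing")]
}
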