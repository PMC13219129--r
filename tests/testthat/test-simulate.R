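test_that("covariance_spec validates its matrix", {
  ok <- diag(3)
  expect_s3_class(covariance_spec(0.5, ok), "covariance_spec")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(covariance_spec(0.5, bad), "positive semi-definite")
  asym <- ok; asym[1, 2] <- 0.3
  expect_error(covariance_spec(0.5, asym), "symmetric")
  expect_error(covariance_spec(1.2, ok), "rho_within")
})

test_that("degenerate limit: rho_within = 1 with zero noise gives identical voxel series", {
  p <- make_parcellation(3, 5, c(6, 6, 6), seed = 3)
  spec <- covariance_spec(1, diag(3), noise_sd = 0, n_timepoints = 30)
  st <- simulate_timeseries(p, spec, seed = 4)
  for (b in st$blocks) {
    expect_equal(max(abs(sweep(b, 2, b[1, ]))), 0)
  }
})

test_that("empirical similarity converges to the covariance targets at T = 4000", {
  p <- make_parcellation(3, 10, c(8, 8, 8), seed = 5)
  spec <- covariance_spec(0.8, diag(3), n_timepoints = 4000)
  st <- simulate_timeseries(p, spec, seed = 6)
  fc <- fc_feature_vector(st)
  pl <- fc_pair_labels(p$network_names)
  within <- fc[pl$i == pl$j]
  between <- fc[pl$i != pl$j]
  # oracle: analytic voxel-pair correlation rho_within; independent latents
  expect_true(all(abs(within - 0.8) < 0.05))
  expect_true(all(abs(between) < 0.05))
})

test_that("timeseries generation is deterministic per seed", {
  p <- make_parcellation(2, 4, c(5, 5, 5), seed = 1)
  spec <- covariance_spec(0.4, diag(2), n_timepoints = 20)
  expect_identical(simulate_timeseries(p, spec, seed = 9)$blocks,
                   simulate_timeseries(p, spec, seed = 9)$blocks)
})

test_that("plant_outcome: deterministic identity link is monotone in the feature", {
  fc <- matrix(0, 20, 120)
  fc[, 7] <- seq(-1, 1, length.out = 20)
  spec <- outcome_spec(active_features = 7, weights = 2, link = "identity",
                       base = 10, noise_sd = 0)
  out <- plant_outcome(fc, spec, seed = 1)
  expect_equal(out$pfs_months, pmax(0.5, 10 + 2 * fc[, 7]))
  expect_false(is.unsorted(out$pfs_months))
})

test_that("plant_outcome honors event rate, OS ordering and positivity", {
  set.seed(31)
  fc <- matrix(rnorm(40 * 120, sd = 0.1), 40, 120)
  out <- plant_outcome(fc, outcome_spec(event_rate = 1), seed = 2)
  expect_true(all(out$pfs_event == 1L))
  expect_true(all(out$pfs_months > 0))
  expect_true(all(out$os_months >= out$pfs_months))
  expect_error(outcome_spec(active_features = integer(0)), "non-empty")
})

test_that("auto noise yields a generative signal-to-noise of about 9:1", {
  set.seed(55)
  fc <- matrix(rnorm(2000 * 120, sd = 0.1), 2000, 120)
  spec <- outcome_spec()
  out <- plant_outcome(fc, spec, seed = 3)
  # oracle: least-squares fit of the true link values
  fit <- stats::lm(out$pfs_months ~ out$signal)
  expect_equal(summary(fit)$r.squared, 0.9, tolerance = 0.03)
})

test_that("probability maps: attenuation structure shows up as ordered effect sizes", {
  p <- make_parcellation(2, 8, c(6, 6, 6), seed = 8)
  # attenuation 1 with zero noise: patient identical to control
  m0 <- simulate_probability_maps(p, attenuation = 1, noise_sd = 0, seed = 1)
  expect_identical(m0$control, m0$patient)
  es0 <- network_effect_sizes(m0$control, m0$patient, p)
  expect_equal(es0$delta, c(0, 0))

  # attenuation (1.0, 0.5): deltas (0, d > 0), matching enumeration oracle
  m1 <- simulate_probability_maps(p, attenuation = c(1.0, 0.5), noise_sd = 0,
                                  seed = 2)
  es1 <- network_effect_sizes(m1$control, m1$patient, p)
  expect_equal(es1$delta[1], 0)
  expect_gt(es1$delta[2], 0)
  ids <- p$voxel_ids[[2]]
  expect_equal(es1$delta[2],
               cliffs_delta_oracle(m1$control[[2]][ids], m1$patient[[2]][ids]))
  expect_true(all(unlist(m1$patient) >= 0 & unlist(m1$patient) <= 1))
})

test_that("strong attenuation of one network produces the largest delta", {
  p <- tiny_parcellation()
  att <- rep(0.9, 15); att[4] <- 0.2
  m <- simulate_probability_maps(p, attenuation = att, seed = 3)
  es <- network_effect_sizes(m$control, m$patient, p)
  expect_equal(which.max(es$delta), 4L)
})

test_that("tumor segmentations are connected, deterministic, and PFS-coupled", {
  p <- tiny_parcellation()
  seg <- simulate_segmentations(8, p, location_pfs_coupling = 6, seed = 9)
  seg2 <- simulate_segmentations(8, p, location_pfs_coupling = 6, seed = 9)
  expect_identical(seg$masks, seg2$masks)
  # connectivity: each mask is one 6-connected component
  for (m in seg$masks) {
    vox <- which(m)
    reached <- vox[1]
    frontier <- vox[1]
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, grid_neighbors, p$grid_shape)))
      frontier <- setdiff(intersect(nb, vox), reached)
      reached <- c(reached, frontier)
    }
    expect_setequal(reached, vox)
  }
  # coupling oracle: direct overlap count with the short-PFS networks
  short_ids <- unlist(p$voxel_ids[c("DAN", "VIS", "FPN", "DMN")])
  ov <- vapply(seg$masks, function(m) sum(m[short_ids]) / sum(m), numeric(1))
  expect_equal(seg$pfs_shift, -6 * ov)
  expect_true(all(seg$pfs_shift <= 0))
})

test_that("lesion record fixtures carry the RANO-relevant fields", {
  rec <- make_lesion_records(data.frame(
    lesion_id = 1, timepoint = "baseline", d1_mm = 12, d2_mm = 15,
    axial_slices = 3))
  expect_true(rec$enhancing)
  expect_equal(sum(is_measurable(rec$d1_mm, rec$d2_mm, rec$axial_slices,
                                 rec$enhancing)), 1L)
  expect_error(make_lesion_records(data.frame(lesion_id = 1)),
               "missing columns")
  expect_error(make_lesion_records(data.frame(
    lesion_id = 1, timepoint = "b", d1_mm = -1, d2_mm = 5, axial_slices = 2)),
    "positive")
})
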