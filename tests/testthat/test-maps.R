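test_that("tumor frequency map is the voxelwise mask mean and linear", {
  m1 <- c(1, 1, 0, 0); m2 <- c(0, 1, 0, 0)
  expect_equal(tumor_frequency_map(list(m1, m1, m1)), m1)
  expect_equal(tumor_frequency_map(list(c(1, 0, 0, 0), c(0, 0, 1, 0))),
               c(0.5, 0, 0.5, 0))
  set.seed(61)
  masks <- replicate(10, runif(30) < 0.3, simplify = FALSE)
  f <- tumor_frequency_map(masks)
  expect_equal(f, Reduce(`+`, lapply(masks, as.numeric)) / 10)  # brute force
  expect_true(all(f >= 0 & f <= 1))
})

test_that("voxelwise PFS association is the point-biserial correlation", {
  # identical masks: no contrast anywhere
  same <- replicate(5, c(1, 1, 0, 0) == 1, simplify = FALSE)
  expect_true(all(is.na(voxelwise_pfs_association(same, 1:5))))

  # 2-voxel, 4-subject toy with planted association
  masks <- list(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, TRUE), c(FALSE, FALSE))
  pfs <- c(3, 5, 10, 12)
  r <- voxelwise_pfs_association(masks, pfs)
  pres1 <- c(1, 1, 0, 0); pres2 <- c(0, 1, 1, 0)
  expect_equal(r[1], stats::cor(pres1, pfs))
  expect_equal(r[2], stats::cor(pres2, pfs))
  # antisymmetry under PFS sign flip
  expect_equal(voxelwise_pfs_association(masks, -pfs), -r)
  # voxels touched by < 2 tumors are sentinel
  masks2 <- list(c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, FALSE))
  expect_true(is.na(voxelwise_pfs_association(masks2, pfs)[1]))
})

test_that("per-network averaging honors parcellation and probability modes", {
  p <- make_parcellation(3, 5, c(6, 6, 6), seed = 2)
  n_vox <- prod(p$grid_shape)
  cmap <- rep(3.5, n_vox)
  expect_equal(unname(average_map_per_network(cmap, p)), rep(3.5, 3))

  ind <- numeric(n_vox); ind[p$voxel_ids[[1]]] <- 1
  expect_equal(unname(average_map_per_network(ind, p)), c(1, 0, 0))

  set.seed(3)
  m <- rnorm(n_vox)
  m[p$voxel_ids[[2]][1]] <- NA  # sentinel excluded
  avg <- average_map_per_network(m, p)
  o <- vapply(p$voxel_ids, function(ids) mean(m[ids], na.rm = TRUE), numeric(1))
  expect_equal(avg, o)

  w <- list(A = runif(n_vox), B = runif(n_vox), C = runif(n_vox))
  avg_w <- average_map_per_network(m, probability_maps = w)
  ok <- !is.na(m)
  expect_equal(avg_w[["A"]], sum(w$A[ok] * m[ok]) / sum(w$A[ok]))
})

test_that("Cliff's delta has its closed small-sample values", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(5, 6, 7)), -1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4)), -5 / 9)
})

test_that("rank-based Cliff's delta agrees exactly with pair enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    a <- sample(0:10, sample(3:40, 1), replace = TRUE)  # plenty of ties
    b <- sample(0:10, sample(3:40, 1), replace = TRUE)
    d <- cliffs_delta(a, b)
    expect_equal(d, cliffs_delta_oracle(a, b))
    expect_equal(d, -cliffs_delta(b, a))
    expect_lte(abs(d), 1)
  }
})

test_that("effect-size magnitudes follow the 0.33 / 0.47 bands", {
  expect_equal(cliffs_magnitude(c(0.32, -0.32)), rep("negligible/small", 2))
  expect_equal(cliffs_magnitude(0.40), "moderate")
  expect_equal(cliffs_magnitude(0.33), "moderate")
  expect_equal(cliffs_magnitude(c(0.47, -0.9)), rep("large", 2))
})

test_that("network effect sizes compare maps over each network's own support", {
  p <- make_parcellation(2, 6, c(5, 5, 5), seed = 4)
  n_vox <- prod(p$grid_shape)
  set.seed(5)
  control <- list(A = runif(n_vox), B = runif(n_vox))
  names(control) <- p$network_names
  patient <- control
  es <- network_effect_sizes(control, patient, p)
  expect_equal(es$delta, c(0, 0))
  expect_equal(es$magnitude, rep("negligible/small", 2))

  patient[[2]] <- patient[[2]] * 0.3
  es2 <- network_effect_sizes(control, patient, p)
  ids <- p$voxel_ids[[2]]
  expect_equal(es2$delta[2],
               cliffs_delta_oracle(control[[2]][ids], patient[[2]][ids]))
  expect_gt(es2$delta[2], es2$delta[1])
})

test_that("feature-weight averaging counts each network's 15 pairs", {
  w <- rep(1, 120)
  expect_equal(unname(average_network_feature_weights(w)), rep(1, 15))

  w2 <- numeric(120)
  lab <- fc_pair_labels()$label
  w2[lab == "SMDxSMI"] <- 1
  avg <- average_network_feature_weights(w2)
  expect_equal(avg[["SMD"]], 1 / 15)
  expect_equal(avg[["SMI"]], 1 / 15)
  expect_equal(sum(avg), 2 / 15)

  set.seed(6)
  w3 <- rnorm(120)
  avg3 <- average_network_feature_weights(w3)
  pl <- fc_pair_labels()
  for (g in c(1, 7, 15)) {
    expect_equal(unname(avg3[g]), mean(w3[pl$i == g | pl$j == g]))
  }
})

test_that("weight projection is the per-voxel dot product and linear", {
  set.seed(7)
  maps <- lapply(1:4, function(i) runif(20))
  names(maps) <- paste0("N", 1:4)
  e1 <- c(1, 0, 0, 0)
  expect_equal(project_weights_to_voxels(e1, maps), maps[[1]])
  expect_equal(project_weights_to_voxels(rep(0, 4), maps), numeric(20))
  w <- rnorm(4)
  proj <- project_weights_to_voxels(w, maps)
  o <- vapply(1:20, function(v) sum(w * vapply(maps, `[`, numeric(1), v)),
              numeric(1))
  expect_equal(proj, o)
  # linearity in the weights
  w2 <- rnorm(4)
  expect_equal(project_weights_to_voxels(w + 2 * w2, maps),
               proj + 2 * project_weights_to_voxels(w2, maps))
})
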