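#' The 15 resting-state networks used throughout the pipeline
#'
#' Canonical network order: dorsal somatomotor (SMD), inferior somatomotor
#' (SMI), cinguloopercular (CON), auditory (AUD), default mode (DMN),
#' parietal memory (PMN), visual (VIS), frontoparietal (FPN), salience
#' (SAL), ventral attention (VAN), dorsal attention (DAN), medial temporal
#' (MTL), reward (REW), thalamus (THA), basal ganglia (BGA).
#'
#' @return Character vector of the 15 network labels, in canonical order.
#' @export
rsn_networks <- function() {
  c("SMD", "SMI", "CON", "AUD", "DMN", "PMN", "VIS", "FPN",
    "SAL", "VAN", "DAN", "MTL", "REW", "THA", "BGA")
}

# 6-connected neighbors of linear voxel index v on a 3D grid
grid_neighbors <- function(v, grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  v0 <- v - 1L
  x <- v0 %% nx
  y <- (v0 %/% nx) %% ny
  z <- v0 %/% (nx * ny)
  out <- integer(0)
  if (x > 0)      out <- c(out, v - 1L)
  if (x < nx - 1) out <- c(out, v + 1L)
  if (y > 0)      out <- c(out, v - nx)
  if (y < ny - 1) out <- c(out, v + nx)
  if (z > 0)      out <- c(out, v - nx * ny)
  if (z < nz - 1) out <- c(out, v + nx * ny)
  out
}

# Grow a connected cluster of `size` unclaimed voxels from `start`.
# Falls back to a random unclaimed voxel if the frontier empties
# (keeps regions mostly contiguous on crowded grids).
grow_region <- function(start, size, claimed, grid_shape) {
  region <- integer(0)
  frontier <- start
  while (length(region) < size) {
    frontier <- frontier[!claimed[frontier]]
    if (length(frontier) == 0L) {
      free <- which(!claimed)
      if (length(free) == 0L) stopf("grid exhausted while growing region")
      frontier <- free[sample.int(length(free), 1L)]
    }
    v <- frontier[sample.int(length(frontier), 1L)]
    frontier <- setdiff(frontier, v)
    if (claimed[v]) next
    region <- c(region, v)
    claimed[v] <- TRUE
    frontier <- c(frontier, grid_neighbors(v, grid_shape))
  }
  list(region = region, claimed = claimed)
}

#' Build a synthetic spatially clustered parcellation
#'
#' Places `n_networks` seed voxels on a 3D grid and grows disjoint,
#' spatially clustered regions of `voxels_per_network` voxels each by
#' seeded region growth. Deterministic for a fixed seed.
#'
#' @param n_networks Number of networks (15 for the full pipeline).
#' @param voxels_per_network Voxels per network region.
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param seed Integer seed.
#' @param network_names Optional labels; defaults to [rsn_networks()] when
#'   `n_networks == 15`, otherwise `N1..Nk`.
#' @return An object of class `rsn_parcellation`: list with `network_names`,
#'   `voxel_ids` (named list of linear voxel indices), `grid_shape`.
#' @export
make_parcellation <- function(n_networks, voxels_per_network, grid_shape,
                              seed = 1L, network_names = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stopf("grid_shape must be 3 positive integers")
  }
  n_vox <- prod(grid_shape)
  if (n_vox < n_networks * voxels_per_network) {
    stopf("grid too small: %d voxels for %d networks x %d voxels",
          n_vox, n_networks, voxels_per_network)
  }
  if (is.null(network_names)) {
    network_names <- if (n_networks == 15L) rsn_networks()
                     else paste0("N", seq_len(n_networks))
  }
  stopifnot(length(network_names) == n_networks)
  with_seed(seed, {
    claimed <- logical(n_vox)
    seeds <- sample.int(n_vox, n_networks)
    voxel_ids <- vector("list", n_networks)
    for (g in seq_len(n_networks)) {
      res <- grow_region(seeds[g], voxels_per_network, claimed, grid_shape)
      voxel_ids[[g]] <- sort(res$region)
      claimed <- res$claimed
    }
    names(voxel_ids) <- network_names
    structure(
      list(network_names = network_names, voxel_ids = voxel_ids,
           grid_shape = grid_shape),
      class = "rsn_parcellation"
    )
  })
}

#' @export
print.rsn_parcellation <- function(x, ...) {
  cat(sprintf("rsn_parcellation: %d networks on a %s grid, %d voxels total\n",
              length(x$network_names), paste(x$grid_shape, collapse = "x"),
              sum(lengths(x$voxel_ids))))
  invisible(x)
}

validate_parcellation <- function(parc) {
  stopifnot(inherits(parc, "rsn_parcellation"))
  ids <- unlist(parc$voxel_ids, use.names = FALSE)
  if (anyDuplicated(ids)) stopf("parcellation voxel sets are not disjoint")
  if (any(lengths(parc$voxel_ids) == 0L)) stopf("empty network in parcellation")
  invisible(parc)
}
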