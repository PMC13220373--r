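# Shared fixtures, all built in code.

# Standard small cohort: shrinking concentric lesion (nested masks).
shrinking_config <- function(seed = 42, jitter = 0) {
  cohort_config(grid_shape = c(16, 16, 16), voxel_size = 1,
                n_parcels = 12, n_networks = 3, n_streamlines = 150,
                lesion_specs = list(
                  list(center = c(8, 8, 8), radius = 5, jitter = jitter),
                  list(center = c(8, 8, 8), radius = 3.5, jitter = jitter),
                  list(center = c(8, 8, 8), radius = 2, jitter = jitter)),
                seed = seed)
}

# Hand-built two-parcel atlas: a 4x4x4 grid split by the x = 2 plane.
plane_atlas <- function(voxel_size = 1) {
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  parcellation_atlas(lab, voxel_size, network_of = c("NetA", "NetB"))
}

# Mask on an arbitrary grid from explicit voxel indices (n x 3 matrix).
mask_from_voxels <- function(dims, vox, voxel_size = 1, label = "S1") {
  g <- array(0L, dim = dims)
  if (length(vox)) g[vox] <- 1L
  lesion_mask(g, voxel_size, timepoint_label = label)
}

# Symmetric matrix from an upper-triangle edge list (i, j, value).
sym_matrix <- function(P, edges) {
  m <- matrix(0, P, P, dimnames = list(as.character(1:P), as.character(1:P)))
  for (e in edges) {
    m[e[1], e[2]] <- e[3]
    m[e[2], e[1]] <- e[3]
  }
  m
}

# Straight-line streamline between two points, as a 2-point polyline.
segment_streamline <- function(a, b, endpoints) {
  list(points = rbind(a, b), endpoints = endpoints)
}
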