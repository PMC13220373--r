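#' Construct a parcellation atlas
#'
#' A parcellation atlas is the spatial frame of the whole analysis: a 3D
#' integer label volume (0 = background, 1..P = parcels) on an isotropic
#' voxel grid, together with a parcel-to-network assignment mapping every
#' parcel to exactly one resting-state network (RSN).
#'
#' @param labels 3D integer array of parcel labels (0 allowed as background).
#' @param voxel_size isotropic voxel edge length in mm.
#' @param network_of character vector of network names, one per parcel;
#'   names (or positions) are parcel ids 1..P.
#' @return an object of class `parcellation_atlas` with fields `labels`,
#'   `voxel_size`, `network_of`, `networks`, `n_parcels`.
#' @export
parcellation_atlas <- function(labels, voxel_size, network_of) {
  if (length(dim(labels)) != 3L)
    stop_validation("labels must be a 3D array")
  labs <- sort(unique(as.integer(labels)))
  labs <- labs[labs != 0L]
  P <- length(network_of)
  if (P < 1L) stop_validation("network_of must cover at least one parcel")
  if (!identical(labs, seq_len(max(labs))) || max(labs) > P)
    stop_validation("parcel labels must be contiguous in 1..P and covered ",
                    "by the network table")
  if (any(!seq_len(P) %in% labs))
    stop_validation("every parcel id 1..P must be non-empty in the volume")
  if (anyNA(network_of))
    stop_validation("every parcel must be assigned exactly one network")
  network_of <- as.character(network_of)
  names(network_of) <- as.character(seq_len(P))
  structure(list(labels = array(as.integer(labels), dim = dim(labels)),
                 voxel_size = as.numeric(voxel_size),
                 network_of = network_of,
                 networks = unique(network_of),
                 n_parcels = P),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %s voxels @ %.3g mm, %d parcels, %d networks\n",
              paste(dim(x$labels), collapse = "x"), x$voxel_size,
              x$n_parcels, length(x$networks)))
  invisible(x)
}

#' Generate a synthetic parcellation atlas
#'
#' Parcels are the Voronoi cells of `n_parcels` seed voxels drawn without
#' replacement from the grid: every voxel takes the label of its nearest
#' seed (squared Euclidean distance between voxel centers; ties resolved in
#' favour of the lowest parcel id). Every parcel is guaranteed non-empty
#' because each seed voxel is at distance zero from its own seed. Parcels
#' are assigned round-trip to networks so that all `n_networks` networks
#' are used, then the remainder at random.
#'
#' @param config a [cohort_config()] object.
#' @return a [parcellation_atlas()].
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  dims <- config$grid_shape
  nvox <- prod(dims)
  if (config$n_parcels > nvox)
    stop_config("more parcels (", config$n_parcels, ") than voxels (",
                nvox, ")")
  set.seed(child_seed(config$seed, "atlas"))
  seeds <- sample.int(nvox, config$n_parcels)
  # voxel-center coordinates, flattened in array order
  cx <- rep(seq_len(dims[1]) - 0.5, times = dims[2] * dims[3])
  cy <- rep(rep(seq_len(dims[2]) - 0.5, each = dims[1]), times = dims[3])
  cz <- rep(seq_len(dims[3]) - 0.5, each = dims[1] * dims[2])
  best <- rep(Inf, nvox)
  lab <- integer(nvox)
  for (p in seq_len(config$n_parcels)) {
    s <- seeds[p]
    d <- (cx - cx[s])^2 + (cy - cy[s])^2 + (cz - cz[s])^2
    upd <- d < best
    lab[upd] <- p
    best[upd] <- d[upd]
  }
  net_names <- sprintf("RSN%02d", seq_len(config$n_networks))
  assign <- c(seq_len(config$n_networks),
              sample.int(config$n_networks,
                         max(0L, config$n_parcels - config$n_networks),
                         replace = TRUE))[seq_len(config$n_parcels)]
  # random permutation so the guaranteed-coverage block is not spatially biased
  assign <- assign[sample.int(config$n_parcels)]
  parcellation_atlas(array(lab, dim = dims), config$voxel_size,
                     net_names[assign])
}
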