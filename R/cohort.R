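#' Configuration for a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generator: the voxel grid,
#' the parcellation, the streamline set, and the lesion trajectory. The same
#' configuration and seed always regenerate bit-identical data; each
#' generator stage derives its own child seed from the master seed, so
#' adding a stage never perturbs earlier ones.
#'
#' @param grid_shape integer vector of 3 positive grid dimensions (voxels).
#' @param voxel_size isotropic voxel size in mm (default 1).
#' @param n_parcels number of parcels (>= 1).
#' @param n_networks number of resting-state networks (1 <= n <= n_parcels).
#' @param n_streamlines number of streamlines in the healthy template.
#' @param lesion_specs list with one element per timepoint, each a list with
#'   `center` (3D voxel coordinate, continuous), `radius` (voxels, 0 gives an
#'   empty mask) and optional `jitter` (voxels, uniform center displacement
#'   emulating boundary shift; default 0). At least two timepoints are
#'   required so a transition exists.
#' @param seed master integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(grid_shape, voxel_size = 1, n_parcels, n_networks,
                          n_streamlines, lesion_specs, seed) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_config("grid_shape must be 3 positive integers")
  if (voxel_size <= 0) stop_config("voxel_size must be positive")
  if (n_parcels < 1L) stop_config("n_parcels must be >= 1")
  if (n_networks < 1L || n_networks > n_parcels)
    stop_config("need 1 <= n_networks <= n_parcels")
  if (n_streamlines < 1L) stop_config("n_streamlines must be >= 1")
  if (!is.list(lesion_specs) || length(lesion_specs) < 2L)
    stop_config("lesion_specs must list at least two timepoints")
  lesion_specs <- lapply(lesion_specs, function(sp) {
    if (is.null(sp$center) || length(sp$center) != 3L || is.null(sp$radius))
      stop_config("each lesion spec needs a 3D center and a radius")
    if (sp$radius < 0) stop_config("lesion radius must be >= 0")
    list(center = as.numeric(sp$center), radius = as.numeric(sp$radius),
         jitter = as.numeric(if (is.null(sp$jitter)) 0 else sp$jitter))
  })
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 n_parcels = as.integer(n_parcels),
                 n_networks = as.integer(n_networks),
                 n_streamlines = as.integer(n_streamlines),
                 lesion_specs = lesion_specs, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' Runs all generator stages in order — atlas, streamlines + healthy
#' connectome, lesion masks + ground truth — and returns them as one bundle.
#'
#' @param config a [cohort_config()].
#' @return list with `config`, `atlas`, `streamlines`, `healthy`, `masks`
#'   (one [lesion_mask()] per timepoint, labelled S1, S2, ...) and
#'   `ground_truth` (see [generate_lesions()]).
#' @export
generate_cohort <- function(config) {
  atlas <- generate_atlas(config)
  sl <- generate_streamlines(atlas, config)
  les <- generate_lesions(config, streamlines = sl$streamlines,
                          healthy = sl$healthy)
  list(config = config, atlas = atlas, streamlines = sl$streamlines,
       healthy = sl$healthy, masks = les$masks,
       ground_truth = les$ground_truth)
}

# Timepoint transitions analyzed for T sessions: consecutive pairs plus the
# overall first-to-last comparison (S1->S2, S2->S3 and S1->S3 when T = 3).
#' Default set of longitudinal transitions
#'
#' @param n_timepoints number of sessions (>= 2).
#' @return 2-column integer matrix of (from, to) timepoint indices.
#' @export
default_transitions <- function(n_timepoints) {
  if (n_timepoints < 2L) stop_config("need at least two timepoints")
  tr <- cbind(seq_len(n_timepoints - 1L), seq(2L, n_timepoints))
  if (n_timepoints > 2L) tr <- rbind(tr, c(1L, n_timepoints))
  colnames(tr) <- c("from", "to")
  tr
}
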