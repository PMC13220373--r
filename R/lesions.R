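#' Construct a binary lesion mask
#'
#' @param grid 3D array of 0/1 values on the atlas grid.
#' @param voxel_size isotropic voxel size in mm.
#' @param timepoint_label session label, e.g. "S1".
#' @param subject_id subject identifier.
#' @return object of class `lesion_mask`.
#' @export
lesion_mask <- function(grid, voxel_size, timepoint_label = "S1",
                        subject_id = "synthetic") {
  if (length(dim(grid)) != 3L)
    stop_validation("lesion mask must be a 3D array")
  v <- as.vector(grid)
  if (!all(v %in% c(0, 1)))
    stop_validation("lesion mask must be binary (0/1)")
  structure(list(grid = array(as.integer(grid), dim = dim(grid)),
                 voxel_size = as.numeric(voxel_size),
                 timepoint_label = timepoint_label,
                 subject_id = subject_id),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s/%s: %d voxels (%.1f mm^3) on %s grid\n",
              x$subject_id, x$timepoint_label, sum(x$grid),
              sum(x$grid) * x$voxel_size^3,
              paste(dim(x$grid), collapse = "x")))
  invisible(x)
}

# Spherical mask: voxel centers within `radius` (voxel units) of a continuous
# center. radius = 0 yields an empty mask.
sphere_mask <- function(dims, center, radius) {
  g <- array(0L, dim = dims)
  if (radius <= 0) return(g)
  cx <- seq_len(dims[1]) - 0.5
  cy <- seq_len(dims[2]) - 0.5
  cz <- seq_len(dims[3]) - 0.5
  d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
              (cz - center[3])^2, "+")
  g[d2 <= radius^2] <- 1L
  g
}

# Brute-force ground-truth interception: plain per-segment, per-point loop.
# Deliberately written as scalar arithmetic so it is an independent oracle
# for the vectorized engine; both sample each segment at points
# a + (k/n)(b - a), n = ceiling(length / step), and map a coordinate x to
# voxel floor(x) + 1 clamped to the grid.
oracle_streamline_hit <- function(points, grid, step = 0.5) {
  dims <- dim(grid)
  for (seg in seq_len(max(1L, nrow(points) - 1L))) {
    a <- points[seg, ]
    b <- points[min(seg + 1L, nrow(points)), ]
    n <- max(1, ceiling(sqrt(sum((b - a)^2)) / step))
    for (k in 0:n) {
      p <- a + (k / n) * (b - a)
      vi <- min(max(floor(p[1]) + 1, 1), dims[1])
      vj <- min(max(floor(p[2]) + 1, 1), dims[2])
      vk <- min(max(floor(p[3]) + 1, 1), dims[3])
      if (grid[vi, vj, vk] == 1L) return(TRUE)
    }
  }
  FALSE
}

oracle_disconnection_matrix <- function(streamlines, healthy, grid) {
  P <- nrow(healthy)
  hit_counts <- matrix(0, P, P, dimnames = dimnames(healthy))
  for (s in streamlines$streamlines) {
    if (oracle_streamline_hit(s$points, grid)) {
      i <- s$endpoints[1]; j <- s$endpoints[2]
      hit_counts[i, j] <- hit_counts[i, j] + 1
      hit_counts[j, i] <- hit_counts[j, i] + 1
    }
  }
  disc <- matrix(0, P, P, dimnames = dimnames(healthy))
  nz <- healthy > 0
  disc[nz] <- hit_counts[nz] / healthy[nz]
  disc
}

#' Generate a temporally evolving lesion and its ground truth
#'
#' One spherical binary mask per timepoint, with optional uniform center
#' jitter emulating boundary shift between sessions. Shrinking radii give
#' nested masks (volume reduction); a larger later radius emulates transient
#' regrowth, i.e. a negative percent volume change. When the cohort's
#' streamlines and healthy connectome are supplied, ground-truth
#' disconnection fractions are computed for every timepoint by exhaustive
#' per-streamline voxel membership (the brute-force oracle), and every
#' transition's true edge categories are derived from the zero/non-zero
#' status of the implied true weights.
#'
#' @param config a [cohort_config()].
#' @param streamlines optional [streamline_set()] for ground-truth fractions.
#' @param healthy optional healthy count matrix (required with streamlines).
#' @return list with `masks` (list of [lesion_mask()], labels S1, S2, ...)
#'   and `ground_truth`: `lesion_volume_true` (mm^3 per timepoint),
#'   `disconnection_fraction_true` (list of P x P matrices, if streamlines
#'   given) and `edge_category_true` (list per transition).
#' @export
generate_lesions <- function(config, streamlines = NULL, healthy = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  dims <- config$grid_shape
  set.seed(child_seed(config$seed, "lesions"))
  masks <- vector("list", length(config$lesion_specs))
  for (t in seq_along(config$lesion_specs)) {
    sp <- config$lesion_specs[[t]]
    ctr <- sp$center + stats::runif(3, -sp$jitter, sp$jitter)
    if (sp$radius > 0 &&
        (any(ctr + sp$radius < 0) || any(ctr - sp$radius > dims)))
      stop_config("lesion at timepoint ", t, " lies entirely outside the grid")
    masks[[t]] <- lesion_mask(sphere_mask(dims, ctr, sp$radius),
                              config$voxel_size,
                              timepoint_label = paste0("S", t))
  }
  names(masks) <- vapply(masks, `[[`, "", "timepoint_label")
  gt <- list(lesion_volume_true =
               vapply(masks, function(m) sum(m$grid) * m$voxel_size^3, 0))
  if (!is.null(streamlines)) {
    if (is.null(healthy))
      stop_validation("healthy connectome required for ground truth")
    gt$disconnection_fraction_true <-
      lapply(masks, function(m)
        oracle_disconnection_matrix(streamlines, healthy, m$grid))
    tr <- default_transitions(length(masks))
    gt$edge_category_true <- lapply(seq_len(nrow(tr)), function(r) {
      wa <- healthy * (1 - gt$disconnection_fraction_true[[tr[r, 1]]])
      wb <- healthy * (1 - gt$disconnection_fraction_true[[tr[r, 2]]])
      up <- upper.tri(wa)
      cat_true <- ifelse(wa[up] > 0 & wb[up] == 0, "disconnection",
                  ifelse(wa[up] == 0 & wb[up] > 0, "re-emerging",
                  ifelse(wa[up] > 0 & wb[up] > 0 &
                           (wb[up] - wa[up]) / ifelse(wa[up] > 0, wa[up], 1) >
                             0.10, "over-connection",
                  ifelse(wa[up] > 0 & wb[up] > 0, "persistent-other",
                         "absent-both"))))
      list(from = tr[r, 1], to = tr[r, 2], category = cat_true)
    })
  }
  list(masks = masks, ground_truth = gt)
}
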