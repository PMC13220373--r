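#' Streamline sets
#'
#' A streamline is a 3D polyline in the continuous voxel frame of the atlas
#' grid: a coordinate `x` in `[0, dim)` lies in voxel `floor(x) + 1` (1-based
#' array index). Each streamline carries its unordered endpoint parcel pair
#' `{i, j}` with `i != j`; its first and last points lie inside those
#' parcels. The voxel frame is the only coordinate convention used
#' internally — affine transforms are handled at I/O time only.
#'
#' @param streamlines list; each element a list with `points` (n x 3 numeric
#'   matrix, n >= 2) and `endpoints` (integer pair, stored sorted).
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines) {
  for (s in streamlines) {
    if (!is.matrix(s$points) || ncol(s$points) != 3L || nrow(s$points) < 1L)
      stop_validation("each streamline needs an n x 3 point matrix")
    if (length(s$endpoints) != 2L || s$endpoints[1] == s$endpoints[2])
      stop_validation("endpoints must be two distinct parcel ids")
  }
  structure(list(streamlines = lapply(streamlines, function(s)
    list(points = s$points, endpoints = sort(as.integer(s$endpoints)))),
    n = length(streamlines)), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines\n", x$n))
  invisible(x)
}

# Resample a polyline so consecutive points are at most `step` voxels apart.
# Each segment A->B is replaced by points A + (k/n) (B - A), k = 0..n with
# n = ceiling(|B - A| / step); shared segment endpoints are not duplicated.
# Both the vectorized interception path and the brute-force oracle use this
# exact arithmetic, so their sampled point sets agree bitwise.
densify_polyline <- function(points, step = 0.5) {
  if (!is.matrix(points) || ncol(points) != 3L || nrow(points) < 1L)
    stop_validation("polyline must be a non-empty n x 3 matrix")
  if (nrow(points) == 1L) return(points)
  out <- vector("list", nrow(points) - 1L)
  for (k in seq_len(nrow(points) - 1L)) {
    a <- points[k, ]
    b <- points[k + 1L, ]
    n <- max(1, ceiling(sqrt(sum((b - a)^2)) / step))
    t <- seq.int(0L, n) / n
    seg <- cbind(a[1] + t * (b[1] - a[1]),
                 a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    out[[k]] <- if (k == 1L) seg else seg[-1L, , drop = FALSE]
  }
  do.call(rbind, out)
}

# 1-based linear voxel indices of continuous voxel-frame coordinates,
# clamped onto the grid.
voxel_index <- function(points, dims) {
  i <- pmin.int(pmax.int(floor(points[, 1]) + 1, 1), dims[1])
  j <- pmin.int(pmax.int(floor(points[, 2]) + 1, 1), dims[2])
  k <- pmin.int(pmax.int(floor(points[, 3]) + 1, 1), dims[3])
  as.integer(i + (j - 1) * dims[1] + (k - 1) * dims[1] * dims[2])
}

#' Generate synthetic streamlines and the healthy connectome
#'
#' Draws `n_streamlines` polylines. For each, two distinct parcels are
#' sampled uniformly, a random voxel center is chosen inside each parcel as
#' an endpoint, and the path is a gentle arc: the straight segment bent at a
#' jittered midpoint, then densified to at most one-voxel point spacing so
#' no traversed voxel can be skipped by the interception test. The healthy
#' connectome counts streamlines per unordered endpoint pair; its minimum
#' non-zero entry is therefore at least 1.
#'
#' @param atlas a [parcellation_atlas()].
#' @param config the [cohort_config()] used to build the atlas.
#' @return list with `streamlines` (a [streamline_set()]) and `healthy`
#'   (P x P symmetric integer count matrix, zero diagonal).
#' @export
generate_streamlines <- function(atlas, config) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  set.seed(child_seed(config$seed, "streamlines"))
  dims <- dim(atlas$labels)
  P <- atlas$n_parcels
  if (P < 2L) stop_config("streamline generation needs at least 2 parcels")
  vox_by_parcel <- split(seq_along(atlas$labels), as.vector(atlas$labels))
  vox_by_parcel <- vox_by_parcel[names(vox_by_parcel) != "0"]
  center_of <- function(lin) {
    lin <- lin - 1L
    i <- lin %% dims[1]
    j <- (lin %/% dims[1]) %% dims[2]
    k <- lin %/% (dims[1] * dims[2])
    c(i, j, k) + 0.5
  }
  sls <- vector("list", config$n_streamlines)
  for (s in seq_len(config$n_streamlines)) {
    pair <- sort(sample.int(P, 2L))
    a <- center_of(sample(vox_by_parcel[[as.character(pair[1])]], 1L))
    b <- center_of(sample(vox_by_parcel[[as.character(pair[2])]], 1L))
    bend <- stats::runif(3, -1, 1) * (0.15 * sqrt(sum((b - a)^2)))
    mid <- pmin(pmax((a + b) / 2 + bend, 0.01), dims - 0.01)
    pts <- densify_polyline(rbind(a, mid, b), step = 0.75)
    sls[[s]] <- list(points = pts, endpoints = pair)
  }
  set <- streamline_set(sls)
  healthy <- matrix(0L, P, P, dimnames = list(as.character(seq_len(P)),
                                              as.character(seq_len(P))))
  for (s in set$streamlines) {
    i <- s$endpoints[1]; j <- s$endpoints[2]
    healthy[i, j] <- healthy[i, j] + 1L
    healthy[j, i] <- healthy[j, i] + 1L
  }
  list(streamlines = set, healthy = healthy)
}
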