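#' Does a lesion intercept a streamline?
#'
#' A streamline is intercepted if any sampled point of its polyline, after
#' densification to at most one-voxel point spacing, falls in a lesion
#' voxel. No minimum overlap length is required — a single touched voxel
#' counts, the most sensitive reading of lesion-tract intersection.
#'
#' @param streamline a single streamline (list with `points`) or a bare
#'   n x 3 point matrix in the voxel frame.
#' @param mask a [lesion_mask()] on the atlas grid.
#' @return logical.
#' @export
streamline_intercepted <- function(streamline, mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  pts <- if (is.matrix(streamline)) streamline else streamline$points
  if (is.null(pts) || nrow(pts) == 0L)
    stop_validation("empty polyline")
  dense <- densify_polyline(pts, step = 0.5)
  idx <- voxel_index(dense, dim(mask$grid))
  any(mask$grid[idx] == 1L)
}

#' Disconnection and spared fractions for every parcel pair
#'
#' For each parcel pair with healthy streamlines, the disconnection
#' fraction is the proportion of that pair's reference streamlines
#' intercepted by the lesion; the spared fraction is its complement
#' (1 - disconnection). Pairs with no healthy streamlines have nothing to
#' intercept and carry spared = 1, disconnection = 0 by convention, keeping
#' patient matrices consistent with the reference connectome.
#'
#' @param streams a [streamline_set()].
#' @param healthy P x P healthy streamline-count matrix.
#' @param mask a [lesion_mask()].
#' @return object of class `spared_fraction_matrix`: list with symmetric
#'   P x P matrices `spared` and `disconnection` (zero diagonal on
#'   `disconnection`), and `n_intercepted` per pair.
#' @export
disconnection_fractions <- function(streams, healthy, mask) {
  stopifnot(inherits(streams, "streamline_set"))
  check_square_symmetric(healthy, "healthy connectome")
  P <- nrow(healthy)
  dims <- dim(mask$grid)
  grid_flat <- as.vector(mask$grid)
  hit_counts <- matrix(0, P, P, dimnames = dimnames(healthy))
  for (s in streams$streamlines) {
    i <- s$endpoints[1]; j <- s$endpoints[2]
    if (i > P || j > P || healthy[i, j] <= 0)
      stop_validation("streamline endpoint pair (", i, ",", j,
                      ") absent from the healthy connectome")
    dense <- densify_polyline(s$points, step = 0.5)
    if (any(grid_flat[voxel_index(dense, dims)] == 1L)) {
      hit_counts[i, j] <- hit_counts[i, j] + 1
      hit_counts[j, i] <- hit_counts[j, i] + 1
    }
  }
  disc <- matrix(0, P, P, dimnames = dimnames(healthy))
  nz <- healthy > 0
  disc[nz] <- hit_counts[nz] / healthy[nz]
  spared <- 1 - disc
  diag(spared) <- 1
  structure(list(spared = spared, disconnection = disc,
                 n_intercepted = hit_counts),
            class = "spared_fraction_matrix")
}

#' Patient-weighted connectivity matrix
#'
#' The estimated post-stroke streamline count per edge:
#' `weighted(i, j) = healthy(i, j) * spared(i, j)`. Weights are bounded by
#' the healthy counts and inherit their symmetry and zero diagonal.
#'
#' @param healthy P x P healthy count matrix.
#' @param spared a [disconnection_fractions()] result or a bare P x P
#'   spared-fraction matrix in \[0, 1\].
#' @return symmetric P x P weighted matrix.
#' @export
weight_patient <- function(healthy, spared) {
  sp <- if (inherits(spared, "spared_fraction_matrix")) spared$spared else spared
  check_square_symmetric(healthy, "healthy connectome")
  if (!identical(dim(sp), dim(healthy)))
    stop_validation("spared matrix dimensions differ from healthy")
  if (any(sp < 0) || any(sp > 1))
    stop_validation("spared fractions must lie in [0, 1]")
  w <- healthy * sp
  diag(w) <- 0
  w
}

#' Binary connectivity matrix
#'
#' Thresholds a weighted matrix at zero: strictly positive weights become 1
#' (existing connection), zeros stay 0 — either all reference streamlines
#' of the pair are intersected by the lesion, or the healthy atlas has no
#' streamlines there at all.
#'
#' @param weighted P x P weighted connectivity matrix.
#' @return P x P matrix in \{0, 1\}.
#' @export
binarize <- function(weighted) {
  check_square_symmetric(weighted, "weighted connectome")
  (weighted > 0) * 1
}
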