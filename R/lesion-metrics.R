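#' Lesion volume in cubic millimetres
#'
#' @param mask a [lesion_mask()].
#' @return voxel count times voxel_size^3.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$grid) * mask$voxel_size^3
}

#' Percent lesion volume change, reduction-positive
#'
#' Computed as `(v_earlier - v_later) / v_earlier * 100`: positive values
#' indicate volume reduction (recovery), negative values volume increase
#' (regrowth). `percent_change(v, 0)` is 100 (complete resolution).
#'
#' @param v_earlier volume at the earlier timepoint (must be > 0).
#' @param v_later volume at the later timepoint.
#' @return signed percentage.
#' @export
percent_change <- function(v_earlier, v_later) {
  if (any(v_earlier <= 0))
    stop_validation("percent change undefined for zero baseline volume")
  (v_earlier - v_later) / v_earlier * 100
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree perfectly
#' (DSC = 1), avoiding 0/0 in line with common segmentation practice.
#'
#' @param mask_a,mask_b [lesion_mask()] objects on the same grid.
#' @return value in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "lesion_mask"), inherits(mask_b, "lesion_mask"))
  if (!identical(dim(mask_a$grid), dim(mask_b$grid)))
    stop_validation("mask grids differ in shape")
  na <- sum(mask_a$grid); nb <- sum(mask_b$grid)
  if (na + nb == 0) return(1)
  2 * sum(mask_a$grid == 1L & mask_b$grid == 1L) / (na + nb)
}

#' Normalized mutual information of two images
#'
#' Registration-quality metric `NMI = (H(A) + H(B)) / H(A, B)` from the
#' joint histogram, with equal-width binning over the pooled intensity
#' range of the two images. Under this normalization NMI >= 1, identical
#' (non-constant) images give 2, and independent images approach 1.
#'
#' @param image_a,image_b numeric arrays of the same shape.
#' @param n_bins number of histogram bins per image (>= 2, default 32).
#' @return NMI value (>= 1).
#' @export
normalized_mutual_information <- function(image_a, image_b, n_bins = 32L) {
  if (!identical(dim(image_a), dim(image_b)))
    stop_validation("images differ in shape")
  if (n_bins < 2L) stop_validation("n_bins must be >= 2")
  va <- as.vector(image_a); vb <- as.vector(image_b)
  if (min(va) == max(va) || min(vb) == max(vb))
    stop_validation("constant image has zero entropy; NMI undefined")
  r <- range(c(va, vb))
  bin <- function(x)
    pmin.int(floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  ba <- bin(va)
  bb <- bin(vb)
  joint <- tabulate(ba + (bb - 1L) * n_bins, nbins = n_bins * n_bins)
  pj <- joint[joint > 0] / length(ba)
  pa <- tabulate(ba, nbins = n_bins); pa <- pa[pa > 0] / length(ba)
  pb <- tabulate(bb, nbins = n_bins); pb <- pb[pb > 0] / length(bb)
  ent <- function(p) -sum(p * log(p))
  (ent(pa) + ent(pb)) / ent(pj)
}

#' Lesion load per parcel and per network
#'
#' Intersects the lesion mask with every atlas parcel. Per-parcel damaged
#' volume is the overlap voxel count times voxel volume; network loads are
#' the sums over member parcels. Parcels without overlap report 0.
#'
#' @param mask a [lesion_mask()].
#' @param atlas a [parcellation_atlas()] on the same grid.
#' @return list with data.frames `parcels` (parcel, network, damaged_mm3)
#'   and `networks` (network, damaged_mm3), plus `total_mm3` and
#'   `background_mm3` (lesion volume on unlabeled voxels).
#' @export
lesion_load_by_parcel <- function(mask, atlas) {
  stopifnot(inherits(mask, "lesion_mask"),
            inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(mask$grid), dim(atlas$labels)))
    stop_validation("mask and atlas grids differ in shape")
  P <- atlas$n_parcels
  vol <- mask$voxel_size^3
  hit <- as.vector(atlas$labels)[as.vector(mask$grid) == 1L]
  counts <- tabulate(hit[hit > 0L], nbins = P)
  parcels <- data.frame(parcel = seq_len(P),
                        network = unname(atlas$network_of),
                        damaged_mm3 = counts * vol)
  nets <- stats::aggregate(damaged_mm3 ~ network, parcels, sum)
  nets <- nets[match(atlas$networks, nets$network), , drop = FALSE]
  rownames(nets) <- NULL
  list(parcels = parcels, networks = nets,
       total_mm3 = lesion_volume(mask),
       background_mm3 = sum(hit == 0L) * vol)
}

#' Per-subject longitudinal lesion metrics table
#'
#' One row per timepoint: volume, percent change from the previous session
#' and from the first session (reduction-positive), and Dice similarity with
#' the previous session's mask.
#'
#' @param masks list of [lesion_mask()] in session order.
#' @return data.frame with columns timepoint, volume_mm3, pct_change_prev,
#'   pct_change_first, dsc_prev.
#' @export
lesion_metrics_table <- function(masks) {
  vols <- vapply(masks, lesion_volume, 0)
  n <- length(masks)
  pc <- function(a, b) if (vols[a] > 0) percent_change(vols[a], vols[b]) else NA_real_
  data.frame(
    timepoint = vapply(masks, `[[`, "", "timepoint_label"),
    volume_mm3 = unname(vols),
    pct_change_prev = c(NA_real_, vapply(seq_len(n - 1L),
                                         function(t) pc(t, t + 1L), 0)),
    pct_change_first = c(NA_real_, vapply(seq(2L, length.out = n - 1L),
                                          function(t) pc(1L, t), 0)),
    dsc_prev = c(NA_real_, vapply(seq_len(n - 1L), function(t)
      dice_coefficient(masks[[t]], masks[[t + 1L]]), 0)),
    row.names = NULL)
}
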