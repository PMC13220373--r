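#' Baseline floor: 5th percentile of non-zero baseline weights
#'
#' Relative change is unstable when the baseline weight is near zero, so
#' persistent edges are screened against a minimum absolute floor: the 5th
#' percentile of all strictly positive baseline edge weights (upper
#' triangle) of the transition, computed with linear interpolation between
#' order statistics. The floor depends only on the baseline matrix, so it
#' is identical across sensitivity thresholds.
#'
#' @param w_baseline P x P weighted matrix at the earlier timepoint, or a
#'   bare numeric vector of baseline weights.
#' @return the floor value.
#' @export
baseline_floor <- function(w_baseline) {
  x <- if (is.matrix(w_baseline)) {
    check_square_symmetric(w_baseline, "baseline weighted matrix")
    w_baseline[upper.tri(w_baseline)]
  } else as.numeric(w_baseline)
  x <- x[x > 0]
  if (length(x) == 0)
    stop_validation("all baseline weights are zero; floor undefined")
  stats::quantile(x, 0.05, type = 7, names = FALSE)
}

#' Classify persistent edges by relative change
#'
#' Persistent edges (weight > 0 at both timepoints) with baseline at or
#' above the floor are classed as substantial-increase (relative change
#' strictly above `+threshold_pct`), substantial-decrease (strictly below
#' `-threshold_pct`) or stable. Edges with baseline strictly below the
#' floor are flagged `floor_excluded` and carry no class. Threshold
#' comparisons are made on the raw change ratio, so a change of exactly
#' the threshold is stable.
#'
#' @param w_a,w_b weighted matrices at the two timepoints.
#' @param threshold_pct relative-change threshold in percent (default 10).
#' @param floor baseline floor; defaults to [baseline_floor()] of `w_a`.
#' @return data.frame of class `edge_change_table`, one row per persistent
#'   edge: i, j, w_baseline, w_followup, rel_change_pct, floor_value,
#'   floor_excluded, class (NA when excluded).
#' @export
classify_persistent <- function(w_a, w_b, threshold_pct = 10, floor = NULL) {
  check_square_symmetric(w_a, "baseline weighted matrix")
  check_square_symmetric(w_b, "follow-up weighted matrix")
  if (!identical(dim(w_a), dim(w_b)))
    stop_validation("matrix dimensions differ")
  if (threshold_pct <= 0) stop_validation("threshold_pct must be positive")
  if (is.null(floor)) floor <- baseline_floor(w_a)
  P <- nrow(w_a)
  pairs <- upper_pairs(P)
  a <- w_a[pairs]; b <- w_b[pairs]
  keep <- a > 0 & b > 0
  pairs <- pairs[keep, , drop = FALSE]
  a <- a[keep]; b <- b[keep]
  frac <- (b - a) / a
  excluded <- a < floor
  cls <- ifelse(frac > threshold_pct / 100, "substantial-increase",
         ifelse(frac < -threshold_pct / 100, "substantial-decrease",
                "stable"))
  cls[excluded] <- NA_character_
  out <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    w_baseline = a, w_followup = b,
                    rel_change_pct = frac * 100,
                    floor_value = floor, floor_excluded = excluded,
                    class = factor(cls, levels = c("substantial-increase",
                                                   "substantial-decrease",
                                                   "stable")))
  class(out) <- c("edge_change_table", "data.frame")
  attr(out, "threshold_pct") <- threshold_pct
  attr(out, "n_parcels") <- P
  out
}

#' Net substantial change per network
#'
#' Every classed edge is attributed to both endpoint networks: an edge
#' between two networks counts once for each, an intra-network edge once
#' for its single network (an edge cannot contribute twice to the same
#' network). Net change is the number of substantially increased minus
#' substantially decreased connections per network.
#'
#' @param table an [classify_persistent()] result.
#' @param network_of character vector of network names per parcel id.
#' @return data.frame: network, n_increase, n_decrease, net.
#' @export
net_change_by_network <- function(table, network_of) {
  stopifnot(inherits(table, "edge_change_table"))
  network_of <- as.character(network_of)
  nets <- unique(network_of)
  inc <- stats::setNames(numeric(length(nets)), nets)
  dec <- inc
  keep <- !table$floor_excluded & !is.na(table$class) &
    table$class != "stable"
  rows <- table[keep, , drop = FALSE]
  if (nrow(rows) > 0) {
    ni <- network_of[rows$i]; nj <- network_of[rows$j]
    for (r in seq_len(nrow(rows))) {
      touched <- unique(c(ni[r], nj[r]))
      if (rows$class[r] == "substantial-increase")
        inc[touched] <- inc[touched] + 1
      else
        dec[touched] <- dec[touched] + 1
    }
  }
  out <- data.frame(network = nets, n_increase = unname(inc),
                    n_decrease = unname(dec), net = unname(inc - dec))
  attr(out, "threshold_pct") <- attr(table, "threshold_pct")
  out
}

#' Threshold sensitivity sweep
#'
#' Re-runs the substantial-change analysis at several relative-change
#' thresholds (primary 10%, with 5% and 20% flanking by default). The
#' baseline floor is recomputed for each threshold — and is identical
#' every time, since it depends only on the baseline weights. The
#' stability report states, per network, whether the sign of the net
#' change is preserved across thresholds (zeros are compatible with
#' either sign).
#'
#' @param w_a,w_b weighted matrices at the two timepoints.
#' @param thresholds vector of positive percentages (default c(5, 10, 20)).
#' @param network_of character vector of network names per parcel id.
#' @return list with `net_change` (long data.frame with a threshold_pct
#'   column), `floors` (named per-threshold floor values), and `stability`
#'   (network, signs per threshold, sign_stable flag).
#' @export
sensitivity_sweep <- function(w_a, w_b, thresholds = c(5, 10, 20),
                              network_of) {
  if (any(thresholds <= 0)) stop_validation("thresholds must be positive")
  per <- lapply(thresholds, function(th) {
    fl <- baseline_floor(w_a)
    tab <- classify_persistent(w_a, w_b, threshold_pct = th, floor = fl)
    nc <- net_change_by_network(tab, network_of)
    nc$threshold_pct <- th
    nc$floor_value <- fl
    nc
  })
  long <- do.call(rbind, per)
  nets <- unique(long$network)
  stab <- do.call(rbind, lapply(nets, function(n) {
    signs <- sign(long$net[long$network == n])
    nz <- signs[signs != 0]
    data.frame(network = n,
               sign_stable = length(unique(nz)) <= 1L)
  }))
  list(net_change = long,
       floors = stats::setNames(vapply(per, function(x) x$floor_value[1], 0),
                                paste0("thr", thresholds)),
       stability = stab)
}
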