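EDGE_CATEGORIES <- c("disconnection", "re-emerging", "over-connection",
                     "persistent-other", "absent-both")

#' Classify every edge between two timepoints
#'
#' Each unordered edge (upper triangle, self-connections excluded) receives
#' exactly one category from the zero/non-zero status of its weights at the
#' two timepoints:
#' \itemize{
#'   \item disconnection — present at baseline, absent at follow-up;
#'   \item re-emerging — absent at baseline, present at follow-up;
#'   \item over-connection — present at both and relative increase strictly
#'     greater than `over_threshold_pct` (default 10%);
#'   \item persistent-other — present at both, not over-connected;
#'   \item absent-both — absent at both timepoints.
#' }
#' The first three categories are mutually exclusive by construction. The
#' relative change `((w_followup - w_baseline) / w_baseline) * 100` is
#' recorded for edges present at both timepoints; the threshold comparison
#' is done on the raw ratio so a change of exactly the threshold is never
#' classed as over-connection.
#'
#' @param w_a weighted matrix at the earlier timepoint.
#' @param w_b weighted matrix at the later timepoint.
#' @param over_threshold_pct strictly-greater-than threshold in percent.
#' @return data.frame of class `edge_transition_table`: columns i, j, w_a,
#'   w_b, category, rel_change_pct (NA unless present at both timepoints).
#' @export
classify_edges <- function(w_a, w_b, over_threshold_pct = 10) {
  check_square_symmetric(w_a, "baseline weighted matrix")
  check_square_symmetric(w_b, "follow-up weighted matrix")
  if (!identical(dim(w_a), dim(w_b)))
    stop_validation("matrix dimensions differ")
  if (any(w_a < 0) || any(w_b < 0))
    stop_validation("weights must be non-negative")
  if (over_threshold_pct <= 0)
    stop_validation("over_threshold_pct must be positive")
  P <- nrow(w_a)
  pairs <- upper_pairs(P)
  a <- w_a[pairs]; b <- w_b[pairs]
  persistent <- a > 0 & b > 0
  rel <- rep(NA_real_, length(a))
  rel[persistent] <- (b[persistent] - a[persistent]) / a[persistent] * 100
  frac <- rep(NA_real_, length(a))
  frac[persistent] <- (b[persistent] - a[persistent]) / a[persistent]
  category <- character(length(a))
  category[a > 0 & b == 0] <- "disconnection"
  category[a == 0 & b > 0] <- "re-emerging"
  category[persistent] <-
    ifelse(frac[persistent] > over_threshold_pct / 100,
           "over-connection", "persistent-other")
  category[a == 0 & b == 0] <- "absent-both"
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], w_a = a, w_b = b,
                    category = factor(category, levels = EDGE_CATEGORIES),
                    rel_change_pct = rel)
  class(out) <- c("edge_transition_table", "data.frame")
  attr(out, "over_threshold_pct") <- over_threshold_pct
  attr(out, "n_parcels") <- P
  out
}

#' Absolute and normalized change counts for a transition
#'
#' Counts edges per category and normalizes each count by the number of
#' existing connections at the earlier timepoint (strictly positive
#' baseline weights), expressed as a percentage. Two over-connection
#' variants are reported: the plain count, and the count restricted to
#' edges whose baseline weight reaches the 5th-percentile baseline floor —
#' the floor exists to counter inflation of relative changes at
#' near-zero baselines.
#'
#' @param table an [classify_edges()] result.
#' @param binary_a binary connectivity at the earlier timepoint (defaults
#'   to the baseline weights in `table`).
#' @return one-row data.frame: n_existing_baseline, n_disconnections,
#'   n_reemerging, n_overconnections, n_overconnections_floored,
#'   n_persistent_other, n_absent_both and normalized (`*_norm_pct`)
#'   counterparts for the three change categories.
#' @export
count_changes <- function(table, binary_a = NULL) {
  stopifnot(inherits(table, "edge_transition_table"))
  n_existing <- if (is.null(binary_a)) sum(table$w_a > 0)
                else sum(binarize(binary_a)[upper.tri(binary_a)])
  if (n_existing == 0)
    stop_validation("no existing connections at the earlier timepoint; ",
                    "normalized counts undefined")
  tab <- base::table(table$category)
  floor_val <- if (any(table$w_a > 0)) {
    stats::quantile(table$w_a[table$w_a > 0], 0.05, type = 7, names = FALSE)
  } else NA_real_
  n_over_floored <- sum(table$category == "over-connection" &
                          table$w_a >= floor_val)
  data.frame(
    n_existing_baseline = n_existing,
    n_disconnections = as.integer(tab[["disconnection"]]),
    n_reemerging = as.integer(tab[["re-emerging"]]),
    n_overconnections = as.integer(tab[["over-connection"]]),
    n_overconnections_floored = as.integer(n_over_floored),
    n_persistent_other = as.integer(tab[["persistent-other"]]),
    n_absent_both = as.integer(tab[["absent-both"]]),
    disconnections_norm_pct = 100 * tab[["disconnection"]] / n_existing,
    reemerging_norm_pct = 100 * tab[["re-emerging"]] / n_existing,
    overconnections_norm_pct = 100 * tab[["over-connection"]] / n_existing)
}

#' Per-network gained and lost connections
#'
#' Attributes every re-emerging (gained) and disconnected (lost) edge to
#' its endpoint networks: a cross-network edge counts once for each of the
#' two networks, an intra-network edge once for its single network. The
#' difference gained - lost summarizes each network's net connection
#' turnover for the transition.
#'
#' @param table an [classify_edges()] result.
#' @param network_of character vector of network names per parcel id.
#' @return data.frame: network, gained, lost, difference.
#' @export
rsn_gain_loss <- function(table, network_of) {
  stopifnot(inherits(table, "edge_transition_table"))
  network_of <- as.character(network_of)
  if (attr(table, "n_parcels") > length(network_of))
    stop_validation("network_of must map every parcel")
  nets <- unique(network_of)
  count_touch <- function(rows) {
    cnt <- stats::setNames(numeric(length(nets)), nets)
    if (nrow(rows) > 0) {
      ni <- network_of[rows$i]; nj <- network_of[rows$j]
      for (r in seq_len(nrow(rows)))
        for (n in unique(c(ni[r], nj[r]))) cnt[n] <- cnt[n] + 1
    }
    cnt
  }
  gained <- count_touch(table[table$category == "re-emerging", , drop = FALSE])
  lost <- count_touch(table[table$category == "disconnection", , drop = FALSE])
  data.frame(network = nets, gained = unname(gained), lost = unname(lost),
             difference = unname(gained - lost))
}

#' Lesion-evolution covariate table
#'
#' Contextualizes the discrete connectivity changes of each transition with
#' the lesion's own evolution: percent volume change (reduction-positive),
#' Dice overlap of the two masks, the absolute and normalized category
#' counts, and the normalized re-emerging percentage as the "re-emerging
#' ratio".
#'
#' @param masks list of [lesion_mask()] per timepoint.
#' @param counts_list list of [count_changes()] rows, one per transition.
#' @param transitions 2-column (from, to) matrix; defaults to
#'   [default_transitions()].
#' @return data.frame, one row per transition.
#' @export
lesion_covariate_table <- function(masks, counts_list, transitions = NULL) {
  if (length(masks) < 2L) stop_validation("need at least two timepoints")
  if (is.null(transitions)) transitions <- default_transitions(length(masks))
  stopifnot(length(counts_list) == nrow(transitions))
  rows <- lapply(seq_len(nrow(transitions)), function(r) {
    a <- transitions[r, 1]; b <- transitions[r, 2]
    va <- lesion_volume(masks[[a]])
    cbind(data.frame(
      from = masks[[a]]$timepoint_label, to = masks[[b]]$timepoint_label,
      volume_pct_change = if (va > 0)
        percent_change(va, lesion_volume(masks[[b]])) else NA_real_,
      dsc = dice_coefficient(masks[[a]], masks[[b]])),
      counts_list[[r]],
      data.frame(reemerging_ratio_pct =
                   counts_list[[r]]$reemerging_norm_pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
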