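#' Per-edge connectivity loss relative to the healthy template
#'
#' `loss = healthy - weighted`, equivalently `healthy * disconnection`:
#' how many reference streamlines of each edge the lesion removes.
#'
#' @param healthy P x P healthy count matrix.
#' @param weighted P x P patient-weighted matrix (elementwise <= healthy).
#' @return symmetric non-negative P x P loss matrix.
#' @export
connectivity_loss <- function(healthy, weighted) {
  check_square_symmetric(healthy, "healthy connectome")
  if (!identical(dim(weighted), dim(healthy)))
    stop_validation("matrix dimensions differ")
  if (any(weighted > healthy + 1e-9))
    stop_validation("weighted connectivity exceeds healthy counts")
  pmax(healthy - weighted, 0)
}

#' Within- and between-network vulnerability
#'
#' Aggregates per-edge connectivity losses to the resting-state-network
#' level. For each network, the within-network loss sums edges with both
#' endpoints in the network, the between-network loss sums edges with
#' exactly one endpoint in it (so every cross-network edge is attributed to
#' both of its endpoint networks). Each raw loss is normalized by the same
#' network's healthy total of the corresponding kind and expressed as a
#' percentage; a network with no healthy connectivity of one kind reports
#' 0 and is flagged. All sums run over unordered pairs (upper triangle,
#' self-connections excluded).
#'
#' @param loss P x P loss matrix from [connectivity_loss()].
#' @param healthy P x P healthy count matrix.
#' @param network_of character vector of network names per parcel id.
#' @return data.frame with one row per network: within_loss_raw,
#'   between_loss_raw, within_healthy, between_healthy, within_pct,
#'   between_pct, zero_within_denominator, zero_between_denominator.
#' @export
network_vulnerability <- function(loss, healthy, network_of) {
  check_square_symmetric(healthy, "healthy connectome")
  P <- nrow(healthy)
  if (length(network_of) != P)
    stop_validation("network_of must map every parcel")
  up <- upper.tri(healthy)
  nets <- unique(as.character(network_of))
  rows <- lapply(nets, function(n) {
    memb <- as.character(network_of) == n
    within <- outer(memb, memb, "&") & up
    between <- outer(memb, memb, FUN = xor) & up
    wl <- sum(loss[within]); wh <- sum(healthy[within])
    bl <- sum(loss[between]); bh <- sum(healthy[between])
    data.frame(network = n,
               within_loss_raw = wl, between_loss_raw = bl,
               within_healthy = wh, between_healthy = bh,
               within_pct = if (wh > 0) 100 * wl / wh else 0,
               between_pct = if (bh > 0) 100 * bl / bh else 0,
               zero_within_denominator = wh == 0,
               zero_between_denominator = bh == 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
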