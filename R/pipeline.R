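#' Subject record with timepoints and optional clinical scores
#'
#' Clinical scores are carried as plain descriptive data — the package
#' computes no statistics on them. Accepted scales and ranges: modified
#' Rankin scale (mRS, 0-5), NIH stroke scale (NIHSS, 0-42), Barthel index
#' (BI, 0-100), Fugl-Meyer assessment upper extremity (FMA-UE, 0-66).
#'
#' @param subject_id subject identifier.
#' @param timepoints character session labels, e.g. c("S1","S2","S3").
#' @param days_post_onset optional numeric days after stroke onset.
#' @param scores optional data.frame with column `timepoint` and any of
#'   `mrs`, `nihss`, `bi`, `fma_ue`; NA marks a missing assessment.
#' @return object of class `subject_record`.
#' @export
subject_record <- function(subject_id, timepoints, days_post_onset = NULL,
                           scores = NULL) {
  ranges <- list(mrs = c(0, 5), nihss = c(0, 42), bi = c(0, 100),
                 fma_ue = c(0, 66))
  if (!is.null(scores)) {
    if (!"timepoint" %in% names(scores))
      stop_validation("scores need a timepoint column")
    for (sc in intersect(names(ranges), names(scores))) {
      v <- scores[[sc]]
      bad <- !is.na(v) & (v < ranges[[sc]][1] | v > ranges[[sc]][2])
      if (any(bad))
        stop_validation(sc, " score out of range [", ranges[[sc]][1], ", ",
                        ranges[[sc]][2], "]")
    }
  }
  structure(list(subject_id = subject_id, timepoints = timepoints,
                 days_post_onset = days_post_onset, scores = scores),
            class = "subject_record")
}

#' Pipeline run configuration
#'
#' Defaults reproduce the primary analysis settings: a 10% over-connection
#' and substantial-change threshold, a 5/10/20% sensitivity sweep, and the
#' linear-interpolation percentile for the baseline floor.
#'
#' @param cohort a [cohort_config()] describing the synthetic subject.
#' @param output_dir directory for the report bundle.
#' @param over_threshold_pct relative-increase threshold (percent).
#' @param sensitivity_thresholds thresholds for the sensitivity sweep.
#' @param subject_id subject identifier used in outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort, output_dir, over_threshold_pct = 10,
                       sensitivity_thresholds = c(5, 10, 20),
                       subject_id = "synthetic") {
  stopifnot(inherits(cohort, "cohort_config"))
  if (over_threshold_pct <= 0 || any(sensitivity_thresholds <= 0))
    stop_config("thresholds must be positive")
  structure(list(cohort = cohort, output_dir = output_dir,
                 over_threshold_pct = over_threshold_pct,
                 sensitivity_thresholds = sensitivity_thresholds,
                 percentile_variant = "linear-interpolation-type7",
                 subject_id = subject_id),
            class = "run_config")
}

#' Run the full longitudinal disconnectome pipeline
#'
#' Generates (or accepts) a cohort, then per timepoint computes spared /
#' disconnection fractions, weighted and binary connectivity, lesion
#' metrics and loads, and network vulnerability; per transition (every
#' consecutive pair plus first-to-last) classifies edges, counts changes,
#' attributes gains/losses to networks, runs the edge-level
#' substantial-change analysis with its baseline floor, and sweeps the
#' sensitivity thresholds. All tables are written as CSV into
#' `output_dir`, together with a JSON manifest (configuration, seed,
#' package version) from which the entire bundle can be regenerated
#' bit-identically.
#'
#' @param config a [run_config()].
#' @param cohort optionally a pre-generated [generate_cohort()] result;
#'   by default the cohort is generated from `config$cohort`.
#' @return (invisibly) a list with every computed object and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  files <- character()
  emit <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    files <<- c(files, out(name))
  }
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  atlas <- cohort$atlas; masks <- cohort$masks
  healthy <- cohort$healthy
  labels <- names(masks)
  nT <- length(masks)

  # per-timepoint stage
  spared <- lapply(masks, function(m)
    disconnection_fractions(cohort$streamlines, healthy, m))
  weighted <- lapply(spared, function(sp) weight_patient(healthy, sp))
  binary <- lapply(weighted, binarize)
  for (t in seq_len(nT)) {
    for (kind in c("spared", "disconnection", "weighted", "binary")) {
      m <- switch(kind, spared = spared[[t]]$spared,
                  disconnection = spared[[t]]$disconnection,
                  weighted = weighted[[t]], binary = binary[[t]])
      f <- out(sprintf("%s_%s.csv", kind, labels[t]))
      write_connectome_csv(m, f)
      files <- c(files, f)
    }
  }
  metrics <- cbind(subject = config$subject_id, lesion_metrics_table(masks))
  emit(metrics, "lesion_metrics.csv")
  loads <- do.call(rbind, lapply(seq_len(nT), function(t) {
    ld <- lesion_load_by_parcel(masks[[t]], atlas)
    cbind(subject = config$subject_id, timepoint = labels[t], ld$parcels)
  }))
  emit(loads, "lesion_load.csv")
  vuln <- do.call(rbind, lapply(seq_len(nT), function(t) {
    loss <- connectivity_loss(healthy, weighted[[t]])
    cbind(subject = config$subject_id, timepoint = labels[t],
          network_vulnerability(loss, healthy, atlas$network_of))
  }))
  emit(vuln, "vulnerability.csv")

  # per-transition stage
  tr <- default_transitions(nT)
  tr_label <- sprintf("%s_%s", labels[tr[, 1]], labels[tr[, 2]])
  edge_tables <- list(); counts_list <- list(); gains <- list()
  edge_changes <- list(); nets <- list(); sweeps <- list()
  for (r in seq_len(nrow(tr))) {
    a <- tr[r, 1]; b <- tr[r, 2]
    et <- classify_edges(weighted[[a]], weighted[[b]],
                         over_threshold_pct = config$over_threshold_pct)
    edge_tables[[r]] <- et
    counts_list[[r]] <- count_changes(et, binary[[a]])
    gains[[r]] <- rsn_gain_loss(et, atlas$network_of)
    et_out <- et
    et_out$network_i <- atlas$network_of[et$i]
    et_out$network_j <- atlas$network_of[et$j]
    emit(et_out, sprintf("edges_%s.csv", tr_label[r]))
    fl <- baseline_floor(weighted[[a]])
    ec <- classify_persistent(weighted[[a]], weighted[[b]],
                              threshold_pct = config$over_threshold_pct,
                              floor = fl)
    edge_changes[[r]] <- ec
    nets[[r]] <- net_change_by_network(ec, atlas$network_of)
    emit(ec, sprintf("edge_changes_%s_thr%g.csv", tr_label[r],
                     config$over_threshold_pct))
    sweeps[[r]] <- sensitivity_sweep(weighted[[a]], weighted[[b]],
                                     thresholds = config$sensitivity_thresholds,
                                     network_of = atlas$network_of)
  }
  summary_df <- cbind(subject = config$subject_id, transition = tr_label,
                      do.call(rbind, counts_list))
  emit(summary_df, "transitions_summary.csv")
  gain_df <- do.call(rbind, lapply(seq_along(gains), function(r)
    cbind(transition = tr_label[r], gains[[r]])))
  emit(gain_df, "rsn_gain_loss.csv")
  net_df <- do.call(rbind, lapply(seq_along(nets), function(r)
    cbind(transition = tr_label[r], nets[[r]])))
  emit(net_df, "net_change.csv")
  sweep_df <- do.call(rbind, lapply(seq_along(sweeps), function(r)
    cbind(transition = tr_label[r], sweeps[[r]]$net_change)))
  emit(sweep_df, "sensitivity_net_change.csv")
  stab_df <- do.call(rbind, lapply(seq_along(sweeps), function(r)
    cbind(transition = tr_label[r], sweeps[[r]]$stability)))
  emit(stab_df, "sensitivity_stability.csv")
  covar <- lesion_covariate_table(masks, counts_list, tr)
  emit(covar, "lesion_covariates.csv")

  manifest <- list(
    package = "disconnectome",
    package_version = as.character(utils::packageVersion("disconnectome")),
    subject_id = config$subject_id,
    seed = config$cohort$seed,
    over_threshold_pct = config$over_threshold_pct,
    sensitivity_thresholds = config$sensitivity_thresholds,
    percentile_variant = config$percentile_variant,
    cohort = unclass(config$cohort))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, out("manifest.json"))

  invisible(list(config = config, cohort = cohort, spared = spared,
                 weighted = weighted, binary = binary, metrics = metrics,
                 loads = loads, vulnerability = vuln,
                 edge_tables = edge_tables, counts = counts_list,
                 gain_loss = gain_df, net_change = net_df,
                 sweeps = sweeps, covariates = covar, files = files))
}

#' Descriptive clinical side-by-side table
#'
#' Joins per-transition net connectivity changes for selected networks
#' (typically the somatomotor networks) with raw clinical score deltas.
#' Purely descriptive: no association statistic is computed or implied.
#'
#' @param record a [subject_record()] with scores.
#' @param net_changes long data.frame with columns transition, network,
#'   net (as produced by [run_pipeline()]'s `net_change`).
#' @param networks networks to keep (default: all present).
#' @return data.frame with one row per transition x network: net change
#'   and each available scale's delta (later minus earlier; NA where a
#'   score is missing).
#' @export
clinical_sidecar <- function(record, net_changes, networks = NULL) {
  stopifnot(inherits(record, "subject_record"))
  tps <- record$timepoints
  tr <- default_transitions(length(tps))
  tr_label <- sprintf("%s_%s", tps[tr[, 1]], tps[tr[, 2]])
  if (is.null(networks)) networks <- unique(net_changes$network)
  scales <- intersect(c("mrs", "nihss", "bi", "fma_ue"),
                      names(record$scores))
  get_score <- function(sc, tp) {
    if (is.null(record$scores)) return(NA_real_)
    v <- record$scores[[sc]][record$scores$timepoint == tp]
    if (length(v) == 0) NA_real_ else as.numeric(v[1])
  }
  rows <- lapply(seq_len(nrow(tr)), function(r) {
    base <- data.frame(subject = record$subject_id,
                       transition = tr_label[r])
    for (sc in scales)
      base[[paste0("delta_", sc)]] <-
        get_score(sc, tps[tr[r, 2]]) - get_score(sc, tps[tr[r, 1]])
    nc <- net_changes[net_changes$transition == tr_label[r] &
                        net_changes$network %in% networks, , drop = FALSE]
    if (nrow(nc) == 0)
      return(cbind(base, network = NA_character_, net = NA_real_))
    merge(base, nc[, c("transition", "network", "net")], by = "transition")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
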