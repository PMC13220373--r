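#' Published example lesion-volume and clinical-score trajectories
#'
#' Lesion volumes (mm^3) and clinical scores of a published longitudinal
#' case series of four first-time ischemic stroke patients, assessed within
#' one week (S1), at about one month (S2) and at about three months (S3)
#' after onset. The two cortical-stroke patients (P1, P2) have large
#' lesions, the two subcortical (caudate) patients (P3, P4) small ones; P2
#' shows transient volume regrowth between S2 and S3. These tables serve as
#' worked-example inputs for [percent_change()] and [clinical_sidecar()].
#'
#' @return a data.frame (`patient`, `timepoint`, `volume_mm3` for volumes;
#'   `patient`, `timepoint`, `days_post_onset`, `mrs`, `nihss`, `bi`,
#'   `fma_ue` for scores).
#' @export
example_lesion_volumes <- function() {
  utils::read.csv(system.file("extdata", "example_lesion_volumes.csv",
                              package = "disconnectome"))
}

#' @rdname example_lesion_volumes
#' @export
example_clinical_scores <- function() {
  utils::read.csv(system.file("extdata", "example_clinical_scores.csv",
                              package = "disconnectome"))
}
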