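#' Write and read lesion masks and atlases as NIfTI
#'
#' Masks are written as uint8 binary volumes, atlas labels as int16/int32
#' integer volumes, with the isotropic voxel size recorded in the header.
#' Streamline coordinates never pass through NIfTI affines: the package
#' works in the voxel frame throughout, and these helpers only carry the
#' volumes and voxel size.
#'
#' @param mask a [lesion_mask()].
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_lesion_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  img <- RNifti::asNifti(mask$grid,
                         pixdim = rep(mask$voxel_size, 3), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lesion_nifti
#' @param timepoint_label,subject_id metadata for the reconstructed mask.
#' @export
read_lesion_nifti <- function(path, timepoint_label = "S1",
                              subject_id = "unknown") {
  img <- RNifti::readNifti(path)
  lesion_mask(array(as.integer(img > 0), dim = dim(img)),
              voxel_size = RNifti::pixdim(img)[1],
              timepoint_label = timepoint_label, subject_id = subject_id)
}

#' @rdname write_lesion_nifti
#' @param atlas a [parcellation_atlas()].
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  img <- RNifti::asNifti(atlas$labels, pixdim = rep(atlas$voxel_size, 3),
                         datatype = "int32")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lesion_nifti
#' @param network_of parcel-to-network assignment for the read atlas.
#' @export
read_atlas_nifti <- function(path, network_of) {
  img <- RNifti::readNifti(path)
  parcellation_atlas(array(as.integer(img), dim = dim(img)),
                     voxel_size = RNifti::pixdim(img)[1],
                     network_of = network_of)
}

#' Streamline polyline text format
#'
#' A plain whitespace-delimited format: each streamline starts with a
#' header line `# endpoints i j`, followed by one `x y z` line per point
#' (continuous voxel-frame coordinates), with a blank line between
#' streamlines. Coordinates are printed at full double precision.
#'
#' @param streams a [streamline_set()].
#' @param path output text file.
#' @return the path, invisibly.
#' @export
write_streamlines_txt <- function(streams, path) {
  stopifnot(inherits(streams, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in streams$streamlines) {
    writeLines(sprintf("# endpoints %d %d", s$endpoints[1], s$endpoints[2]),
               con)
    writeLines(apply(s$points, 1, function(p)
      paste(sprintf("%.17g", p), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_streamlines_txt
#' @export
read_streamlines_txt <- function(path) {
  lines <- readLines(path)
  sls <- list()
  pts <- NULL
  ep <- NULL
  flush_one <- function() {
    if (!is.null(ep)) {
      if (is.null(pts) || nrow(pts) == 0L)
        stop_validation("streamline block without points in ", path)
      sls[[length(sls) + 1L]] <<- list(points = pts, endpoints = ep)
    }
    pts <<- NULL; ep <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") { flush_one(); next }
    if (startsWith(ln, "#")) {
      flush_one()
      tok <- strsplit(ln, "\\s+")[[1]]
      ep <- as.integer(tok[(length(tok) - 1L):length(tok)])
    } else {
      p <- as.numeric(strsplit(ln, "\\s+")[[1]])
      pts <- rbind(pts, p)
    }
  }
  flush_one()
  streamline_set(sls)
}

#' Connectivity matrix CSV I/O
#'
#' Square matrices are written with parcel ids as both header row and
#' first column, at full double precision, so a round trip is lossless.
#'
#' @param m P x P matrix with parcel-id dimnames.
#' @param path CSV file path.
#' @return the path (write) or the matrix (read).
#' @export
write_connectome_csv <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(parcel = rownames(m), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- colnames(df)[-1]
  storage.mode(m) <- "double"
  m
}
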