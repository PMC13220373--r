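#' @keywords internal
"_PACKAGE"

# Deterministic child seed for a named pipeline stage. Each stage draws from
# its own stream so adding or reordering stages never perturbs the output of
# earlier ones. Result always fits in a 32-bit integer.
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% 2147483647)
}

stop_validation <- function(...) {
  stop(structure(class = c("disconnectome_validation_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("disconnectome_config_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Upper-triangle (i < j) index pairs of a P x P matrix, as a 2-column matrix.
upper_pairs <- function(P) {
  idx <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

check_square_symmetric <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_validation(what, " must be a square matrix")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop_validation(what, " must be symmetric")
  invisible(m)
}

#' Format a percentage for display
#'
#' Rounds to one decimal place and drops a trailing ".0", so 54.01 prints as
#' "54" and 52.74 as "52.7". Stored values are never rounded; this is for
#' report columns only.
#'
#' @param x numeric vector of percentages.
#' @return character vector.
#' @export
format_pct <- function(x) {
  r <- round(x, 1)
  out <- sprintf("%.1f", r)
  sub("\\.0$", "", out)
}
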