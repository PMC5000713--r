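#' Construct a spillover matrix
#'
#' Square matrix over fluorescence channels; `spill[i, j]` is the fraction of
#' fluorochrome `i`'s signal detected in channel `j` (row = source
#' fluorochrome's primary channel, column = detecting channel). The diagonal
#' is 1. Observed intensities relate to true intensities per event by
#' `observed = true %*% spill`; compensation solves this linear system.
#'
#' @param mat square numeric matrix with identical row/column channel names.
#' @return matrix of class `spillover_matrix`.
#' @export
spillover_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("spillover matrix must be square")
  if (is.null(rownames(mat)) || is.null(colnames(mat)) ||
      !identical(rownames(mat), colnames(mat)))
    stop("spillover matrix needs identical channel row and column names")
  if (any(abs(diag(mat) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  if (any(mat < 0)) stop("spillover entries must be >= 0")
  if (abs(det(mat)) < 1e-12) stop("spillover matrix is singular")
  class(mat) <- c("spillover_matrix", "matrix", "array")
  mat
}

#' Default spillover matrix for the 10-color instrument layout
#'
#' A plausible mild spillover pattern between spectrally adjacent detectors of
#' the same laser plus a few cross-laser terms. Purely a simulation default;
#' real acquisitions supply their instrument's matrix.
#'
#' @param channels channel names; default the eight detectors used by the
#'   panel schema.
#' @return a [spillover_matrix()].
#' @export
default_spillover <- function(channels = c("FL1", "FL2", "FL3", "FL4",
                                           "FL6", "FL8", "FL9", "FL10")) {
  n <- length(channels)
  m <- diag(n)
  dimnames(m) <- list(channels, channels)
  # neighboring blue-laser detectors spill into each other
  pairs <- list(c("FL1", "FL2", 0.08), c("FL2", "FL1", 0.02),
                c("FL2", "FL3", 0.05), c("FL3", "FL4", 0.06),
                c("FL4", "FL3", 0.02), c("FL6", "FL8", 0.04),
                c("FL8", "FL6", 0.01), c("FL9", "FL10", 0.05),
                c("FL10", "FL9", 0.02), c("FL3", "FL6", 0.03))
  for (p in pairs) {
    if (p[1] %in% channels && p[2] %in% channels)
      m[p[1], p[2]] <- as.numeric(p[3])
  }
  spillover_matrix(m)
}

#' Identity (no-spill) matrix
#' @param channels channel names.
#' @return a [spillover_matrix()] equal to the identity.
#' @export
identity_spillover <- function(channels) {
  m <- diag(length(channels))
  dimnames(m) <- list(channels, channels)
  spillover_matrix(m)
}

#' Apply spillover compensation to an event table
#'
#' Replaces the fluorescence columns by the solution of
#' `observed = true %*% spill` for every event; scatter and time columns are
#' untouched. Channels of the table absent from the matrix are left as-is.
#'
#' @param table an [event_table()].
#' @param spill a [spillover_matrix()]; its channels must be a subset of the
#'   table's channels.
#' @return the compensated [event_table()].
#' @export
compensate <- function(table, spill) {
  stopifnot(inherits(spill, "spillover_matrix"))
  ch <- rownames(spill)
  missing <- setdiff(ch, colnames(table))
  if (length(missing) > 0L)
    stop("spillover channels absent from table: ", paste(missing, collapse = ", "))
  if (abs(det(unclass(spill))) < 1e-12) stop("spillover matrix is singular")
  obs <- as.matrix(table[, ch, drop = FALSE])
  # observed = true %*% S  =>  true = observed %*% S^-1
  true <- obs %*% solve(unclass(spill))
  out <- table
  out[, ch] <- true
  out
}

#' Read / write a spillover matrix as a labelled plain-text table
#'
#' Tab-separated square table with channel names as both header and first
#' column, editable by hand.
#'
#' @param path file path.
#' @return `read_spillover` returns a [spillover_matrix()];
#'   `write_spillover` invisibly returns `path`.
#' @export
read_spillover <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  spillover_matrix(m)
}

#' @rdname read_spillover
#' @param spill a [spillover_matrix()].
#' @export
write_spillover <- function(spill, path) {
  utils::write.table(as.data.frame(unclass(spill)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
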