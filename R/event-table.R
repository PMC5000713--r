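#' Construct an event table
#'
#' An `event_table` is the package's container for one flow-cytometry
#' acquisition: a data frame with one row per event and columns
#' `TIME` (acquisition seconds), `FSC-INT`, `FSC-TOF`, `FSC-PEAK`, `SSC`
#' (signal area, width, height of the forward scatter plus side scatter)
#' and one column per fluorescence channel (`FL1` ... `FL10`, raw linear
#' intensities in arbitrary digitizer units). Acquisition metadata travel as
#' attributes so the table behaves like a plain data frame everywhere else.
#'
#' @param data data.frame of per-event measurements. Must contain `TIME`,
#'   `FSC-INT`, `FSC-TOF`, `FSC-PEAK`, `SSC`; any further columns are
#'   fluorescence channels.
#' @param panel_id panel identifier, e.g. `"P01"`.
#' @param sample_id free-form sample identifier.
#' @param markers named character vector mapping fluorescence channel names to
#'   marker names, e.g. `c(FL1 = "CD8", FL9 = "CD3")`.
#' @param duration acquisition duration in seconds.
#' @param volume_ul whole-blood volume equivalent of the acquired sample, in
#'   microliters.
#' @param spillover optional spillover matrix (see [spillover_matrix()])
#'   describing the mixing the raw intensities were subjected to.
#' @param truth optional data.frame of per-event hidden ground-truth labels
#'   (simulator bookkeeping; dropped when writing FCS).
#'
#' @return A data.frame of class `event_table`.
#' @seealso [read_fcs()], [write_fcs()], [simulate_panel_acquisition()]
#' @export
event_table <- function(data, panel_id = NA_character_, sample_id = NA_character_,
                        markers = character(), duration = NA_real_,
                        volume_ul = NA_real_, spillover = NULL, truth = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("TIME", "FSC-INT", "FSC-TOF", "FSC-PEAK", "SSC")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L)
    stop("event table is missing required columns: ", paste(missing, collapse = ", "))
  if (!is.null(truth) && nrow(truth) != nrow(data))
    stop("truth table must have one row per event")
  fl <- setdiff(names(data), required)
  bad <- setdiff(names(markers), fl)
  if (length(bad) > 0L)
    stop("marker map refers to channels absent from the table: ",
         paste(bad, collapse = ", "))
  structure(as.data.frame(data),
            panel_id = panel_id, sample_id = sample_id,
            markers = markers, duration = duration, volume_ul = volume_ul,
            spillover = spillover, truth = truth,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d events x %d parameters (panel %s, sample %s)\n",
              nrow(x), ncol(x),
              attr(x, "panel_id"), attr(x, "sample_id")))
  mk <- attr(x, "markers")
  if (length(mk) > 0L)
    cat("  markers:", paste(sprintf("%s=%s", names(mk), mk), collapse = ", "), "\n")
  cat(sprintf("  duration %.1f s, volume %.1f uL\n",
              attr(x, "duration"), attr(x, "volume_ul")))
  invisible(x)
}

#' Fluorescence channel names of an event table
#' @param table an [event_table()].
#' @return character vector of fluorescence channel column names.
#' @export
fl_channels <- function(table) {
  setdiff(colnames(table), c("TIME", "FSC-INT", "FSC-TOF", "FSC-PEAK", "SSC"))
}

#' Per-event hidden ground-truth labels of a simulated acquisition
#' @param table an [event_table()].
#' @return the truth data.frame recorded by the simulator, or `NULL` for
#'   tables that were not simulated (e.g. read from FCS).
#' @export
event_truth <- function(table) attr(table, "truth")

# Resolve a channel reference that may be a raw column name ("SSC", "FL3")
# or a marker name ("CD3") via the table's channel->marker map.
resolve_channel <- function(table, ref) {
  if (ref %in% colnames(table)) return(ref)
  mk <- attr(table, "markers")
  hit <- names(mk)[mk == ref]
  if (length(hit) == 1L) return(hit)
  stop("unknown channel or marker: ", ref)
}
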