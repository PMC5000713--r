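# Universal morphology / acquisition quality gates applied, in every panel,
# before any marker gating: flow stability over time, two-stage doublet
# exclusion, and the All Cells gate separating intact leukocytes from debris
# and dying (FSC-reduced) cells. The published gates are drawn by eye; the
# defaults below are reproducible automated analogues and are all tunable.

#' Quality-control gate configuration
#'
#' @param flow_window flow-stability window length, seconds.
#' @param flow_k exclusion multiplier: a window is discarded when its event
#'   count deviates from the median window count by more than `flow_k` times
#'   the median absolute deviation.
#' @param tof_band half-width of the accepted relative band around the median
#'   `FSC-TOF` (signal width); doublets carry roughly doubled width.
#' @param peak_band half-width of the accepted relative band around the median
#'   `FSC-INT`/`FSC-PEAK` (area/height) ratio; doublets roughly double it.
#' @param fsc_min All Cells lower `FSC-INT` bound separating intact cells from
#'   dying cells and debris (raw units).
#' @param fsc_debris_max events below this `FSC-INT` are classified as debris
#'   rather than dying cells.
#' @param ssc_max upper side-scatter bound of the All Cells gate.
#' @param ssc_pbl_max,ssc_mo_max side-scatter boundaries of the informative
#'   lymphoid (PBL) / monocyte (Mo) / granulocyte (Gr) scatter classes.
#' @param fsc_scale multiplier on the FSC bounds; the uncentrifuged absolute
#'   counting tube shows globally elevated FSC, handled by
#'   `qc_config(fsc_scale = 1.15)` rather than a separate gate set.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(flow_window = 1, flow_k = 5,
                      tof_band = 0.25, peak_band = 0.25,
                      fsc_min = 185000, fsc_debris_max = 80000,
                      ssc_max = Inf, ssc_pbl_max = 30000, ssc_mo_max = 85000,
                      fsc_scale = 1) {
  cfg <- list(flow_window = flow_window, flow_k = flow_k,
              tof_band = tof_band, peak_band = peak_band,
              fsc_min = fsc_min * fsc_scale,
              fsc_debris_max = fsc_debris_max * fsc_scale,
              ssc_max = ssc_max, ssc_pbl_max = ssc_pbl_max,
              ssc_mo_max = ssc_mo_max)
  if (any(vapply(cfg[c("flow_window", "flow_k", "tof_band", "peak_band",
                       "fsc_min", "fsc_debris_max")], function(x) x <= 0, TRUE)))
    stop("qc_config widths and bounds must be positive")
  class(cfg) <- "qc_config"
  cfg
}

#' Flow-stability gate
#'
#' Bins events into fixed time windows and excludes whole windows whose event
#' count is an outlier against the median window count (more than
#' `flow_k` median absolute deviations away). Emulates the visual check of
#' event rate against time used to discard acquisition irregularities such as
#' pressure bursts or clogs.
#'
#' @param table an [event_table()].
#' @param cfg a [qc_config()].
#' @return logical mask, `TRUE` for retained events.
#' @export
flow_gate <- function(table, cfg = qc_config()) {
  n <- nrow(table)
  if (n == 0L) return(logical(0))
  tm <- table[["TIME"]]
  dur <- max(tm) - min(tm)
  if (!is.finite(dur) || dur < cfg$flow_window) {
    warning("acquisition shorter than one flow window; all events kept")
    return(rep(TRUE, n))
  }
  breaks <- seq(min(tm), max(tm) + cfg$flow_window, by = cfg$flow_window)
  win <- findInterval(tm, breaks, rightmost.closed = FALSE)
  counts <- tabulate(win, nbins = length(breaks) - 1L)
  full <- seq_len(length(counts) - 1L)  # last window may be partial
  med <- stats::median(counts[full])
  s <- stats::mad(counts[full])
  if (s == 0) s <- sqrt(max(med, 1))  # Poisson-scale fallback for flat streams
  bad_win <- which(abs(counts - med) > cfg$flow_k * s)
  !(win %in% bad_win)
}

#' Two-stage doublet (singlet) gate
#'
#' Stage one accepts events whose `FSC-TOF` (signal width) lies within a
#' relative band around the median width; summed-transit doublets have about
#' twice the width. Stage two accepts events whose `FSC-INT`/`FSC-PEAK`
#' (area/height) ratio lies within a band around its median; doublets keep a
#' single-cell peak height but doubled area. Bands are medians of the current
#' acquisition, so the gate adapts to the panel's scatter scale.
#'
#' @inheritParams flow_gate
#' @return logical mask, `TRUE` for retained (singlet) events.
#' @export
singlet_gate <- function(table, cfg = qc_config()) {
  n <- nrow(table)
  if (n == 0L) return(logical(0))
  tof <- table[["FSC-TOF"]]
  ratio <- table[["FSC-INT"]] / table[["FSC-PEAK"]]
  m1 <- stats::median(tof)
  keep1 <- abs(tof / m1 - 1) <= cfg$tof_band
  m2 <- stats::median(ratio[keep1])
  keep1 & abs(ratio / m2 - 1) <= cfg$peak_band
}

#' All Cells gate with scatter-class labels
#'
#' Excludes debris (very low FSC) and dying cells (reduced FSC) on the
#' FSC/SSC plane, keeping the intact circulating leukocytes and
#' non-leukocytes. Retained events are additionally labelled by scatter
#' region as `PBL` (small, low complexity), `Mo` (intermediate) or `Gr`
#' (large, high side scatter); the labels are informative only, since subset
#' gating downstream runs on the full All Cells population.
#'
#' @inheritParams flow_gate
#' @return list with elements `mask` (logical; `TRUE` = in All Cells),
#'   `class` (character per event: `"kept"`, `"debris"` or `"lowfsc"`) and
#'   `scatter` (character per event: `"PBL"`, `"Mo"`, `"Gr"` for kept events,
#'   `NA` otherwise).
#' @export
all_cells_gate <- function(table, cfg = qc_config()) {
  n <- nrow(table)
  fsc <- table[["FSC-INT"]]
  ssc <- table[["SSC"]]
  cls <- rep("kept", n)
  cls[fsc < cfg$fsc_min] <- "lowfsc"
  cls[fsc < cfg$fsc_debris_max] <- "debris"
  cls[ssc > cfg$ssc_max] <- "lowfsc"
  mask <- cls == "kept"
  sc <- rep(NA_character_, n)
  sc[mask & ssc < cfg$ssc_pbl_max] <- "PBL"
  sc[mask & ssc >= cfg$ssc_pbl_max & ssc < cfg$ssc_mo_max] <- "Mo"
  sc[mask & ssc >= cfg$ssc_mo_max] <- "Gr"
  list(mask = mask, class = cls, scatter = sc)
}

#' Combined pre-gating quality-control mask
#'
#' Convenience wrapper running [flow_gate()], [singlet_gate()] and
#' [all_cells_gate()] and intersecting their masks, which by construction
#' compose monotonically.
#'
#' @inheritParams flow_gate
#' @return list with `mask` (the intersection), the three component masks,
#'   and the All Cells `class`/`scatter` labels.
#' @export
qc_gates <- function(table, cfg = qc_config()) {
  fg <- flow_gate(table, cfg)
  sg <- singlet_gate(table, cfg)
  ac <- all_cells_gate(table, cfg)
  list(mask = fg & sg & ac$mask, flow = fg, singlet = sg,
       all_cells = ac$mask, class = ac$class, scatter = ac$scatter)
}
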