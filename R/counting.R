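# Bead-based absolute cell enumeration: count the acquired beads per
# fluorescence channel (doublets added twice), average across channels, and
# convert gated cell counts into cells per microliter of blood via
#   (cells acquired / beads acquired) x (beads per tube / blood volume).

#' Count acquired beads per fluorescence channel
#'
#' Identifies bead events inside the FSC-low/SSC-high Beads gate by their
#' positive fluorescence in each configured channel, splits them into
#' singlets and doublets at the valley of the FSC distribution between the
#' two bead modes (fallback: 1.5x the singlet mode), and computes per
#' channel the effective count `singlets + 2 x doublets` plus the mean
#' across channels. The two singlet gates of the cell pipeline are *not*
#' applied to beads — bead doublets must stay countable.
#'
#' @param table a P12 [event_table()].
#' @param config a [diob_config()] supplying the Beads-gate bounds and the
#'   bead positivity cut.
#' @param channels bead fluorescence channels present in the table.
#' @param flow_mask optional logical mask of flow-stable events to count
#'   within (default: all events).
#' @return list of class `bead_count_result`: `per_channel` (data.frame with
#'   `channel`, `singlets`, `doublets`, `effective`), `mean_effective`,
#'   `singlet_fraction` (percent, averaged over channels) and `split_fsc`
#'   (the singlet/doublet FSC threshold used).
#' @export
count_beads <- function(table, config = diob_config(),
                        channels = c("FL1", "FL2", "FL3", "FL4", "FL8"),
                        flow_mask = rep(TRUE, nrow(table))) {
  channels <- intersect(channels, colnames(table))
  if (length(channels) == 0L) stop("no bead channels present in table")
  fsc <- table[["FSC-INT"]]
  ssc <- table[["SSC"]]
  in_gate <- flow_mask & fsc < config$beads_fsc_max & ssc >= config$beads_ssc_min
  if (!any(in_gate))
    stop("no events in the Beads gate; bead counting impossible")

  # singlet/doublet split: valley of the FSC density between the singlet
  # mode (the robust majority) and twice its location
  bead_fsc <- fsc[in_gate]
  m <- stats::median(bead_fsc)
  split <- 1.5 * m
  hi_tail <- bead_fsc[bead_fsc > 1.1 * m & bead_fsc < 3 * m]
  if (length(hi_tail) > 20 && length(bead_fsc) > 200) {
    d <- stats::density(bead_fsc, n = 512, from = 1.1 * m, to = 3 * m)
    sub <- d$x < 2.2 * m
    valley <- d$x[sub][which.min(d$y[sub])]
    if (is.finite(valley) && valley > 1.1 * m) split <- valley
  }

  rows <- lapply(channels, function(chn) {
    pos <- in_gate & table[[chn]] >= config$bead_pos_cut
    s <- sum(pos & fsc < split)
    dbl <- sum(pos & fsc >= split)
    data.frame(channel = chn, singlets = s, doublets = dbl,
               effective = s + 2L * dbl, stringsAsFactors = FALSE)
  })
  per_channel <- do.call(rbind, rows)
  if (all(per_channel$singlets + per_channel$doublets == 0))
    stop("no fluorescent bead events in the Beads gate; bead counting impossible")
  sf <- with(per_channel, 100 * singlets / pmax(singlets + doublets, 1))
  structure(list(per_channel = per_channel,
                 mean_effective = mean(per_channel$effective),
                 singlet_fraction = mean(sf),
                 split_fsc = split),
            class = "bead_count_result")
}

#' @export
print.bead_count_result <- function(x, ...) {
  cat(sprintf("bead_count_result: mean effective %.1f beads (%.2f%% singlets)\n",
              x$mean_effective, x$singlet_fraction))
  print(x$per_channel, row.names = FALSE)
  invisible(x)
}

#' Absolute cell count from the bead formula
#'
#' `cells per uL = (cells acquired / beads acquired) x
#' (beads per tube / blood volume)`.
#'
#' @param cells_acquired gated cell event count.
#' @param beads_acquired acquired bead count (typically the mean effective
#'   count from [count_beads()]).
#' @param beads_per_tube known bead count of the tube lot.
#' @param blood_volume_ul blood volume pipetted into the tube, microliters.
#' @return cells per microliter of blood.
#' @export
absolute_count <- function(cells_acquired, beads_acquired, beads_per_tube,
                           blood_volume_ul) {
  if (any(beads_acquired <= 0)) stop("beads_acquired must be > 0")
  if (any(blood_volume_ul <= 0)) stop("blood_volume_ul must be > 0")
  (cells_acquired / beads_acquired) * (beads_per_tube / blood_volume_ul)
}

#' Transfer absolute counts onto a panel's population statistics
#'
#' Fills the `abs_per_ul` column of a panel's [apply_gate_tree()] statistics
#' from the absolute counts measured in the bead panel: a subset anchored to
#' a major cell type (T, B, NK, Mo, Gr) gets
#' `absolute(major) x pct_major / 100`; populations without a major anchor
#' (DCs, basophils, non-immune cells, and the major-level gates themselves)
#' get `absolute(all leukocytes) x pct_all / 100`.
#'
#' @param stats statistics data.frame from [apply_gate_tree()].
#' @param anchors named character vector mapping the schema's major node ids
#'   to anchor types (`"T"`, `"B"`, `"NK"`, `"Mo"`, `"Gr"`, `"Leu"`), as
#'   stored in each panel schema.
#' @param p12_abs named numeric vector of absolute counts per microliter
#'   with entries `Leu`, `T`, `B`, `NK`, `Mo`, `Gr` (from the bead panel).
#' @return `stats` with `abs_per_ul` filled.
#' @export
propagate_absolute <- function(stats, anchors, p12_abs) {
  if (!"Leu" %in% names(p12_abs))
    stop("p12_abs must provide an all-leukocyte absolute count ('Leu')")
  abs_out <- numeric(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    maj <- stats$major[i]
    if (!is.na(maj) && maj %in% names(anchors)) {
      type <- anchors[[maj]]
      if (!type %in% names(p12_abs))
        stop("missing absolute-count anchor for major type ", type)
      abs_out[i] <- if (type == "Leu")
        p12_abs[["Leu"]] * stats$pct_all[i] / 100
      else
        p12_abs[[type]] * stats$pct_major[i] / 100
    } else {
      abs_out[i] <- p12_abs[["Leu"]] * stats$pct_all[i] / 100
    }
  }
  stats$abs_per_ul <- abs_out
  stats
}
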