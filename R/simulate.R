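# Synthetic whole-blood acquisition engine. Every simulated event carries a
# hidden ground-truth record (population label, per-axis phenotype class,
# artifact flags) so gated statistics can be validated against what was
# planted, at any point of the pipeline.

# all markers the simulator can draw: the assay's marker universe plus any
# marker the profile declares explicitly (unlisted ones default to negative)
known_markers <- function(profile) {
  unique(c(diob_markers(),
           unlist(lapply(profile$populations, function(p) {
             c(names(p$levels), unlist(lapply(p$axes, `[[`, "markers")))
           }))))
}

# Draw marker levels (and axis classes) for `labels`, then raw intensities.
# Returns list(values = n x length(markers) matrix, axes = data.frame).
draw_marker_block <- function(profile, labels, markers) {
  n <- length(labels)
  tpl <- profile$template
  lev <- matrix("neg", nrow = n, ncol = length(markers),
                dimnames = list(NULL, markers))
  axis_names <- unique(unlist(lapply(profile$populations,
                                     function(p) names(p$axes))))
  axes <- as.data.frame(matrix(NA_character_, nrow = n, ncol = length(axis_names),
                               dimnames = list(NULL, axis_names)),
                        stringsAsFactors = FALSE)
  for (pop in unique(labels)) {
    idx <- which(labels == pop)
    pd <- profile$populations[[pop]]
    fixed <- pd$levels[names(pd$levels) %in% markers]
    for (m in names(fixed)) lev[idx, m] <- fixed[[m]]
    for (ax_name in names(pd$axes)) {
      ax <- pd$axes[[ax_name]]
      if (!any(ax$markers %in% markers)) next
      cls <- sample(names(ax$classes), length(idx), replace = TRUE,
                    prob = ax$probs)
      axes[idx, ax_name] <- cls
      for (j in seq_along(ax$markers)) {
        m <- ax$markers[j]
        if (!m %in% markers) next
        lev[idx, m] <- vapply(cls, function(cl) ax$classes[[cl]][j], "")
      }
    }
  }
  loc <- matrix(tpl$locations[lev], nrow = n)
  noise <- if (tpl$sdlog > 0)
    matrix(exp(stats::rnorm(n * length(markers), 0, tpl$sdlog)), nrow = n)
  else 1
  list(values = loc * noise, axes = axes)
}

# scatter block for cell events: FSC-INT/TOF/PEAK/SSC
draw_scatter_block <- function(profile, labels, dead, fsc_shift = 1) {
  n <- length(labels)
  sc <- profile$scatter
  cls <- vapply(profile$populations[labels], `[[`, "", "scatter")
  locs <- t(vapply(sc$locations[cls], identity, c(fsc = 0, ssc = 0)))
  for (pop in unique(labels)) {
    ov <- profile$populations[[pop]]$scatter_override
    if (!is.null(ov)) {
      idx <- labels == pop
      for (k in names(ov)) locs[idx, k] <- ov[[k]]
    }
  }
  rln <- function(loc, sdlog) {
    if (sdlog > 0) loc * exp(stats::rnorm(n, 0, sdlog)) else loc
  }
  fsc <- rln(locs[, "fsc"], sc$fsc_sdlog) * fsc_shift
  fsc[dead] <- fsc[dead] * profile$dead_fsc_factor
  ssc <- rln(locs[, "ssc"], sc$ssc_sdlog)
  u <- if (sc$tof_sdlog > 0) exp(stats::rnorm(n, 0, sc$tof_sdlog)) else rep(1, n)
  data.frame(`FSC-INT` = fsc, `FSC-TOF` = sc$tof_location * u,
             `FSC-PEAK` = fsc / u, SSC = ssc, check.names = FALSE)
}

draw_debris_block <- function(profile, n, markers, fsc_shift = 1) {
  sc <- profile$scatter
  rln <- function(loc, sdlog) {
    if (sdlog > 0) loc * exp(stats::rnorm(n, 0, sdlog)) else rep(loc, n)
  }
  fsc <- rln(sc$debris[["fsc"]], sc$debris_sdlog) * fsc_shift
  u <- if (sc$tof_sdlog > 0) exp(stats::rnorm(n, 0, sc$tof_sdlog)) else rep(1, n)
  tpl <- profile$template
  noise <- if (tpl$sdlog > 0)
    matrix(exp(stats::rnorm(n * length(markers), 0, tpl$sdlog)), nrow = n)
  else 1
  list(scatter = data.frame(`FSC-INT` = fsc, `FSC-TOF` = sc$tof_location * u,
                            `FSC-PEAK` = fsc / u,
                            SSC = rln(sc$debris[["ssc"]], sc$debris_sdlog),
                            check.names = FALSE),
       values = matrix(tpl$locations[["neg"]], n, length(markers)) * noise)
}

draw_times <- function(profile, n) {
  D <- profile$duration
  b <- profile$burst
  if (is.null(b)) return(stats::runif(n, 0, D))
  d <- min(b$duration, D - b$start)
  w <- b$rate * d / ((D - d) + b$rate * d)  # fraction of events in the burst
  in_burst <- stats::runif(n) < w
  tm <- numeric(n)
  tm[in_burst] <- stats::runif(sum(in_burst), b$start, b$start + d)
  out <- stats::runif(sum(!in_burst), 0, D - d)
  out[out >= b$start] <- out[out >= b$start] + d
  tm[!in_burst] <- out
  tm
}

panel_stream_seed <- function(seed, panel_id) {
  idx <- suppressWarnings(as.integer(sub("^P", "", panel_id)))
  if (is.na(idx)) idx <- 99L
  (as.integer(seed) * 1000L + idx) %% 2147483647L
}

#' Simulate one panel's whole-blood acquisition
#'
#' Generates an [event_table()] of `n_events` rows for one staining panel:
#' leukocyte singlets drawn from the profile's leaf populations, plus the
#' configured fractions of debris, FSC-reduced dead cells and constructed
#' doublets (sum of two singlets' integral signals, summed time-of-flight,
#' maximum peak). Raw fluorescence intensities are mixed through the
#' profile's spillover matrix. Event times are uniform over the acquisition
#' unless a burst artifact is configured (see [with_burst()]). Deterministic
#' given `(profile, panel, n_events, seed)`; each panel derives its own
#' random substream from the seed, so adding or dropping a panel never
#' changes another panel's events.
#'
#' @param profile a [build_default_profile()] profile.
#' @param panel a panel schema (see [build_diob_schema()]).
#' @param n_events number of events to acquire.
#' @param seed master seed.
#' @return an [event_table()] with hidden per-event truth (see
#'   [event_truth()]): `artifact` (`"cell"`, `"debris"`, `"doublet"`),
#'   `dead`, `label`, and one column per phenotype axis.
#' @export
simulate_panel_acquisition <- function(profile, panel, n_events, seed = 1L) {
  stopifnot(n_events > 0)
  markers <- unname(panel$channels)
  unknown <- setdiff(markers, known_markers(profile))
  if (length(unknown) > 0L)
    stop("configuration error: marker(s) not templated in profile: ",
         paste(unknown, collapse = ", "))
  set.seed(panel_stream_seed(seed, panel$id))
  fsc_shift <- if (is.null(panel$fsc_shift)) 1 else panel$fsc_shift

  probs <- c(cell = 1 - profile$debris_fraction - profile$doublet_fraction,
             debris = profile$debris_fraction,
             doublet = profile$doublet_fraction)
  kind <- sample(names(probs), n_events, replace = TRUE, prob = probs)
  n_cell <- sum(kind == "cell")
  n_debris <- sum(kind == "debris")
  n_doublet <- sum(kind == "doublet")

  freqs <- population_frequencies(profile)
  pool_n <- n_cell + 2L * n_doublet
  labels <- sample(names(freqs), pool_n, replace = TRUE, prob = freqs)
  dead <- c(stats::runif(n_cell) < profile$dead_fraction,
            rep(FALSE, 2L * n_doublet))
  mk <- draw_marker_block(profile, labels, markers)
  sc <- draw_scatter_block(profile, labels, dead, fsc_shift)

  i_single <- seq_len(n_cell)
  i1 <- n_cell + seq_len(n_doublet)
  i2 <- n_cell + n_doublet + seq_len(n_doublet)

  scatter <- rbind(
    sc[i_single, , drop = FALSE],
    if (n_doublet > 0) data.frame(
      `FSC-INT` = sc[i1, "FSC-INT"] + sc[i2, "FSC-INT"],
      `FSC-TOF` = sc[i1, "FSC-TOF"] + sc[i2, "FSC-TOF"],
      `FSC-PEAK` = pmax(sc[i1, "FSC-PEAK"], sc[i2, "FSC-PEAK"]),
      SSC = sc[i1, "SSC"] + sc[i2, "SSC"], check.names = FALSE),
    NULL)
  values <- rbind(mk$values[i_single, , drop = FALSE],
                  if (n_doublet > 0)
                    mk$values[i1, , drop = FALSE] + mk$values[i2, , drop = FALSE])
  truth <- data.frame(
    artifact = c(rep("cell", n_cell), rep("doublet", n_doublet)),
    dead = c(dead[i_single], rep(FALSE, n_doublet)),
    label = c(labels[i_single], rep(NA_character_, n_doublet)),
    stringsAsFactors = FALSE)
  if (ncol(mk$axes) > 0) {
    ax_na <- mk$axes[i1, , drop = FALSE]
    if (nrow(ax_na) > 0) ax_na[] <- NA_character_
    truth <- cbind(truth, rbind(mk$axes[i_single, , drop = FALSE], ax_na))
  }

  if (n_debris > 0) {
    db <- draw_debris_block(profile, n_debris, markers, fsc_shift)
    scatter <- rbind(scatter, db$scatter)
    values <- rbind(values, db$values)
    tr_db <- data.frame(artifact = rep("debris", n_debris), dead = FALSE,
                        label = NA_character_, stringsAsFactors = FALSE)
    for (axn in setdiff(names(truth), names(tr_db)))
      tr_db[[axn]] <- NA_character_
    truth <- rbind(truth, tr_db[, names(truth), drop = FALSE])
  }

  # spillover mixing over the panel's channels
  spill <- profile$spillover
  ch <- names(panel$channels)
  sub <- unclass(spill)[intersect(ch, rownames(spill)),
                        intersect(ch, rownames(spill)), drop = FALSE]
  full <- diag(length(ch)); dimnames(full) <- list(ch, ch)
  full[rownames(sub), colnames(sub)] <- sub
  observed <- values %*% full

  tm <- draw_times(profile, nrow(scatter))
  ord <- order(tm)
  df <- cbind(data.frame(TIME = tm, check.names = FALSE), scatter,
              as.data.frame(observed) |> stats::setNames(ch))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  event_table(df, panel_id = panel$id, sample_id = sprintf("sim-seed%d", seed),
              markers = panel$channels, duration = profile$duration,
              volume_ul = panel$volume_ul,
              spillover = spillover_matrix(full), truth = truth)
}

#' Simulate the bead-spiked absolute-counting acquisition
#'
#' Mixes leukocyte events (stained for CD45, CD3, CD19/CD20, CD16, CD56)
#' with counting-bead events. The number of cell events follows the
#' profile's true leukocyte concentration times the blood volume and the
#' acquired fraction of the tube; expected acquired beads are
#' `beads_per_tube * acquired_fraction`. Beads sit at FSC-low/SSC-high
#' scatter and emit in the five configured channels; bead doublets appear at
#' the configured rate with doubled FSC and intensity. Cells (but not beads)
#' show the elevated FSC of an uncentrifuged sample. The profile's true
#' cells-per-microliter for all majors is recorded in the truth attributes.
#'
#' @param profile a profile.
#' @param config a [bead_config()].
#' @param acquired_fraction fraction of the tube volume actually acquired,
#'   in (0, 1].
#' @param seed master seed.
#' @return an [event_table()]; `attr(, "true_abs")` holds the ground-truth
#'   absolute counts and `event_truth()` the per-event labels (artifacts
#'   `"cell"`, `"doublet"`, `"debris"`, `"bead"`, `"bead_doublet"`).
#' @export
simulate_trucount_acquisition <- function(profile, config = bead_config(),
                                          acquired_fraction = 1, seed = 1L) {
  stopifnot(inherits(config, "bead_config"),
            acquired_fraction > 0, acquired_fraction <= 1)
  set.seed(panel_stream_seed(seed, "P12"))
  fsc_shift <- 1.15

  channels <- c(FL1 = "CD19_20", FL2 = "CD16", FL3 = "CD56", FL4 = "CD45",
                FL9 = "CD3")
  all_ch <- union(names(channels), config$channels)
  markers <- unname(channels)

  n_cells_total <- round(profile$leukocytes_per_ul * config$blood_volume_ul *
                           acquired_fraction)
  d <- profile$trucount_doublet_fraction
  n_cell_events <- round(n_cells_total / (1 + d))
  n_doublet <- round(n_cell_events * d)
  n_single <- n_cell_events - n_doublet
  # no wash steps in the counting tube: debris is ~5x the washed-panel rate
  n_debris <- round(5 * profile$debris_fraction * n_cell_events)

  freqs <- population_frequencies(profile)
  pool_n <- n_single + 2L * n_doublet
  labels <- sample(names(freqs), pool_n, replace = TRUE, prob = freqs)
  dead <- c(stats::runif(n_single) < profile$dead_fraction,
            rep(FALSE, 2L * n_doublet))
  mk <- draw_marker_block(profile, labels, markers)
  sc <- draw_scatter_block(profile, labels, dead, fsc_shift)
  # widen to all channels; unstained channels are background
  bg <- profile$template$locations[["neg"]]
  vals <- matrix(bg, nrow = pool_n, ncol = length(all_ch),
                 dimnames = list(NULL, all_ch))
  if (profile$template$sdlog > 0)
    vals <- vals * exp(stats::rnorm(length(vals), 0, profile$template$sdlog))
  vals[, names(channels)] <- mk$values

  i_single <- seq_len(n_single)
  i1 <- n_single + seq_len(n_doublet)
  i2 <- n_single + n_doublet + seq_len(n_doublet)
  scatter <- rbind(
    sc[i_single, , drop = FALSE],
    if (n_doublet > 0) data.frame(
      `FSC-INT` = sc[i1, "FSC-INT"] + sc[i2, "FSC-INT"],
      `FSC-TOF` = sc[i1, "FSC-TOF"] + sc[i2, "FSC-TOF"],
      `FSC-PEAK` = pmax(sc[i1, "FSC-PEAK"], sc[i2, "FSC-PEAK"]),
      SSC = sc[i1, "SSC"] + sc[i2, "SSC"], check.names = FALSE),
    NULL)
  values <- rbind(vals[i_single, , drop = FALSE],
                  if (n_doublet > 0)
                    vals[i1, , drop = FALSE] + vals[i2, , drop = FALSE])
  artifact <- c(rep("cell", n_single), rep("doublet", n_doublet))
  label <- c(labels[i_single], rep(NA_character_, n_doublet))
  dead_out <- c(dead[i_single], rep(FALSE, n_doublet))

  if (n_debris > 0) {
    db <- draw_debris_block(profile, n_debris, all_ch, fsc_shift)
    scatter <- rbind(scatter, db$scatter)
    values <- rbind(values, db$values)
    artifact <- c(artifact, rep("debris", n_debris))
    label <- c(label, rep(NA_character_, n_debris))
    dead_out <- c(dead_out, rep(FALSE, n_debris))
  }

  # beads: doublet_rate is the fraction of bead events that are doublets
  n_beads <- round(config$beads_per_tube * acquired_fraction)
  nd_b <- round(n_beads * config$doublet_rate / (1 + config$doublet_rate))
  ns_b <- n_beads - 2L * nd_b
  n_bead_events <- ns_b + nd_b
  if (n_bead_events > 0) {
    mult <- c(rep(1, ns_b), rep(2, nd_b))
    rln <- function(n, loc, sdlog) loc * exp(stats::rnorm(n, 0, sdlog))
    bfsc <- rln(n_bead_events, config$fsc, config$fsc_sdlog) * mult
    u <- exp(stats::rnorm(n_bead_events, 0, profile$scatter$tof_sdlog))
    bead_sc <- data.frame(
      `FSC-INT` = bfsc,
      `FSC-TOF` = profile$scatter$tof_location * u * mult,
      `FSC-PEAK` = (bfsc / mult) / u,
      SSC = rln(n_bead_events, config$ssc, config$fsc_sdlog),
      check.names = FALSE)
    bead_vals <- matrix(bg, nrow = n_bead_events, ncol = length(all_ch),
                        dimnames = list(NULL, all_ch))
    for (chn in config$channels)
      bead_vals[, chn] <- rln(n_bead_events, config$intensity,
                              config$intensity_sdlog) * mult
    scatter <- rbind(scatter, bead_sc)
    values <- rbind(values, bead_vals)
    artifact <- c(artifact, rep("bead", ns_b), rep("bead_doublet", nd_b))
    label <- c(label, rep(NA_character_, n_bead_events))
    dead_out <- c(dead_out, rep(FALSE, n_bead_events))
  }

  spill <- profile$spillover
  sub <- unclass(spill)[intersect(all_ch, rownames(spill)),
                        intersect(all_ch, rownames(spill)), drop = FALSE]
  full <- diag(length(all_ch)); dimnames(full) <- list(all_ch, all_ch)
  full[rownames(sub), colnames(sub)] <- sub
  observed <- values %*% full

  tm <- draw_times(profile, nrow(scatter))
  ord <- order(tm)
  df <- cbind(data.frame(TIME = tm), scatter,
              as.data.frame(observed) |> stats::setNames(all_ch))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  truth <- data.frame(artifact = artifact, dead = dead_out, label = label,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(truth) <- NULL
  tab <- event_table(df, panel_id = "P12", sample_id = sprintf("sim-seed%d", seed),
                     markers = channels, duration = profile$duration,
                     volume_ul = config$blood_volume_ul * acquired_fraction,
                     spillover = spillover_matrix(full), truth = truth)
  attr(tab, "true_abs") <- true_absolute_counts(profile)
  attr(tab, "bead_config") <- config
  attr(tab, "acquired_fraction") <- acquired_fraction
  tab
}

#' Remove all stochastic nuisance from a profile
#'
#' Sets template and scatter spreads to zero, removes debris, dead cells and
#' doublets, and replaces the spillover matrix by the identity. Events then
#' sit exactly at their template locations — the configuration used for
#' exact-recovery tests.
#'
#' @param profile a profile.
#' @param keep_spillover keep the spillover matrix (compensation must then
#'   undo it exactly).
#' @return the stripped profile.
#' @export
zero_noise_profile <- function(profile = build_default_profile(),
                               keep_spillover = FALSE) {
  profile$template$sdlog <- 0
  profile$scatter$fsc_sdlog <- 0
  profile$scatter$ssc_sdlog <- 0
  profile$scatter$tof_sdlog <- 0
  profile$scatter$debris_sdlog <- 0
  profile$dead_fraction <- 0
  profile$debris_fraction <- 0
  profile$doublet_fraction <- 0
  profile$trucount_doublet_fraction <- 0
  if (!keep_spillover)
    profile$spillover <- identity_spillover(rownames(profile$spillover))
  profile
}
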