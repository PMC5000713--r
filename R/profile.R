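# Ground-truth profile for the whole-blood simulator.
#
# The profile fixes, for every leaf population of circulating cells: its
# frequency among all intact leukocytes, its scatter class, and its marker
# phenotype. Phenotypes combine fixed levels (neg/lo/pos/hi) with "axes":
# joint categorical draws over groups of markers (memory phenotype, chemokine
# receptors, activation markers ...) whose per-event outcome is recorded as
# hidden truth, so any gated statistic can be checked against what was
# actually planted.

#' Marker-level intensity template
#'
#' Raw-intensity central values for the four expression levels used by the
#' phenotype notation (neg / lo / pos / hi), shared by all markers, plus the
#' lognormal shape parameter of the per-event spread around them. Locations
#' must be strictly increasing in level. Values are linear digitizer units on
#' the default 20-bit scale.
#'
#' @param locations named numeric, central raw intensity per level.
#' @param sdlog lognormal shape (sd of log intensity) around the location;
#'   `0` gives noise-free template draws.
#' @return list of class `marker_template`.
#' @export
marker_template <- function(locations = c(neg = 50, lo = 4000,
                                          pos = 20000, hi = 150000),
                            sdlog = 0.25) {
  stopifnot(all(c("neg", "lo", "pos", "hi") %in% names(locations)))
  if (!(locations["neg"] < locations["lo"] &&
        locations["lo"] < locations["pos"] &&
        locations["pos"] < locations["hi"]))
    stop("template locations must satisfy neg < lo < pos < hi")
  if (sdlog < 0) stop("template spread must be >= 0")
  structure(list(locations = locations, sdlog = sdlog),
            class = "marker_template")
}

# joint categorical axis over a group of markers
pop_axis <- function(markers, classes, probs) {
  stopifnot(length(classes) == length(probs), abs(sum(probs) - 1) < 1e-9)
  stopifnot(all(vapply(classes, length, 0L) == length(markers)))
  list(markers = markers, classes = classes, probs = probs)
}

# single-marker Bernoulli axis: positive with probability p, else negative
act_axis <- function(marker, p, pos_level = "pos") {
  pop_axis(marker,
           classes = stats::setNames(list(pos_level, "neg"),
                                     c(paste0(marker, "+"), paste0(marker, "-"))),
           probs = c(p, 1 - p))
}

pop_def <- function(freq, scatter, levels, axes = list(), major = NA_character_,
                    scatter_override = NULL) {
  list(freq = freq, scatter = scatter, levels = levels, axes = axes,
       major = major, scatter_override = scatter_override)
}

#' Default ground-truth profile of fresh whole blood
#'
#' Leaf-population frequencies sit at the midpoints of the ranges reported
#' for healthy donors: T cells ~25% of leukocytes (second most common), B
#' cells ~5%, NK cells ~4% with the CD56lo/CD16+ subset near 90% of NK,
#' monocytes ~8% with the CD14hi/CD16- subset at ~85%, dendritic cells <1%,
#' basophils ~1%, neutrophils the remainder (~52%), eosinophils ~3%, and
#' HSC/EPC/CEC together ~0.01%. Dead (FSC-reduced) cells default to 0.6% of
#' cell events, debris to 2%, cell doublets to 2%.
#'
#' Marker phenotypes implement the subset definitions of the assay (see
#' [subset_definitions()]); activation markers are Bernoulli axes with
#' plausible resting-state positive fractions. All intensity distributions
#' are simulation defaults, not measured claims.
#'
#' @param seed integer stored with the profile; per-acquisition substreams
#'   are derived from it so that simulating one panel never perturbs another.
#' @param template a [marker_template()].
#' @param spillover a [spillover_matrix()] mixed into every simulated
#'   acquisition.
#' @param leukocytes_per_ul true leukocyte concentration of the simulated
#'   donor, cells per microliter.
#' @param dead_fraction,debris_fraction,doublet_fraction artifact rates
#'   (fractions of cell events / all events).
#' @param trucount_doublet_fraction cell-doublet fraction in the
#'   uncentrifuged absolute-counting tube (more dilute, fewer coincidences).
#' @return list of class `ground_truth_profile`.
#' @export
build_default_profile <- function(seed = 1L,
                                  template = marker_template(),
                                  spillover = default_spillover(),
                                  leukocytes_per_ul = 6000,
                                  dead_fraction = 0.006,
                                  debris_fraction = 0.02,
                                  doublet_fraction = 0.02,
                                  trucount_doublet_fraction = 0.01) {
  stopifnot(dead_fraction >= 0, dead_fraction < 1,
            debris_fraction >= 0, debris_fraction < 1,
            doublet_fraction >= 0, doublet_fraction < 1)

  t_common <- c(CD3 = "pos", CD45 = "hi", LIN = "pos",
                TCRab = "pos", TCRgd = "neg", CD127 = "pos")
  mem_axis <- function(p) pop_axis(
    c("CD197", "CD45RA"),
    classes = list(naive = c("pos", "pos"), eff = c("neg", "pos"),
                   em = c("neg", "neg"), cm = c("pos", "neg")),
    probs = p)
  t_act <- function(cd38 = 0.30) list(
    cd38 = act_axis("CD38", cd38), cd69 = act_axis("CD69", 0.05),
    cd80 = act_axis("CD80", 0.02), cd86 = act_axis("CD86", 0.03),
    hladr = act_axis("HLADR", 0.08), cd279 = act_axis("CD279", 0.15),
    cd152 = act_axis("CD152", 0.05))
  th_axes <- c(list(
    mem = mem_axis(c(0.35, 0.10, 0.30, 0.25)),
    chem = pop_axis(c("CD183", "CD196"),
                    classes = list(th1 = c("pos", "neg"), th2 = c("neg", "neg"),
                                   th17 = c("neg", "pos"), th1_17 = c("pos", "pos")),
                    probs = c(0.30, 0.35, 0.15, 0.20)),
    treg = pop_axis(c("CD25", "CD127"),
                    classes = list(treg = c("hi", "neg"), act = c("pos", "pos"),
                                   conv = c("neg", "pos")),
                    probs = c(0.06, 0.08, 0.86))),
    t_act(0.30))
  tc_axes <- c(list(mem = mem_axis(c(0.25, 0.20, 0.35, 0.20)),
                    cd25 = act_axis("CD25", 0.06)),
               t_act(0.35))

  b_common <- c(CD19 = "pos", CD20 = "pos", CD19_20 = "pos", CD45 = "hi",
                LIN = "pos", HLADR = "pos")
  b_axes <- list(cd25 = act_axis("CD25", 0.05), cd69 = act_axis("CD69", 0.03),
                 cd80 = act_axis("CD80", 0.10), cd86 = act_axis("CD86", 0.15))
  b_pop <- function(freq, CD27, CD38, CD5, CD24, extra = c()) {
    pop_def(freq, "PBL",
            c(b_common, CD27 = CD27, CD38 = CD38, CD5 = CD5, CD24 = CD24, extra),
            b_axes, major = "B")
  }

  nk_common <- c(CD3 = "neg", CD45 = "hi", LIN = "pos")
  nk_axes <- list(
    cd314 = act_axis("CD314", 0.85),
    nkr = pop_axis(c("CD94", "CD159a", "CD159c"),
                   classes = list(nkg2a = c("pos", "pos", "neg"),
                                  nkg2c = c("pos", "neg", "pos"),
                                  cd94only = c("pos", "neg", "neg"),
                                  none = c("neg", "neg", "neg")),
                   probs = c(0.40, 0.15, 0.15, 0.30)),
    cd25 = act_axis("CD25", 0.04), cd69 = act_axis("CD69", 0.06))

  mo_common <- c(CD45 = "hi", LIN = "pos")
  mo_axes <- function(hladr = c(0.05, 0.70, 0.25)) list(
    cd80 = act_axis("CD80", 0.02),
    cd86 = pop_axis("CD86", classes = list(neg = "neg", pos = "pos", hi = "hi"),
                    probs = c(0.05, 0.70, 0.25)),
    cd64 = pop_axis("CD64", classes = list(neg = "neg", pos = "pos", hi = "hi"),
                    probs = c(0.05, 0.65, 0.30)),
    hladr = pop_axis("HLADR", classes = list(neg = "neg", pos = "pos", hi = "hi"),
                     probs = hladr))

  dc_axes <- list(cd83 = act_axis("CD83", 0.10), cd274 = act_axis("CD274", 0.15))

  pops <- list(
    # --- T cells (~26% of leukocytes incl. NKT) -------------------------
    TH = pop_def(0.150, "PBL", c(t_common, CD4 = "hi", CD8 = "neg"),
                 th_axes, major = "T"),
    TC8hi = pop_def(0.055, "PBL", c(t_common, CD4 = "neg", CD8 = "hi"),
                    tc_axes, major = "T"),
    TC8lo = pop_def(0.008, "PBL", c(t_common, CD4 = "neg", CD8 = "lo"),
                    tc_axes, major = "T"),
    DNT = pop_def(0.015, "PBL",
                  c(t_common[setdiff(names(t_common), c("TCRab", "TCRgd"))],
                    CD4 = "neg", CD8 = "neg"),
                  c(list(tcr = pop_axis(c("TCRab", "TCRgd"),
                                        classes = list(ab = c("pos", "neg"),
                                                       gd = c("neg", "pos")),
                                        probs = c(0.3, 0.7)),
                         mem = mem_axis(c(0.2, 0.2, 0.4, 0.2))),
                    t_act(0.3)),
                  major = "T"),
    DPT = pop_def(0.005, "PBL", c(t_common, CD4 = "hi", CD8 = "hi"),
                  c(list(mem = mem_axis(c(0.3, 0.1, 0.4, 0.2))), t_act(0.3)),
                  major = "T"),
    T4lo = pop_def(0.004, "PBL", c(t_common, CD4 = "lo", CD8 = "neg"),
                   t_act(0.3), major = "T"),
    T4hi8lo = pop_def(0.004, "PBL", c(t_common, CD4 = "hi", CD8 = "lo"),
                      t_act(0.3), major = "T"),
    T8hi4lo = pop_def(0.004, "PBL", c(t_common, CD4 = "lo", CD8 = "hi"),
                      t_act(0.3), major = "T"),
    NKT = pop_def(0.015, "PBL", c(t_common, CD4 = "neg", CD8 = "hi"),
                  c(list(mem = mem_axis(c(0.05, 0.30, 0.50, 0.15)),
                         nk = pop_axis(c("CD56", "CD16", "CD314", "CD94",
                                         "CD159a", "CD159c"),
                                       classes = list(
                                         cd56 = c("pos", "neg", "pos", "pos", "pos", "neg"),
                                         cd16 = c("neg", "pos", "pos", "neg", "neg", "neg"),
                                         cd314 = c("neg", "neg", "pos", "neg", "neg", "neg"),
                                         cd94 = c("neg", "neg", "neg", "pos", "pos", "neg")),
                                       probs = c(0.45, 0.25, 0.20, 0.10))),
                    t_act(0.35)),
                  major = "T"),
    # --- B cells (5%) ----------------------------------------------------
    Bnaive = b_pop(0.0300, CD27 = "neg", CD38 = "lo", CD5 = "neg", CD24 = "pos"),
    Bmemory = b_pop(0.0125, CD27 = "pos", CD38 = "lo", CD5 = "neg", CD24 = "pos"),
    Bprenaive = b_pop(0.0020, CD27 = "neg", CD38 = "lo", CD5 = "pos", CD24 = "pos"),
    Btransitional = b_pop(0.0020, CD27 = "neg", CD38 = "hi", CD5 = "pos", CD24 = "hi"),
    Bplasmablast = pop_def(0.0010, "PBL",
                           c(b_common[setdiff(names(b_common), "CD20")],
                             CD20 = "neg", CD27 = "pos", CD38 = "hi",
                             CD5 = "neg", CD24 = "neg"),
                           b_axes, major = "B"),
    Breg = b_pop(0.0015, CD27 = "pos", CD38 = "lo", CD5 = "pos", CD24 = "hi"),
    Brest = b_pop(0.0010, CD27 = "pos", CD38 = "hi", CD5 = "pos", CD24 = "pos"),
    # --- NK cells (4%; NK1 ~90% of NK) ----------------------------------
    NK1 = pop_def(0.0360, "PBL", c(nk_common, CD56 = "lo", CD16 = "pos"),
                  nk_axes, major = "NK"),
    NK2 = pop_def(0.0024, "PBL", c(nk_common, CD56 = "hi", CD16 = "neg"),
                  nk_axes, major = "NK"),
    NK3 = pop_def(0.0016, "PBL", c(nk_common, CD56 = "lo", CD16 = "neg"),
                  nk_axes, major = "NK"),
    # --- Monocytes (8%; Mo1 ~85% of Mo) ---------------------------------
    Mo1 = pop_def(0.0680, "Mo", c(mo_common, CD14 = "hi", CD16 = "neg"),
                  mo_axes(), major = "Mo"),
    Mo2 = pop_def(0.0040, "Mo", c(mo_common, CD14 = "lo", CD16 = "pos"),
                  mo_axes(), major = "Mo"),
    Mo3 = pop_def(0.0048, "Mo", c(mo_common, CD14 = "hi", CD16 = "pos"),
                  mo_axes(), major = "Mo"),
    Mo4 = pop_def(0.0032, "Mo", c(mo_common, CD14 = "lo", CD16 = "neg"),
                  mo_axes(hladr = c(0.60, 0.35, 0.05)), major = "Mo"),
    # --- Granulocytes ----------------------------------------------------
    Neu = pop_def(0.5219, "Gr", c(CD45 = "hi", LIN = "pos", CD66 = "pos",
                                  CD16 = "pos"),
                  list(cd64 = act_axis("CD64", 0.10)), major = "Gr"),
    Eos = pop_def(0.0300, "Gr", c(CD45 = "hi", LIN = "neg", CD66 = "pos",
                                  CD16 = "neg"),
                  list(cd64 = act_axis("CD64", 0.05)), major = "Gr"),
    Baso = pop_def(0.0100, "PBL", c(CD45 = "hi", LIN = "neg", HLADR = "neg",
                                    CD123 = "pos"),
                   list(), major = "Leu",
                   scatter_override = c(ssc = 20000)),
    # --- Dendritic cells (<1%) ------------------------------------------
    pDC = pop_def(0.0030, "PBL", c(CD45 = "hi", LIN = "neg", HLADR = "pos",
                                   CD123 = "hi", CD11c = "neg"),
                  dc_axes, major = "Leu"),
    mDC1 = pop_def(0.0040, "PBL", c(CD45 = "hi", LIN = "neg", HLADR = "pos",
                                    CD11c = "hi", CD123 = "neg", CD1c = "pos"),
                   dc_axes, major = "Leu"),
    mDC2 = pop_def(0.0010, "PBL", c(CD45 = "hi", LIN = "neg", HLADR = "pos",
                                    CD11c = "hi", CD123 = "neg", CD1c = "neg"),
                   dc_axes, major = "Leu"),
    # --- Non-immune cells (~0.01% together) -----------------------------
    HSC133p = pop_def(0.00002, "nonleuk",
                      c(CD45 = "lo", CD34 = "pos", CD133 = "pos", CD146 = "neg"),
                      list(), major = "Leu"),
    HSC133n = pop_def(0.00003, "nonleuk",
                      c(CD45 = "lo", CD34 = "pos", CD133 = "neg", CD146 = "neg"),
                      list(), major = "Leu"),
    EPC45p = pop_def(0.000015, "nonleuk",
                     c(CD45 = "pos", CD34 = "neg", CD133 = "pos", CD146 = "neg"),
                     list(), major = "Leu"),
    EPC45n = pop_def(0.000015, "nonleuk",
                     c(CD45 = "neg", CD34 = "neg", CD133 = "pos", CD146 = "neg"),
                     list(), major = "Leu"),
    CEC = pop_def(0.00002, "nonleuk",
                  c(CD45 = "neg", CD34 = "neg", CD133 = "neg", CD146 = "pos"),
                  list(), major = "Leu")
  )

  freqs <- vapply(pops, `[[`, 0, "freq")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("internal error: leaf frequencies sum to ", sum(freqs))

  profile <- list(
    seed = as.integer(seed),
    populations = pops,
    template = template,
    spillover = spillover,
    leukocytes_per_ul = leukocytes_per_ul,
    dead_fraction = dead_fraction,
    debris_fraction = debris_fraction,
    doublet_fraction = doublet_fraction,
    trucount_doublet_fraction = trucount_doublet_fraction,
    dead_fsc_factor = 0.5,
    scatter = list(
      locations = list(PBL = c(fsc = 250000, ssc = 12000),
                       Mo = c(fsc = 320000, ssc = 45000),
                       Gr = c(fsc = 350000, ssc = 150000),
                       nonleuk = c(fsc = 250000, ssc = 12000)),
      fsc_sdlog = 0.05, ssc_sdlog = 0.15,
      debris = c(fsc = 25000, ssc = 4000), debris_sdlog = 0.30,
      tof_location = 60, tof_sdlog = 0.04),
    duration = 100,
    burst = NULL
  )
  class(profile) <- "ground_truth_profile"
  profile
}

#' @export
print.ground_truth_profile <- function(x, ...) {
  cat(sprintf("ground_truth_profile: %d leaf populations, %g leukocytes/uL\n",
              length(x$populations), x$leukocytes_per_ul))
  cat(sprintf("  dead %.2f%%, debris %.2f%%, doublets %.2f%% (defaults)\n",
              100 * x$dead_fraction, 100 * x$debris_fraction,
              100 * x$doublet_fraction))
  invisible(x)
}

#' Leaf-population frequencies of a profile
#' @param profile a [build_default_profile()] profile.
#' @return named numeric vector over leaf populations, summing to 1.
#' @export
population_frequencies <- function(profile) {
  vapply(profile$populations, `[[`, 0, "freq")
}

#' True major-cell-type fractions implied by a profile
#'
#' Sums leaf frequencies into the five anchor majors used by the absolute
#' counting panel: `T` (all CD3+, including NKT), `B`, `NK`, `Mo` and `Gr`
#' (neutrophils + eosinophils; basophils have lymphoid scatter and fall into
#' Rest of PBL there).
#'
#' @param profile a profile.
#' @return named numeric vector of fractions of all leukocytes.
#' @export
true_major_fractions <- function(profile) {
  f <- population_frequencies(profile)
  majors <- vapply(profile$populations, `[[`, "", "major")
  c(T = sum(f[majors == "T"]), B = sum(f[majors == "B"]),
    NK = sum(f[majors == "NK"]), Mo = sum(f[majors == "Mo"]),
    Gr = sum(f[majors == "Gr"]))
}

#' True absolute counts implied by a profile
#'
#' Bookkeeping identity: cells per microliter for all leukocytes and every
#' anchor major, as `frequency x leukocytes_per_ul`.
#'
#' @param profile a profile.
#' @return named numeric vector, cells per microliter.
#' @export
true_absolute_counts <- function(profile) {
  c(Leu = profile$leukocytes_per_ul,
    true_major_fractions(profile) * profile$leukocytes_per_ul)
}

#' Configure a population-frequency burst artifact
#'
#' Adds a transient rate increase (for flow-gate testing): during
#' `[start, start + duration)` seconds the event rate is multiplied by
#' `rate`. Off by default in [build_default_profile()].
#'
#' @param profile a profile.
#' @param start burst start, seconds.
#' @param duration burst length, seconds.
#' @param rate rate multiplier (> 1).
#' @return the modified profile.
#' @export
with_burst <- function(profile, start, duration, rate) {
  stopifnot(rate > 1, duration > 0, start >= 0)
  profile$burst <- list(start = start, duration = duration, rate = rate)
  profile
}

#' Bead configuration for the absolute-counting tube
#'
#' @param beads_per_tube known number of counting beads in the tube.
#' @param blood_volume_ul whole-blood volume pipetted onto the beads, uL.
#' @param fsc,ssc bead scatter locations (FSC-low / SSC-high).
#' @param channels fluorescence channels in which beads emit.
#' @param doublet_rate fraction of bead events that are bead doublets.
#' @return list of class `bead_config`.
#' @export
bead_config <- function(beads_per_tube = 10000, blood_volume_ul = 50,
                        fsc = 50000, ssc = 400000,
                        channels = c("FL1", "FL2", "FL3", "FL4", "FL8"),
                        doublet_rate = 0.02) {
  stopifnot(beads_per_tube > 0, blood_volume_ul > 0,
            doublet_rate >= 0, doublet_rate <= 0.1)
  structure(list(beads_per_tube = beads_per_tube,
                 blood_volume_ul = blood_volume_ul,
                 fsc = fsc, ssc = ssc, channels = channels,
                 doublet_rate = doublet_rate, intensity = 200000,
                 fsc_sdlog = 0.06, intensity_sdlog = 0.15),
            class = "bead_config")
}
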