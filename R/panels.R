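# The assay content: 12 panel schemas encoding the channel layout, display
# transforms, gate trees and Boolean gates of the whole-blood
# immunophenotyping workflow, the 37 subset definitions, the 27
# activation-marker readouts, and the enumeration of the 208 reported
# populations. The combined CD19/CD20 channel is the marker "CD19_20";
# HLA-DR is "HLADR"; the T-cell receptor markers are "TCRab" / "TCRgd".

#' Schema configuration: marker split thresholds and transforms
#'
#' The published gates were drawn manually against FMO controls; this
#' automated schema replaces them with two raw-intensity split thresholds
#' per marker: `pos_cut` separating negative from positive and `hi_cut`
#' separating lo/pos from hi. Defaults are calibrated to the simulator's
#' intensity templates; analysis of real acquisitions requires user
#' calibration of these cuts per marker and panel.
#'
#' @param pos_cut default negative/positive split, raw units.
#' @param hi_cut default lo/hi split, raw units.
#' @param marker_cuts named list of per-marker overrides, each a list with
#'   elements `pos` and/or `hi`.
#' @param logicle display transform applied to every fluorescence channel
#'   (per-channel overrides may be edited into a built schema).
#' @param ssc_granulo side-scatter lower bound of the granulocyte scatter
#'   gate (raw units, linear scale).
#' @param ssc_mo_band side-scatter band of the monocyte scatter gate.
#' @param beads_fsc_max,beads_ssc_min bounds of the FSC-low/SSC-high Beads
#'   gate, placed not to lose small beads among debris.
#' @param bead_pos_cut raw intensity above which a bead-gate event counts as
#'   fluorescent in a bead channel.
#' @return list of class `diob_config`.
#' @export
diob_config <- function(pos_cut = 800, hi_cut = 55000, marker_cuts = list(),
                        logicle = logicle_params(),
                        ssc_granulo = 85000, ssc_mo_band = c(30000, 85000),
                        beads_fsc_max = 150000, beads_ssc_min = 250000,
                        bead_pos_cut = 10000) {
  structure(list(pos_cut = pos_cut, hi_cut = hi_cut, marker_cuts = marker_cuts,
                 logicle = logicle, ssc_granulo = ssc_granulo,
                 ssc_mo_band = ssc_mo_band, beads_fsc_max = beads_fsc_max,
                 beads_ssc_min = beads_ssc_min, bead_pos_cut = bead_pos_cut),
            class = "diob_config")
}

# raw-space cut for a marker, honoring overrides; errors name marker + panel
marker_cut <- function(config, marker, which = c("pos", "hi"), panel = "?") {
  which <- match.arg(which)
  ov <- config$marker_cuts[[marker]]
  val <- if (!is.null(ov) && !is.null(ov[[which]])) ov[[which]]
         else config[[paste0(which, "_cut")]]
  if (is.null(val) || is.na(val))
    stop("configuration error: no '", which, "' threshold for marker ",
         marker, " in panel ", panel)
  val
}

#' Build the full 12-panel schema
#'
#' Constructs the complete gating content: per panel, the channel-to-marker
#' map, logicle transforms, the gate tree (geometric and Boolean nodes) and
#' the set of report-flagged populations. Gates shared between panels (the
#' CD3 gate of the T panels, the NK gates of both NK panels) carry link ids
#' and identical geometry. Input volume equivalents are 100 uL per panel,
#' 300 uL for the rare-cell panels P10/P11 and 50 uL for the uncentrifuged
#' absolute-counting panel P12.
#'
#' @param config a [diob_config()].
#' @return named list of 12 panel schemas (class `panel_schema`), each with
#'   elements `id`, `channels`, `transforms`, `tree`, `volume_ul`, `qc`,
#'   `fsc_shift`, `anchors` (major node id -> anchor cell type) and
#'   `major_nodes`.
#' @export
build_diob_schema <- function(config = diob_config()) {
  lp <- config$logicle
  # display-space cuts
  pd <- function(m, panel) to_logicle(marker_cut(config, m, "pos", panel), lp)
  hd <- function(m, panel) to_logicle(marker_cut(config, m, "hi", panel), lp)
  LOD <- -0.5; HID <- 1.5  # display-space bounds covering the whole scale

  # shorthand geometric builders (display space)
  g_pos <- function(m, p) gate_threshold(m, lo = pd(m, p))
  g_neg <- function(m, p) gate_threshold(m, hi = pd(m, p))
  g_hi <- function(m, p) gate_threshold(m, lo = hd(m, p))
  g_lo <- function(m, p) gate_threshold(m, lo = pd(m, p), hi = hd(m, p))
  g_nothi <- function(m, p) gate_threshold(m, hi = hd(m, p))
  rect <- function(xm, ym, xlim, ylim) gate_rectangle(xm, ym, xlim, ylim)

  panel <- function(id, channels, nodes, volume_ul = 100, anchors = character(),
                    fsc_shift = 1, qc = qc_config()) {
    transforms <- stats::setNames(rep(list(lp), length(channels)),
                                  names(channels))
    structure(list(id = id, channels = channels, transforms = transforms,
                   tree = gate_tree(nodes), volume_ul = volume_ul,
                   anchors = anchors, fsc_shift = fsc_shift, qc = qc),
              class = "panel_schema")
  }

  # memory quadrant (CD197 x CD45RA) under a parent, with CD38 readouts
  memory_nodes <- function(parent, prefix, p) {
    qs <- list(naive = "++", eff = "-+", em = "--", cm = "+-")
    labs <- c(naive = "Naive", eff = "Effector", em = "EM", cm = "CM")
    out <- list()
    for (k in names(qs)) {
      nid <- paste0(prefix, "_", k)
      out[[length(out) + 1L]] <- gate_node(
        nid, parent,
        gate = gate_quadrant("CD197", "CD45RA", pd("CD197", p), pd("CD45RA", p),
                             qs[[k]]),
        name = paste(labs[[k]], toupper(prefix)), report = TRUE, major = "t")
      out[[length(out) + 1L]] <- gate_node(
        paste0(nid, "_cd38"), nid, gate = g_pos("CD38", p),
        name = paste0("CD38+ ", labs[[k]], " ", toupper(prefix)),
        report = TRUE, major = "t")
    }
    out
  }

  cd3pos <- function(p, report = TRUE) gate_node("t", "root",
                                                 gate = g_pos("CD3", p),
                                                 name = "T cells",
                                                 report = report,
                                                 link = "CD3pos")

  ## ------------------------------------------------------------------ P01
  p <- "P01"
  p01_nodes <- c(list(
    cd3pos(p),
    gate_node("th", "t", gate = rect("CD4", "CD8",
                                     c(hd("CD4", p), HID), c(LOD, pd("CD8", p))),
              name = "TH", report = TRUE, major = "t"),
    gate_node("t8hi", "t", gate = rect("CD8", "CD4",
                                       c(hd("CD8", p), HID), c(LOD, pd("CD4", p))),
              name = "T8hi", report = TRUE, major = "t"),
    gate_node("t8lo", "t", gate = rect("CD8", "CD4",
                                       c(pd("CD8", p), hd("CD8", p)),
                                       c(LOD, pd("CD4", p))),
              name = "T8lo", report = TRUE, major = "t"),
    gate_node("tc", "t", boolean = bool_or("t8hi", "t8lo"),
              name = "TC", report = TRUE, major = "t"),
    gate_node("dnt", "t", gate = rect("CD4", "CD8",
                                      c(LOD, pd("CD4", p)), c(LOD, pd("CD8", p))),
              name = "DNT", report = TRUE, major = "t"),
    gate_node("dpt", "t", gate = rect("CD4", "CD8",
                                      c(hd("CD4", p), HID), c(hd("CD8", p), HID)),
              name = "DPT", report = TRUE, major = "t"),
    gate_node("t4lo", "t", gate = rect("CD4", "CD8",
                                       c(pd("CD4", p), hd("CD4", p)),
                                       c(LOD, pd("CD8", p))),
              name = "CD4lo/CD8- T", report = TRUE, major = "t"),
    gate_node("t4hi8lo", "t", gate = rect("CD4", "CD8",
                                          c(hd("CD4", p), HID),
                                          c(pd("CD8", p), hd("CD8", p))),
              name = "CD4hi/CD8lo T", report = TRUE, major = "t"),
    gate_node("t8hi4lo", "t", gate = rect("CD8", "CD4",
                                          c(hd("CD8", p), HID),
                                          c(pd("CD4", p), hd("CD4", p))),
              name = "CD8hi/CD4lo T", report = TRUE, major = "t")),
    memory_nodes("th", "th", p),
    memory_nodes("t8hi", "t8hi", p),
    memory_nodes("t8lo", "t8lo", p))
  p01 <- panel("P01",
               c(FL1 = "CD8", FL2 = "CD197", FL3 = "CD4", FL4 = "CD45RA",
                 FL6 = "CD38", FL9 = "CD3"),
               p01_nodes, anchors = c(t = "T"))

  ## ------------------------------------------------------------------ P02
  p <- "P02"
  p02_nodes <- list(
    cd3pos(p),
    gate_node("th", "t", gate = g_hi("CD4", p), name = "TH", report = TRUE,
              major = "t"),
    gate_node("th1", "th", gate = gate_quadrant("CD183", "CD196",
                                                pd("CD183", p), pd("CD196", p), "+-"),
              name = "TH1", report = TRUE, major = "t"),
    gate_node("th2", "th", gate = gate_quadrant("CD183", "CD196",
                                                pd("CD183", p), pd("CD196", p), "--"),
              name = "TH2", report = TRUE, major = "t"),
    gate_node("th17", "th", gate = gate_quadrant("CD183", "CD196",
                                                 pd("CD183", p), pd("CD196", p), "-+"),
              name = "TH17", report = TRUE, major = "t"),
    gate_node("th1_17", "th", gate = gate_quadrant("CD183", "CD196",
                                                   pd("CD183", p), pd("CD196", p), "++"),
              name = "TH1/17 (CD183+/CD196+)", report = TRUE, major = "t"),
    gate_node("treg", "th", gate = rect("CD25", "CD127",
                                        c(hd("CD25", p), HID), c(LOD, pd("CD127", p))),
              name = "TREG", report = TRUE, major = "t"))
  p02 <- panel("P02",
               c(FL1 = "CD127", FL2 = "CD196", FL3 = "CD4", FL4 = "CD25",
                 FL6 = "CD183", FL9 = "CD3"),
               p02_nodes, anchors = c(t = "T"))

  ## ------------------------------------------------------------------ P03
  p <- "P03"
  p03_nodes <- list(
    cd3pos(p),
    gate_node("tcrab", "t",
              gate = gate_quadrant("TCRab", "TCRgd", pd("TCRab", p),
                                   pd("TCRgd", p), "+-"),
              name = "TCRab T cells", report = TRUE, major = "t"),
    gate_node("tcrgd", "t",
              gate = gate_quadrant("TCRab", "TCRgd", pd("TCRab", p),
                                   pd("TCRgd", p), "-+"),
              name = "TCRgd T cells", report = TRUE, major = "t"),
    gate_node("cd152t", "t", gate = g_pos("CD152", p), name = "CD152+ T",
              report = TRUE, major = "t"))
  p03 <- panel("P03",
               c(FL1 = "TCRgd", FL2 = "TCRab", FL6 = "CD152", FL9 = "CD3"),
               p03_nodes, anchors = c(t = "T"))

  ## ------------------------------------------------------------------ P04
  p <- "P04"
  q27 <- function(cell) gate_quadrant("CD27", "CD38", pd("CD27", p),
                                      hd("CD38", p), cell)
  p04_nodes <- list(
    gate_node("cd19b", "root", gate = g_pos("CD19", p), name = "CD19+ B cells",
              report = TRUE),
    gate_node("cd20b", "root", gate = g_pos("CD20", p), name = "CD20+ B cells",
              report = TRUE),
    gate_node("b", "root", boolean = bool_or("cd19b", "cd20b"),
              name = "B cells (CD19 or CD20)", report = TRUE),
    gate_node("q_2738_nn", "b", gate = q27("--"), name = "CD27-/CD38-lo B",
              report = TRUE, major = "b"),
    gate_node("q_2738_pn", "b", gate = q27("+-"), name = "CD27+/CD38-lo B",
              report = TRUE, major = "b"),
    gate_node("q_2738_nh", "b", gate = q27("-+"), name = "CD27-/CD38hi B",
              report = TRUE, major = "b"),
    gate_node("q_2738_ph", "b", gate = q27("++"), name = "CD27+/CD38hi B",
              report = TRUE, major = "b"),
    gate_node("prenaive", "q_2738_nn", gate = g_pos("CD5", p),
              name = "Pre-naive B", report = TRUE, major = "b"),
    gate_node("naive", "q_2738_nn", gate = g_neg("CD5", p),
              name = "Naive B", report = TRUE, major = "b"),
    gate_node("memory", "q_2738_pn",
              gate = rect("CD5", "CD24", c(LOD, pd("CD5", p)),
                          c(pd("CD24", p), HID)),
              name = "Memory B", report = TRUE, major = "b"),
    gate_node("transitional", "q_2738_nh",
              gate = rect("CD5", "CD24", c(pd("CD5", p), HID),
                          c(hd("CD24", p), HID)),
              name = "Transitional B", report = TRUE, major = "b"),
    gate_node("plasmablast", "q_2738_ph",
              gate = rect("CD5", "CD24", c(LOD, pd("CD5", p)),
                          c(LOD, pd("CD24", p))),
              name = "Plasmablasts", report = TRUE, major = "b"),
    gate_node("restb", "b",
              boolean = bool_and("b", bool_not(bool_or("prenaive",
                bool_or("naive", bool_or("memory",
                  bool_or("transitional", "plasmablast")))))),
              name = "Rest of B cells", report = TRUE, major = "b"),
    gate_node("breg", "restb",
              gate = rect("CD27", "CD24", c(pd("CD27", p), HID),
                          c(hd("CD24", p), HID)),
              name = "BREG", report = TRUE, major = "b"))
  p04 <- panel("P04",
               c(FL1 = "CD20", FL3 = "CD24", FL4 = "CD5", FL6 = "CD38",
                 FL9 = "CD27", FL10 = "CD19"),
               p04_nodes, anchors = c(b = "B"))

  ## ------------------------------------------------------------------ P05
  p <- "P05"
  act <- function(marker, parent, ctx, major) {
    gate_node(paste0(tolower(marker), "_", parent), parent,
              gate = g_pos(marker, p),
              name = paste0(marker, "+ ", ctx), report = TRUE, major = major)
  }
  p05_nodes <- c(list(
    cd3pos(p),
    gate_node("b5", "root", gate = g_pos("CD19_20", p),
              name = "B cells (CD19/20)", report = TRUE)),
    lapply(c("CD25", "CD69", "CD80", "CD86", "HLADR", "CD279"),
           act, parent = "t", ctx = "T", major = "t"),
    lapply(c("CD25", "CD69", "CD80", "CD86", "HLADR"),
           act, parent = "b5", ctx = "B", major = "b5"))
  p05 <- panel("P05",
               c(FL1 = "CD19_20", FL2 = "CD25", FL3 = "CD86", FL4 = "CD69",
                 FL6 = "CD279", FL8 = "CD80", FL9 = "CD3", FL10 = "HLADR"),
               p05_nodes, anchors = c(t = "T", b5 = "B"))

  ## ------------------------------------------------------------- P06 / P07
  # NK gates are linked between the panels: identical geometry
  nk_gates <- function(p) list(
    gate_node("cd3neg", "root", gate = g_neg("CD3", p), name = "CD3- cells",
              report = TRUE, link = "CD3neg"),
    gate_node("nk", "cd3neg", gate = g_pos("CD56", p), name = "NK cells",
              report = TRUE, link = "NK"),
    gate_node("nk1", "nk", gate = g_pos("CD16", p), name = "NK1 (CD56lo/CD16+)",
              report = TRUE, major = "nk", link = "NK1"),
    gate_node("nk2", "nk", gate = rect("CD16", "CD56", c(LOD, pd("CD16", p)),
                                       c(hd("CD56", p), HID)),
              name = "NK2 (CD56hi/CD16-)", report = TRUE, major = "nk",
              link = "NK2"),
    gate_node("nk3", "nk", gate = rect("CD16", "CD56", c(LOD, pd("CD16", p)),
                                       c(LOD, hd("CD56", p))),
              name = "NK3 (CD56lo/CD16-)", report = TRUE, major = "nk",
              link = "NK3"))
  per_subset <- function(gid, label, p) {
    lapply(c("nk1", "nk2", "nk3"), function(s) {
      gate_node(paste0(s, "_", gid), "nk", boolean = bool_and(s, gid),
                name = paste0(label, " ", toupper(s)), report = TRUE,
                major = "nk")
    })
  }
  p <- "P06"
  p06_nodes <- c(nk_gates(p), list(
    gate_node("cd314nk", "nk", gate = g_pos("CD314", p), name = "CD314+ NK",
              report = TRUE, major = "nk"),
    gate_node("cd25nk", "nk", gate = g_pos("CD25", p), name = "CD25+ NK",
              report = TRUE, major = "nk"),
    gate_node("cd69nk", "nk", gate = g_pos("CD69", p), name = "CD69+ NK",
              report = TRUE, major = "nk")),
    per_subset("cd314nk", "CD314+", p),
    per_subset("cd25nk", "CD25+", p),
    per_subset("cd69nk", "CD69+", p),
    list(
      cd3pos(p, report = FALSE),
      gate_node("nkt56", "t", gate = g_pos("CD56", p), name = "CD56+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt16", "t", gate = g_pos("CD16", p), name = "CD16+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt314", "t", gate = g_pos("CD314", p), name = "CD314+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt", "t", boolean = bool_or("nkt56", bool_or("nkt16", "nkt314")),
                name = "NKT", report = TRUE, major = "t")))
  p06 <- panel("P06",
               c(FL1 = "CD69", FL2 = "CD16", FL3 = "CD56", FL6 = "CD314",
                 FL9 = "CD25", FL10 = "CD3"),
               p06_nodes, anchors = c(nk = "NK", t = "T"))

  p <- "P07"
  p07_nodes <- c(nk_gates(p), list(
    gate_node("cd94nk", "nk", gate = g_pos("CD94", p), name = "CD94+ NK",
              report = TRUE, major = "nk"),
    gate_node("nkg2a_nk", "nk",
              gate = rect("CD159a", "CD94", c(pd("CD159a", p), HID),
                          c(pd("CD94", p), HID)),
              name = "CD159a+/CD94+ NK", report = TRUE, major = "nk"),
    gate_node("nkg2c_nk", "nk",
              gate = rect("CD159c", "CD94", c(pd("CD159c", p), HID),
                          c(pd("CD94", p), HID)),
              name = "CD159c+/CD94+ NK", report = TRUE, major = "nk")),
    per_subset("nkg2a_nk", "CD159a+/CD94+", p),
    per_subset("nkg2c_nk", "CD159c+/CD94+", p),
    list(
      cd3pos(p, report = FALSE),
      gate_node("nkt56", "t", gate = g_pos("CD56", p), name = "CD56+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt16", "t", gate = g_pos("CD16", p), name = "CD16+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt94", "t", gate = g_pos("CD94", p), name = "CD94+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt159a", "t", gate = g_pos("CD159a", p), name = "CD159a+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt159c", "t", gate = g_pos("CD159c", p), name = "CD159c+ NKT",
                report = TRUE, major = "t"),
      gate_node("nkt", "t",
                boolean = bool_or("nkt94", bool_or("nkt56",
                  bool_or("nkt159c", bool_or("nkt159a", "nkt16")))),
                name = "NKT", report = TRUE, major = "t")))
  p07 <- panel("P07",
               c(FL1 = "CD159c", FL2 = "CD16", FL3 = "CD56", FL4 = "CD94",
                 FL6 = "CD159a", FL10 = "CD3"),
               p07_nodes, anchors = c(nk = "NK", t = "T"))

  ## ------------------------------------------------------------------ P08
  p <- "P08"
  q1416 <- function(cell) gate_quadrant("CD14", "CD16", hd("CD14", p),
                                        pd("CD16", p), cell)
  act2 <- function(marker, which, name) {
    g <- if (which == "pos") g_pos(marker, p) else g_hi(marker, p)
    gate_node(paste0(tolower(marker), which, "_mo"), "mo", gate = g,
              name = name, report = TRUE, major = "mo")
  }
  p08_nodes <- list(
    gate_node("mo", "root", gate = g_pos("CD14", p), name = "Monocytes",
              report = TRUE),
    gate_node("mo1", "mo", gate = q1416("+-"), name = "Mo1 (CD14hi/CD16-)",
              report = TRUE, major = "mo"),
    gate_node("mo2", "mo", gate = q1416("-+"), name = "Mo2 (CD14lo/CD16+)",
              report = TRUE, major = "mo"),
    gate_node("mo3", "mo", gate = q1416("++"), name = "Mo3 (CD14hi/CD16+)",
              report = TRUE, major = "mo"),
    gate_node("mo4", "mo", gate = q1416("--"), name = "Mo4 (CD14lo/CD16-)",
              report = TRUE, major = "mo"),
    act2("CD80", "pos", "CD80+ Mo"),
    act2("CD86", "pos", "CD86+ Mo"), act2("CD86", "hi", "CD86hi Mo"),
    act2("CD64", "pos", "CD64+ Mo"), act2("CD64", "hi", "CD64hi Mo"),
    act2("HLADR", "pos", "HLA-DR+ Mo"), act2("HLADR", "hi", "HLA-DRhi Mo"))
  p08 <- panel("P08",
               c(FL1 = "CD14", FL2 = "CD16", FL3 = "CD86", FL6 = "CD80",
                 FL9 = "CD64", FL10 = "HLADR"),
               p08_nodes, anchors = c(mo = "Mo"))

  ## ------------------------------------------------------------------ P09
  p <- "P09"
  p09_nodes <- list(
    gate_node("gran", "root",
              gate = rect("SSC", "CD66", c(config$ssc_granulo, Inf),
                          c(pd("CD66", p), HID)),
              name = "Granulocytes (CD66+/SSChi)", report = TRUE),
    gate_node("neu", "gran", gate = g_pos("CD16", p), name = "Neutrophils",
              report = TRUE, major = "gran"),
    gate_node("eos", "gran", gate = g_neg("CD16", p), name = "Eosinophils",
              report = TRUE, major = "gran"),
    gate_node("cd64neu", "neu", gate = g_pos("CD64", p), name = "CD64+ Neu",
              report = TRUE, major = "gran"),
    gate_node("cd64eos", "eos", gate = g_pos("CD64", p), name = "CD64+ Eos",
              report = TRUE, major = "gran"))
  p09 <- panel("P09",
               c(FL1 = "CD66", FL9 = "CD64", FL10 = "CD16"),
               p09_nodes, anchors = c(gran = "Gr"))

  ## ------------------------------------------------------------------ P10
  p <- "P10"
  p10_nodes <- list(
    gate_node("lin_neg", "root", gate = g_neg("LIN", p), name = "LIN- cells",
              report = TRUE),
    gate_node("hladr_neg", "lin_neg", gate = g_neg("HLADR", p),
              name = "LIN-/HLA-DR- cells"),
    gate_node("baso", "hladr_neg", gate = g_pos("CD123", p),
              name = "Basophils", report = TRUE),
    gate_node("dc", "lin_neg", gate = g_pos("HLADR", p),
              name = "DC (LIN-/HLA-DR+)", report = TRUE),
    gate_node("pdc", "dc",
              gate = rect("CD123", "CD11c", c(hd("CD123", p), HID),
                          c(LOD, pd("CD11c", p))),
              name = "pDC", report = TRUE, major = "dc"),
    gate_node("mdc", "dc",
              gate = rect("CD11c", "CD123", c(hd("CD11c", p), HID),
                          c(LOD, hd("CD123", p))),
              name = "mDC", report = TRUE, major = "dc"),
    gate_node("mdc1", "mdc", gate = g_pos("CD1c", p), name = "mDC-1",
              report = TRUE, major = "dc"),
    gate_node("mdc2", "mdc", gate = g_neg("CD1c", p), name = "mDC-2",
              report = TRUE, major = "dc"),
    gate_node("alldc", "dc", boolean = bool_or("mdc", "pdc"),
              name = "All DCs", report = TRUE, major = "dc"),
    gate_node("cd83dc", "alldc", gate = g_pos("CD83", p), name = "CD83+ DC",
              report = TRUE, major = "dc"),
    gate_node("cd274dc", "alldc", gate = g_pos("CD274", p), name = "CD274+ DC",
              report = TRUE, major = "dc"))
  p10 <- panel("P10",
               c(FL1 = "LIN", FL2 = "CD274", FL3 = "CD123", FL4 = "CD83",
                 FL6 = "CD1c", FL9 = "CD11c", FL10 = "HLADR"),
               p10_nodes, volume_ul = 300, anchors = c(dc = "Leu"))

  ## ------------------------------------------------------------------ P11
  p <- "P11"
  p11_nodes <- list(
    gate_node("epc", "root",
              gate = rect("CD146", "CD133", c(LOD, pd("CD146", p)),
                          c(pd("CD133", p), HID)),
              name = "EPC (CD146-/CD133+)", report = TRUE),
    gate_node("epc45p", "epc", gate = g_pos("CD45", p), name = "CD45+ EPC",
              report = TRUE, major = "epc"),
    gate_node("epc45n", "epc", gate = g_neg("CD45", p), name = "CD45- EPC",
              report = TRUE, major = "epc"),
    gate_node("cd45dim", "root", gate = g_nothi("CD45", p),
              name = "CD45-/lo cells", report = TRUE),
    gate_node("cec", "cd45dim",
              gate = rect("CD146", "CD133", c(pd("CD146", p), HID),
                          c(LOD, pd("CD133", p))),
              name = "CEC (CD146+/CD133-)", report = TRUE, major = "cd45dim"),
    gate_node("hsc", "cd45dim",
              gate = rect("CD146", "CD34", c(LOD, pd("CD146", p)),
                          c(pd("CD34", p), HID)),
              name = "HSC (CD146-/CD34+)", report = TRUE, major = "cd45dim"),
    gate_node("hsc133p", "hsc", gate = g_pos("CD133", p), name = "CD133+ HSC",
              report = TRUE, major = "cd45dim"),
    gate_node("hsc133n", "hsc", gate = g_neg("CD133", p), name = "CD133- HSC",
              report = TRUE, major = "cd45dim"),
    gate_node("cd34_all", "root", gate = g_pos("CD34", p),
              name = "CD34+ (All Cells)", report = TRUE),
    gate_node("cd133_all", "root", gate = g_pos("CD133", p),
              name = "CD133+ (All Cells)", report = TRUE))
  p11 <- panel("P11",
               c(FL1 = "CD146", FL2 = "CD133", FL4 = "CD45", FL6 = "CD34"),
               p11_nodes, volume_ul = 300, anchors = c(epc = "Leu", cd45dim = "Leu"))

  ## ------------------------------------------------------------------ P12
  p <- "P12"
  mo_band <- config$ssc_mo_band
  p12_nodes <- list(
    gate_node("leu", "root", gate = g_pos("CD45", p), name = "Leukocytes (CD45+)",
              report = TRUE),
    gate_node("t12", "leu", gate = g_pos("CD3", p), name = "T cells",
              report = TRUE),
    gate_node("rest1", "leu", boolean = bool_and("leu", bool_not("t12")),
              name = "Rest 1"),
    gate_node("b12", "rest1", gate = g_pos("CD19_20", p), name = "B cells",
              report = TRUE),
    gate_node("rest2", "rest1", boolean = bool_and("rest1", bool_not("b12")),
              name = "Rest 2"),
    gate_node("mo12", "rest2", gate = gate_threshold("SSC", mo_band[1], mo_band[2]),
              name = "Monocytes (scatter)", report = TRUE),
    gate_node("gr12", "rest2", gate = gate_threshold("SSC", mo_band[2], Inf),
              name = "Granulocytes (scatter)", report = TRUE),
    gate_node("rest3", "rest2",
              boolean = bool_and("rest2", bool_not(bool_or("mo12", "gr12"))),
              name = "Rest 3"),
    gate_node("nk56", "rest3", gate = g_pos("CD56", p), name = "CD56+ of Rest 3"),
    gate_node("nk16", "rest3", gate = g_pos("CD16", p), name = "CD16+ of Rest 3"),
    gate_node("nk12", "rest3", boolean = bool_or("nk56", "nk16"),
              name = "NK cells", report = TRUE),
    gate_node("rest4", "rest3", boolean = bool_and("rest3", bool_not("nk12")),
              name = "Rest of cells", report = TRUE),
    gate_node("rest_pbl", "rest4", gate = gate_threshold("SSC", -Inf, mo_band[1]),
              name = "Rest of PBL", report = TRUE),
    gate_node("neu12", "gr12", gate = g_pos("CD16", p), name = "Neu (CD16+ Gr)",
              report = TRUE),
    gate_node("eos12", "gr12", gate = g_neg("CD16", p), name = "Eos (CD16- Gr)",
              report = TRUE),
    gate_node("mo16p", "mo12", gate = g_pos("CD16", p), name = "CD16+ Mo",
              report = TRUE),
    gate_node("mo16n", "mo12", gate = g_neg("CD16", p), name = "CD16- Mo",
              report = TRUE))
  p12 <- panel("P12",
               c(FL1 = "CD19_20", FL2 = "CD16", FL3 = "CD56", FL4 = "CD45",
                 FL8 = NA_character_, FL9 = "CD3"),
               p12_nodes, volume_ul = 50,
               anchors = c(leu = "Leu", t12 = "T", b12 = "B", mo12 = "Mo",
                           gr12 = "Gr", nk12 = "NK"),
               fsc_shift = 1.15, qc = qc_config(fsc_scale = 1.15))
  # FL8 carries no antibody in P12; it is one of the bead channels
  p12$channels <- p12$channels[!is.na(p12$channels)]

  list(P01 = p01, P02 = p02, P03 = p03, P04 = p04, P05 = p05, P06 = p06,
       P07 = p07, P08 = p08, P09 = p09, P10 = p10, P11 = p11, P12 = p12)
}

#' @export
print.panel_schema <- function(x, ...) {
  cat(sprintf("panel_schema %s: %d channels, %d gate nodes, %d uL\n",
              x$id, length(x$channels), length(x$tree$nodes), x$volume_ul))
  invisible(x)
}
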