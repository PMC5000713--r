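# Subset catalogue, activation-marker readouts, the enumeration of reported
# populations, the sequential major-cell-type classification of the
# absolute-counting panel, and helpers for planting pure phenotypes into the
# simulator.

#' All markers known to the assay
#'
#' The marker universe of the 12 panels (Table-style channel maps), including
#' the derived combined channel `CD19_20` and the lineage cocktail `LIN`
#' (CD3/CD14/CD16/CD19/CD20/CD56 pooled into one channel).
#'
#' @return character vector of marker names.
#' @export
diob_markers <- function() {
  c("CD3", "CD4", "CD8", "CD45RA", "CD197", "CD38", "CD127", "CD196",
    "CD25", "CD183", "TCRab", "TCRgd", "CD152", "CD19", "CD20", "CD19_20",
    "CD24", "CD5", "CD27", "CD86", "CD69", "CD279", "CD80", "HLADR",
    "CD16", "CD56", "CD314", "CD159c", "CD94", "CD159a", "CD14", "CD64",
    "CD66", "LIN", "CD274", "CD123", "CD83", "CD1c", "CD11c", "CD146",
    "CD133", "CD45", "CD34")
}

# plant specifications: phenotype levels, scatter class, target panel/node,
# and the sibling gates the planted population must stay out of
.diob_plants <- function() {
  t_ <- c(CD3 = "pos")
  b_ <- c(CD19 = "pos", CD20 = "pos", CD19_20 = "pos")
  list(
    TH1 = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD183 = "pos", CD196 = "neg"),
               panel = "P02", target = "th1", siblings = c("th2", "th17", "th1_17")),
    TH2 = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD183 = "neg", CD196 = "neg"),
               panel = "P02", target = "th2", siblings = c("th1", "th17", "th1_17")),
    TH17 = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD183 = "neg", CD196 = "pos"),
                panel = "P02", target = "th17", siblings = c("th1", "th2", "th1_17")),
    TREG = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD25 = "hi", CD127 = "neg"),
                panel = "P02", target = "treg", siblings = character()),
    NaiveTH = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD197 = "pos", CD45RA = "pos"),
                   panel = "P01", target = "th_naive",
                   siblings = c("th_eff", "th_em", "th_cm")),
    EffectorTH = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD197 = "neg", CD45RA = "pos"),
                      panel = "P01", target = "th_eff",
                      siblings = c("th_naive", "th_em", "th_cm")),
    EMTH = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD197 = "neg", CD45RA = "neg"),
                panel = "P01", target = "th_em",
                siblings = c("th_naive", "th_eff", "th_cm")),
    CMTH = list(levels = c(t_, CD4 = "hi", CD8 = "neg", CD197 = "pos", CD45RA = "neg"),
                panel = "P01", target = "th_cm",
                siblings = c("th_naive", "th_eff", "th_em")),
    NaiveTC = list(levels = c(t_, CD8 = "hi", CD4 = "neg", CD197 = "pos", CD45RA = "pos"),
                   panel = "P01", target = "t8hi_naive",
                   siblings = c("t8hi_eff", "t8hi_em", "t8hi_cm", "th")),
    EffectorTC = list(levels = c(t_, CD8 = "hi", CD4 = "neg", CD197 = "neg", CD45RA = "pos"),
                      panel = "P01", target = "t8hi_eff",
                      siblings = c("t8hi_naive", "t8hi_em", "t8hi_cm", "th")),
    EMTC = list(levels = c(t_, CD8 = "hi", CD4 = "neg", CD197 = "neg", CD45RA = "neg"),
                panel = "P01", target = "t8hi_em",
                siblings = c("t8hi_naive", "t8hi_eff", "t8hi_cm", "th")),
    CMTC = list(levels = c(t_, CD8 = "hi", CD4 = "neg", CD197 = "pos", CD45RA = "neg"),
                panel = "P01", target = "t8hi_cm",
                siblings = c("t8hi_naive", "t8hi_eff", "t8hi_em", "th")),
    TCRabT = list(levels = c(t_, TCRab = "pos", TCRgd = "neg"),
                  panel = "P03", target = "tcrab", siblings = "tcrgd"),
    TCRgdT = list(levels = c(t_, TCRab = "neg", TCRgd = "pos"),
                  panel = "P03", target = "tcrgd", siblings = "tcrab"),
    PreNaiveB = list(levels = c(b_, CD27 = "neg", CD38 = "lo", CD5 = "pos", CD24 = "pos"),
                     panel = "P04", target = "prenaive",
                     siblings = c("naive", "memory", "transitional", "plasmablast", "breg")),
    NaiveB = list(levels = c(b_, CD27 = "neg", CD38 = "lo", CD5 = "neg", CD24 = "pos"),
                  panel = "P04", target = "naive",
                  siblings = c("prenaive", "memory", "transitional", "plasmablast", "breg")),
    MemoryB = list(levels = c(b_, CD27 = "pos", CD38 = "lo", CD5 = "neg", CD24 = "pos"),
                   panel = "P04", target = "memory",
                   siblings = c("prenaive", "naive", "transitional", "plasmablast", "breg")),
    TransitionalB = list(levels = c(b_, CD27 = "neg", CD38 = "hi", CD5 = "pos", CD24 = "hi"),
                         panel = "P04", target = "transitional",
                         siblings = c("prenaive", "naive", "memory", "plasmablast", "breg")),
    Plasmablasts = list(levels = c(b_, CD27 = "pos", CD38 = "hi", CD5 = "neg", CD24 = "neg"),
                        panel = "P04", target = "plasmablast",
                        siblings = c("prenaive", "naive", "memory", "transitional", "breg")),
    BREG = list(levels = c(b_, CD27 = "pos", CD38 = "lo", CD5 = "pos", CD24 = "hi"),
                panel = "P04", target = "breg",
                siblings = c("prenaive", "naive", "memory", "transitional", "plasmablast")),
    NK1 = list(levels = c(CD3 = "neg", CD56 = "pos", CD16 = "pos"),
               panel = "P06", target = "nk1", siblings = c("nk2", "nk3")),
    NK2 = list(levels = c(CD3 = "neg", CD56 = "hi", CD16 = "neg"),
               panel = "P06", target = "nk2", siblings = c("nk1", "nk3")),
    NK3 = list(levels = c(CD3 = "neg", CD56 = "lo", CD16 = "neg"),
               panel = "P06", target = "nk3", siblings = c("nk1", "nk2")),
    NKT = list(levels = c(CD3 = "pos", CD56 = "pos"),
               panel = "P06", target = "nkt", siblings = "nk"),
    Neutrophils = list(levels = c(CD66 = "pos", CD16 = "pos"), scatter = "Gr",
                       panel = "P09", target = "neu", siblings = "eos"),
    Eosinophils = list(levels = c(CD66 = "pos", CD16 = "neg"), scatter = "Gr",
                       panel = "P09", target = "eos", siblings = "neu"),
    Basophils = list(levels = c(LIN = "neg", HLADR = "neg", CD123 = "pos"),
                     panel = "P10", target = "baso", siblings = c("pdc", "mdc")),
    pDC = list(levels = c(LIN = "neg", HLADR = "pos", CD123 = "hi", CD11c = "neg"),
               panel = "P10", target = "pdc", siblings = c("mdc", "baso")),
    mDC1 = list(levels = c(LIN = "neg", HLADR = "pos", CD11c = "hi",
                           CD123 = "neg", CD1c = "pos"),
                panel = "P10", target = "mdc1", siblings = c("mdc2", "pdc", "baso")),
    mDC2 = list(levels = c(LIN = "neg", HLADR = "pos", CD11c = "hi",
                           CD123 = "neg", CD1c = "neg"),
                panel = "P10", target = "mdc2", siblings = c("mdc1", "pdc", "baso")),
    Mo1 = list(levels = c(CD14 = "hi", CD16 = "neg"), scatter = "Mo",
               panel = "P08", target = "mo1", siblings = c("mo2", "mo3", "mo4")),
    Mo2 = list(levels = c(CD14 = "lo", CD16 = "pos"), scatter = "Mo",
               panel = "P08", target = "mo2", siblings = c("mo1", "mo3", "mo4")),
    Mo3 = list(levels = c(CD14 = "hi", CD16 = "pos"), scatter = "Mo",
               panel = "P08", target = "mo3", siblings = c("mo1", "mo2", "mo4")),
    Mo4 = list(levels = c(CD14 = "lo", CD16 = "neg"), scatter = "Mo",
               panel = "P08", target = "mo4", siblings = c("mo1", "mo2", "mo3")),
    HSC = list(levels = c(CD45 = "lo", CD146 = "neg", CD34 = "pos", CD133 = "neg"),
               panel = "P11", target = "hsc", siblings = c("cec", "epc")),
    CEC = list(levels = c(CD45 = "neg", CD146 = "pos", CD133 = "neg", CD34 = "neg"),
               panel = "P11", target = "cec", siblings = c("hsc", "epc")),
    EPC = list(levels = c(CD45 = "neg", CD146 = "neg", CD133 = "pos", CD34 = "neg"),
               panel = "P11", target = "epc", siblings = c("hsc", "cec"))
  )
}

#' The 37 monitored cell subsets
#'
#' One row per monitored subset: 34 immune subsets (14 T, 6 B, 3 NK, NKT,
#' neutrophils, eosinophils, basophils, 3 DC, 4 monocyte) and 3 non-immune
#' subsets (HSC, CEC, EPC), with their phenotype definitions, the panel that
#' identifies each, and the gate-tree node reporting it.
#'
#' @return data.frame with columns `subset`, `major_type`, `class`
#'   (`"immune"` / `"non_immune"`), `definition`, `panel`, `node`.
#' @export
subset_definitions <- function() {
  plants <- .diob_plants()
  majors <- c(rep("T", 14), rep("B", 6), rep("NK", 3), "T",
              "Gr", "Gr", "Leu", rep("DC", 3), rep("Mo", 4),
              rep("non-immune", 3))
  defs <- c(
    TH1 = "CD3+/CD4+/CD8-/CD183+/CD196-",
    TH2 = "CD3+/CD4+/CD8-/CD183-/CD196-",
    TH17 = "CD3+/CD4+/CD8-/CD183-/CD196+",
    TREG = "CD3+/CD4+/CD8-/CD25hi/CD127-lo",
    NaiveTH = "CD3+/CD4+/CD8-/CD197+/CD45RA+",
    EffectorTH = "CD3+/CD4+/CD8-/CD197-/CD45RA+",
    EMTH = "CD3+/CD4+/CD8-/CD197-/CD45RA-",
    CMTH = "CD3+/CD4+/CD8-/CD197+/CD45RA-",
    NaiveTC = "CD3+/CD8+/CD4-/CD197+/CD45RA+",
    EffectorTC = "CD3+/CD8+/CD4-/CD197-/CD45RA+",
    EMTC = "CD3+/CD8+/CD4-/CD197-/CD45RA-",
    CMTC = "CD3+/CD8+/CD4-/CD197+/CD45RA-",
    TCRabT = "CD3+/TCRab+/TCRgd-",
    TCRgdT = "CD3+/TCRgd+/TCRab-",
    PreNaiveB = "CD19+ or CD20+/CD27-/CD38-lo/CD5+",
    NaiveB = "CD19+ or CD20+/CD27-/CD38-lo/CD5-",
    MemoryB = "CD19+ or CD20+/CD27+/CD38-lo/CD5-/CD24+",
    TransitionalB = "CD19+ or CD20+/CD27-/CD38hi/CD5+/CD24hi",
    Plasmablasts = "CD19+ or CD20+/CD27+/CD38hi/CD5-/CD24-",
    BREG = "CD19+ or CD20+/CD27+/CD24hi after exclusion of the other five B subsets",
    NK1 = "CD3-/CD56+/CD16+",
    NK2 = "CD3-/CD56hi/CD16-",
    NK3 = "CD3-/CD56lo/CD16-",
    NKT = "CD3+/CD56+ or CD3+/CD16+ or CD3+/CD314+",
    Neutrophils = "CD66+/CD16+",
    Eosinophils = "CD66+/CD16-",
    Basophils = "LIN-/HLA-DR-/CD123+",
    pDC = "LIN-/HLA-DR+/CD123hi/CD11c-",
    mDC1 = "LIN-/HLA-DR+/CD11chi/CD123-lo/CD1c+",
    mDC2 = "LIN-/HLA-DR+/CD11chi/CD123-lo/CD1c-",
    Mo1 = "CD14hi/CD16-",
    Mo2 = "CD14lo/CD16+",
    Mo3 = "CD14hi/CD16+",
    Mo4 = "CD14lo/CD16-",
    HSC = "CD45-lo/CD146-/CD34+",
    CEC = "CD45-lo/CD146+/CD133-",
    EPC = "CD146-/CD133+"
  )
  stopifnot(identical(names(defs), names(plants)))
  data.frame(
    subset = names(defs),
    major_type = majors,
    class = ifelse(majors == "non-immune", "non_immune", "immune"),
    definition = unname(defs),
    panel = vapply(plants, `[[`, "", "panel"),
    node = vapply(plants, `[[`, "", "target"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' The 27 activation-marker readouts
#'
#' Activation and functional-state readouts, one row per marker-on-cell-type
#' determination: CD38 on TH and TC memory subsets (P01), CD152 on T (P03),
#' six markers on T and five on B (P05), CD25/CD69/CD314 on NK (P06),
#' the CD94/CD159a and CD94/CD159c receptor complexes on NK (P07), four
#' markers on monocytes (P08), CD64 on neutrophils and eosinophils (P09),
#' and CD83/CD274 on DCs (P10).
#'
#' @return data.frame with columns `panel`, `marker`, `cell_type`.
#' @export
activation_readouts <- function() {
  rows <- rbind(
    c("P01", "CD38", "TH"), c("P01", "CD38", "TC"),
    c("P03", "CD152", "T"),
    c("P05", "CD25", "T"), c("P05", "CD69", "T"), c("P05", "CD80", "T"),
    c("P05", "CD86", "T"), c("P05", "HLADR", "T"), c("P05", "CD279", "T"),
    c("P05", "CD25", "B"), c("P05", "CD69", "B"), c("P05", "CD80", "B"),
    c("P05", "CD86", "B"), c("P05", "HLADR", "B"),
    c("P06", "CD25", "NK"), c("P06", "CD69", "NK"), c("P06", "CD314", "NK"),
    c("P07", "CD159a/CD94", "NK"), c("P07", "CD159c/CD94", "NK"),
    c("P08", "CD80", "Mo"), c("P08", "CD86", "Mo"), c("P08", "CD64", "Mo"),
    c("P08", "HLADR", "Mo"),
    c("P09", "CD64", "Neu"), c("P09", "CD64", "Eos"),
    c("P10", "CD83", "DC"), c("P10", "CD274", "DC"))
  stats::setNames(as.data.frame(rows, stringsAsFactors = FALSE),
                  c("panel", "marker", "cell_type"))
}

#' Enumerate all reported populations of a schema
#'
#' The deterministic list of per-sample population statistics the pipeline
#' reports: for every panel the morphology populations (All Cells, plus the
#' PBL/Mo/Gr scatter classes for the eleven cell panels), every
#' report-flagged gate-tree node (subsets, intermediate gates, activation
#' readouts, Boolean combinations), and the counting-bead population of the
#' absolute-counting panel. With the full 12-panel schema the enumeration
#' totals 208 entries; dropping a panel shrinks it by exactly that panel's
#' entries.
#'
#' @param schemas a schema list from [build_diob_schema()] (or a subset of
#'   its panels).
#' @return data.frame with columns `panel`, `population`, `source`
#'   (`"morphology"`, `"gate"`, `"beads"`).
#' @export
list_reported_populations <- function(schemas = build_diob_schema()) {
  out <- list()
  for (schema in schemas) {
    morpho <- c("All Cells",
                if (schema$id != "P12") c("PBL", "Mo scatter", "Gr scatter"))
    out[[length(out) + 1L]] <- data.frame(
      panel = schema$id, population = morpho, source = "morphology",
      stringsAsFactors = FALSE)
    rep_nodes <- Filter(function(nd) isTRUE(nd$report), schema$tree$nodes)
    if (length(rep_nodes) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        panel = schema$id,
        population = vapply(rep_nodes, `[[`, "", "name"),
        source = "gate", stringsAsFactors = FALSE)
    if (schema$id == "P12")
      out[[length(out) + 1L]] <- data.frame(
        panel = "P12", population = "Beads", source = "beads",
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Sequential major-cell-type classification of the absolute-counting panel
#'
#' Runs the quality-control gates and the strictly sequential exclusion
#' chain of the bead panel on an uncentrifuged acquisition: CD45+
#' leukocytes, then T cells (CD3+), B cells (CD19/CD20+ of the rest),
#' monocytes and granulocytes (scatter, of the rest), NK cells (CD56 and/or
#' CD16+, of the rest) and the remaining Rest of cells / Rest of PBL, plus
#' the CD16 splits of granulocytes (neutrophils vs eosinophils) and
#' monocytes. The majors are mutually disjoint and, together with the final
#' rest, partition the CD45+ leukocytes.
#'
#' @param table a P12 [event_table()] (e.g. from
#'   [simulate_trucount_acquisition()]).
#' @param schema the P12 panel schema.
#' @return population statistics as from [apply_gate_tree()], with the QC
#'   masks attached as attribute `"qc"`.
#' @export
classify_p12_majors <- function(table, schema = build_diob_schema()$P12) {
  stopifnot(schema$id == "P12")
  qc <- qc_gates(table, schema$qc)
  stats <- apply_gate_tree(table, schema$tree, schema$transforms,
                           root_mask = qc$mask)
  attr(stats, "qc") <- qc
  stats
}

#' Profile containing a single pure phenotype
#'
#' Builds a noise-free profile whose only population carries exactly the
#' given marker levels — used to verify that a planted phenotype lands in
#' its intended subset gate and in no sibling gate.
#'
#' @param levels named character vector of marker levels
#'   (`neg`/`lo`/`pos`/`hi`); unlisted markers are negative.
#' @param scatter scatter class of the planted population.
#' @return a profile with one population named `"planted"`, no artifacts,
#'   zero template spread and identity spillover.
#' @export
pure_population_profile <- function(levels, scatter = "PBL") {
  profile <- zero_noise_profile(build_default_profile())
  profile$populations <- list(
    planted = pop_def(1, scatter, levels, list(), major = "Leu"))
  profile
}

#' Plant specification for one monitored subset
#'
#' Returns the pure-phenotype plant for a subset of [subset_definitions()]:
#' the profile, the panel to simulate, and the target/sibling node ids to
#' check.
#'
#' @param subset subset name as in `subset_definitions()$subset`.
#' @return list with elements `profile`, `panel`, `target`, `siblings`.
#' @export
subset_plant <- function(subset) {
  plants <- .diob_plants()
  if (!subset %in% names(plants))
    stop("unknown subset: ", subset)
  sp <- plants[[subset]]
  list(profile = pure_population_profile(sp$levels,
                                         scatter = if (is.null(sp$scatter)) "PBL" else sp$scatter),
       panel = sp$panel, target = sp$target, siblings = sp$siblings)
}
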