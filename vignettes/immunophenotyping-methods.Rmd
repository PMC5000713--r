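---
title: "Methods: models, gates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, gates and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunogate)
```

This vignette documents the science inside `immunogate`: the data model,
the automated analogues of manually drawn gates, the synthetic-blood
generator that stands in for donor samples, and the design decisions taken
where the underlying assay description leaves the implementation open.

## The assay in brief

Twelve 10-color staining panels are acquired from one blood draw. Panels
P01–P03 resolve T-cell subsets (memory phenotypes by CD197/CD45RA, helper
lineages by CD183/CD196, regulatory T cells by CD25hi/CD127−lo, T-cell
receptor classes), P04 resolves six B-cell subsets by CD27/CD38/CD5/CD24,
P05 reads lymphocyte activation markers with CD19 and CD20 pooled into one
channel, P06/P07 resolve NK subsets by CD56/CD16 plus receptor complexes
and pool NKT membership gates, P08 splits monocytes by CD14/CD16, P09
splits CD66+ granulocytes by CD16 into neutrophils and eosinophils, P10
identifies basophils and dendritic cells after lineage-cocktail exclusion,
P11 identifies HSC/EPC/CEC through CD45/CD34/CD133/CD146, and P12 mixes a
known number of fluorescent beads with 50 µL of uncentrifuged blood to
anchor every percentage to an absolute cells-per-µL scale.

Every panel starts from the same morphology QC: a flow-stability gate, two
doublet gates, and the All Cells gate. Percentages are reported relative
to the immediate parent gate, the major cell type and All Cells; absolute
subset counts are the major-type absolutes from P12 multiplied by the
subset's within-major fraction.

## Morphology QC: automated analogues of visual gates

The published gates are drawn by eye; `immunogate` replaces them with
deterministic rules, all configurable through `qc_config()`:

* **Flow gate** — events are binned into 1-s windows; a window is excluded
  when its event count deviates from the median window count by more than
  5 median absolute deviations (Poisson-scale fallback `sqrt(median)` when
  the MAD is zero, e.g. for perfectly flat streams). Acquisitions shorter
  than one window are kept whole, with a warning. There is no numeric
  criterion to inherit for this gate; the MAD rule is this package's
  stand-in and is flagged as such.
* **Singlet gates** — stage one keeps events whose FSC time-of-flight
  (signal width) is within ±25% of the acquisition median; stage two keeps
  events whose FSC area/height ratio is within ±25% of its median.
  Constructed doublets carry summed area and width but single-cell height,
  so the second stage removes doublets whose widths happen to look normal.
  The bands adapt to each acquisition's scatter scale.
* **All Cells gate** — debris (FSC below 80,000) and dying cells (FSC
  below 185,000, the region PI-positive cells shift into) are excluded;
  retained events are labelled PBL / monocyte / granulocyte by side
  scatter (boundaries 30,000 and 85,000) for information only, since
  subset gating runs on all leukocytes. The uncentrifuged counting tube
  shows globally elevated FSC; it uses the same gate with bounds scaled by
  1.15 (`qc_config(fsc_scale = 1.15)`) rather than a separate gate set.
  No dead-cell dye channel is modelled: the reduced-FSC exclusion covers
  dying cells, and a small tail of dying granulocytes that remains above
  the bound is knowingly kept.

## Display transform and compensation

Fluorescence is gated in logicle display space. The biexponential inverse
`S(y) = a·e^{by} − c·e^{−dy} − f` is solved in closed form from the
parameters T (top of scale, default 1,048,576 — the 20-bit digitizer
maximum), M (4.5 decades), W (0.5 decades of linearization) and A (0
additional negative decades); the forward transform inverts it with 22
bisection steps plus 4 Newton iterations, giving round-trip error below
1e−6 relative. Parameters are per channel and per panel, mirroring the
practice of tuning scale settings per parameter. Scatter channels stay
linear.

Compensation solves `observed = true × S` per event for a supplied
spillover matrix S (diagonal 1, non-negative, invertible); estimating S
from capture beads is out of scope, matching the workflow in which the
matrix arrives from instrument QC.

## Gating engine conventions

* All boundaries are half-open `[lo, hi)`. Quadrant cells and hi/lo splits
  are therefore disjoint and partition their parent exactly — an event can
  never sit in two quadrants.
* Gate coordinates live in display space, because that is where the
  original gates were drawn. Raw-space thresholds are converted once, at
  schema build time.
* "hi" versus "lo"/"+" discrimination uses two raw thresholds per marker
  (default 800 for negative/positive, 55,000 for lo/hi), standing in for
  FMO-informed visual boundaries. **These defaults are calibrated to the
  simulator's templates; real data require per-marker, per-panel
  calibration** via `diob_config(marker_cuts = ...)`.
* Boolean gates (`bool_and`/`bool_or`/`bool_not`) evaluate set-wise, so
  pooled membership gates (NKT, the CD19-or-CD20 B gate, the Rest chains)
  count each event once.
* Cross-panel linked gates (the CD3 gate of the T panels; the NK gates of
  P06/P07) are constructed from one shared definition, so their geometry
  is identical by construction.

## Resolved ambiguities in the assay content

Decisions taken where the assay description is internally inconsistent or
silent, recorded here as the package's readings:

* The two pooled-NKT definitions are assigned to panels by marker
  availability: the CD56/CD16/CD314 union to P06 (which carries CD314) and
  the five-way CD94/CD56/CD159c/CD159a/CD16 union to P07 (which carries
  the CD94/CD159 receptors). The labelling of those two definition rows is
  inconsistent in the source material; the channel layout is not.
* pDCs are treated as HLA-DR-positive (DCs are identified by HLA-DR
  expression; the contrary "HLA-DR−" in one definition row is read as a
  typo). The helper-subset chemokine markers are CD183/CD196.
* Transitional B cells require CD24hi (the stricter of the two stated
  levels).
* mDC-2 is gated as the CD1c− fraction of mDC; CD141 is not modelled.
* The 34 immune subsets are: 14 T (TH1/TH2/TH17, TREG,
  naive/effector/EM/CM for both TH and TC, TCRαβ, TCRγδ), 6 B, 3 NK, NKT,
  neutrophils, eosinophils, basophils, 3 DC and 4 monocyte subsets; TH and
  TC themselves count as major-type intermediates. HSC, CEC and EPC are
  the 3 non-immune subsets (37 total). `subset_definitions()` is the
  canonical table.
* The 27 activation readouts are marker-on-cell-type determinations,
  itemized by `activation_readouts()` (CD38 on TH and on TC count
  separately; the CD94/CD159a and CD94/CD159c complexes count as one
  readout each).
* The 208 reported populations per sample are reconstructed as: every
  report-flagged gate node of the 12 panels (162), the morphology
  populations (All Cells for each panel, plus the PBL/Mo/Gr scatter
  classes for the eleven cell panels: 45), and the bead population of P12
  (1). `list_reported_populations()` returns the list; dropping a panel
  shrinks it by exactly that panel's entries. Rare edge populations
  (DNT/DPT and the CD4lo/CD8lo-type gates) are recorded but not
  sub-analyzed.

## Absolute counting

Beads are identified in an FSC-low/SSC-high gate placed so small beads are
not discarded with debris, then confirmed by positive fluorescence in five
channels (FL1–FL4, FL8). Bead singlets and doublets are split at the
valley of the FSC density between the singlet mode and 2.2× its location,
with a 1.5×-mode fallback when too few doublets exist to estimate a
valley. Per channel, `effective = singlets + 2 × doublets`; the mean over
the five channels is the acquired bead count. The cell-side singlet gates
are deliberately not applied to beads — bead doublets must stay countable.
Absolute counts follow
`(cells acquired / beads acquired) × (beads per tube / blood volume)` and
are invariant to the acquired tube fraction, since cells and beads scale
together. Beads per tube and the 50 µL blood volume are configuration
values (`bead_config()`), as bead counts are lot-specific.

Subset absolutes anchor to their major type (T, B, NK, Mo, Gr from P12);
populations without a P12 major (DCs, basophils, non-immune cells) anchor
to the all-leukocyte absolute via their fraction of All Cells.

## Robustness analysis

`cv()` uses the sample (n−1) standard deviation — with three replicates
the population form would understate the spread; the choice is documented
because either reading is defensible. The validity filter excludes a
population when *any* replicate has fewer than 100 events (strictest
reading; a mean-based rule is selectable). CV bins are `<5`, `<10`
(cumulative), `[10, 15)` and `≥15` percent, with boundary values assigned
upward. `replicate_experiment()` computes CVs on each population's
percent-of-All-Cells value, which keeps the closed-form counting-noise
reference `CV ≈ 100·sqrt((1−p)/(p·n))` exact about the denominator;
bead populations use their effective count. Inter-replicate biology is a
lognormal jitter on the leaf frequencies (default sd 0.02 on the log
scale, a modest processing-variation surrogate).

## The synthetic-blood generator

The generator defines the study conditions; its defaults are fixed at the
documented blood composition of healthy donors — T cells 26% of
leukocytes (including 1.5% NKT), B 5%, NK 4% with 90% in the CD56lo/CD16+
subset, monocytes 8% with 85% in CD14hi/CD16−, DCs 0.8%, basophils 1%,
eosinophils 3%, neutrophils the remainder, HSC/EPC/CEC together 0.01%,
dead cells 0.6% of events, debris 2%, doublets 2%, bead doublets 2% of
bead events, 6,000 leukocytes/µL.

Per event, marker intensities are lognormal around four template locations
(neg 50, lo 4,000, pos 20,000, hi 150,000 raw units; shape 0.25) — a
standard approximation that produces realistic logicle displays; the
source material states no intensity distributions, so all template numbers
are implementation defaults, not measured claims. Phenotype axes (memory
quadrant, helper lineage, TREG, receptor complexes, every activation
marker) are joint categorical draws recorded per event, so any gated
statistic can be compared with what was actually planted. Doublets are
sums of two singlets' integral signals with summed time-of-flight and
maximum peak, matching the discrimination logic of the two singlet gates.
Scatter classes put lymphoid cells, monocytes and granulocytes at
separated FSC/SSC locations; dying cells halve their FSC. Spillover mixes
the raw intensities through the profile's matrix, and compensation with
the same matrix restores them (to machine precision in the zero-spread
configuration). One master seed spawns a fixed substream per panel, so
adding or dropping a panel never changes another panel's events.

**What the generator does not emulate:** donor-to-donor biology,
instrument drift, autofluorescence (notably of eosinophils), unspecific
antibody binding, fluorochrome degradation, and continuous marker
distributions that straddle a threshold. Passing recovery tests therefore
demonstrates correctness of the gating logic and the counting algebra,
not readiness of the default thresholds for real donor data.

## Numerical and degenerate-input behaviour

Logicle parameters are validated (`T, M > 0`, `0 ≤ W ≤ M/2`, `A ≥ 0`);
the `d`-coefficient root is bracketed in `(0, b)`. Empty event tables
produce empty masks; a zero-mean CV and an empty CV summary are errors, as
are singular spillover matrices, zero acquired beads, truncated FCS DATA
segments and Boolean references to undefined gates. Gate trees are
topologically sorted with cycle/orphan detection. The simulator is
bit-reproducible given `(profile, panel, n_events, seed)`.

## Problem sizes

The test suite exercises single panels at 2,000–60,000 events, full
pipeline recovery at 100,000 events per panel, bead counting at 10,000
beads, and the replicate experiment at 3 × 100,000 events across all 12
panels — sizes chosen so the binomial error bands are tight relative to
the planted effects. With three replicates a sample CV has two degrees of
freedom, so individual populations legitimately scatter around the
counting-noise reference; the consistency check therefore asserts the 3×
band for at least 90% of populations and a median ratio within [1/3, 3],
rather than a per-population hard bound.
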