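---
title: "HistoCyto: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HistoCyto: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

HistoCyto implements quantitative single-cell analysis of multispectral
confocal images of secondary lymphoid tissue in the HistoCytometry style:
segmented nuclei become cytometry-like events carrying the mean intensity
of every channel, events are gated hierarchically into immune phenotypes,
and frequencies are reported within microanatomical compartments --
extrafollicular space (EF), the follicular mantle zone (MZ) and the
germinal-centre light and dark zones (LZ/DZ; GC = LZ + DZ; a follicle is
MZ + GC). The package also estimates and applies spectral spillover
compensation from single-stain control images, quantifies structural areas
(FDC meshwork, collagen-dense and CD31-dense staining), and detects and
classifies RNAscope puncta as cell-associated or FDC-bound.

Because no deposited imaging data accompany this analysis style, the
package ships a ground-truthed synthetic tissue simulator. Every stage of
the pipeline can therefore be validated against known cell phenotypes,
known compartment geometry and known punctum placement. The reference
scene fixtures under `inst/extdata/scenes/` transcribe published
population frequencies into generator compositions, and the acceptance
script re-runs the full pipeline to check that those compositions are
recovered.

```{r}
library(HistoCyto)
fx <- referenceScene("gc_reference", seed = 1)
res <- runPipeline(fx, "gc_reactivity", verbose = TRUE)
res$quant
```

## The synthetic scene model

A scene is a rectangular field (default reference fixtures: 1.4 x 1.4 mm
at 1 um/pixel) containing elliptical follicles placed on a jittered grid
with a guaranteed clearance of at least 50 um between neighbours.
Within each follicle, a concentric ellipse scaled by `sqrt(gc_fraction)`
is the GC; a chord perpendicular to a random polarity axis splits the GC
so that the dark zone holds `dz_fraction` of its area. Everything outside
follicles is EF.

Cells are nuclei placed by minimum-spacing (Poisson-disk style) sampling:
a candidate centre is accepted only if it is at least
`min_spacing_factor * (r_i + r_j)` from every accepted neighbour (default
factor 0.8, mean nucleus radius 3 um, so nuclei may touch but not overlap
deeply). Per compartment the total cell count is `density x area` and
phenotypes are one multinomial draw from the configured composition; true
expression per marker is log-normal with configured mean and CV.
lo/dim/hi biology is encoded as distinct log-normal modes (e.g. CD20:
negative, dim ~220, hi ~600 arbitrary units).

Rendering draws the nuclear stain over each nucleus disk, nuclear-localised
markers (Ki67, Bcl-6, FoxP3, Helios, pH2Ax) over the same disk, and
membrane/cytoplasmic markers over a 1.2 um annulus around the nucleus.
Annulus pixels that fall on a *neighbouring* nucleus are attenuated to
25% ("volume exclusion"): in a thin section a nucleus displaces most of a
neighbour's cytoplasm along the optical axis, so membrane staining painted
at full strength across foreign nuclei is not realistic -- and, more
importantly for a benchmark, it would make dim-expressing cells and
bleed-contaminated negative cells mathematically indistinguishable at the
nuclear-mean readout, defeating the purpose of a recoverable ground truth.
The simulator is calibrated so that its per-event marker distributions
show the separable modes that manual gating of real tissue exhibits.

The optics model is: per-pixel spectral mixing `observed = t(M) true`
with a block-structured spillover matrix (sequential excitation groups of
2-3 fluorophores; no cross-group terms), additive autofluorescence
(default 3 units), Gaussian PSF blur (sigma 0.6 um), Poisson shot noise
(gain 0.5) plus Gaussian read noise (sd 1.5), clipped to 16 bits. The FDC
meshwork is a correlated-random-walk skeleton confined to the GC,
thickened to ~3 px, drawn until the configured coverage fraction of the GC
is reached. RNAscope puncta are Gaussian spots (sigma 0.8 um); sibling
puncta are kept >= 3 um apart so that ground-truth counts are resolvable
at the simulated optical resolution.

What the simulator does *not* emulate -- and hence what passing tests do
not show about real data: tissue autofluorescence texture, fixation and
staining artefacts, uneven illumination and tile seams, 3D nuclear overlap
beyond the thin-section approximation, cell-shape diversity (all nuclei
are disks), and spatial correlation of expression beyond compartment
membership.

## Pipeline stages and the parameters that matter

* **Spillover estimation** (`estimateSpillover`): for fluorophore f,
  foreground = pixels above the `foregroundQuantile` (default 0.995) of
  f's own channel in its single-stain image; the coefficient into channel
  g is the median of per-pixel background-subtracted ratios. Median-of-
  ratios was chosen over least squares because it tolerates residual
  autofluorescence outliers; least squares is available as an option.
  Negative estimates clamp to 0 and the diagonal is fixed at 1.
  Compensation solves the linear system per pixel and clamps negative
  solutions to 0, since downstream gating assumes non-negative
  intensities. Single-stain controls use a uniform phenotype mixture so
  every marker has an abundant positive population to regress on.

* **Segmentation** (`segmentNuclei`): Gaussian smoothing (0.5 um), Otsu
  threshold, hole filling, distance-transform watershed
  (tolerance 0.2) and size filtering (min: circle of radius 2 um; max:
  4x the median component area, which removes merged clumps and signal
  not bound to a nucleus). At the reference densities (2,500-4,000
  cells/mm^2) segmentation recovers counts within ~3-4%; the residual
  deficit is touching-nucleus merges, an expected failure mode at the
  configured packing.

* **Features** (`extractFeatures`): mean intensity per channel over label
  pixels; centroids use the pixel-centre convention (0-based index + 0.5,
  times the pixel size); area is exported as `volume_um2` and circularity
  `4*pi*A/P^2` as `sphericity` to mirror the HistoCytometry spreadsheet
  vocabulary; the perimeter uses a two-direction Crofton estimate, which
  carries less pixelation bias than boundary-pixel counting.

* **Compartments** (`buildCompartmentMap`): staining density = channel
  smoothed at `density_sigma_um` (default 16 um; at 1 um/px the kernel
  then averages over enough cells that within-region variance does not
  fragment the masks). The follicle mask thresholds the CD20 density at
  the lo/dim boundary of a robust 3-class split (iterated-median centres;
  the cut is the midpoint of the lo and dim centres, which places the
  boundary at the half-height of the density step). GC = Ki67-dense
  region within follicles (same rule, computed over follicle pixels),
  after a 6 um morphological opening; DZ = the largest connected region
  above an Otsu sub-threshold of Ki67 density inside the GC (the LZ/DZ
  split is bimodal); MZ = follicle minus GC. Follicle and GC masks are
  eroded by a border clearance (defaults 8 and 20 um) before labelling:
  compartment scopes are deliberately biased towards well-defined
  interior tissue, the deterministic analogue of restricting analysis to
  unambiguous localities, at the cost of a slightly smaller mask
  (follicle-mask Jaccard against the true ellipses ~0.87). Components
  below `min_follicle_area_um2` (3e4) are dropped. Panels that lack CD20
  (the RNAscope panel) detect follicles as the *low*-density regions of
  the summed CD3 + CD4 channels, and use the FDC channel as the GC
  landmark. A T-cell-zone mask (CD4-dense EF space) supports
  Treg denominators.

* **Thresholds** (`deriveThresholds`): no numeric cuts are published for
  this kind of data, so cutpoints are derived from each scene's own event
  table. Methods per channel: `gmm` (2-3 component mixture on log1p,
  posterior-equality cuts); `kde` (cuts at density-valley minima between
  the dominant modes -- robust to the "bridge" of intermediate values that
  neighbour bleed-in creates); `cluster` (k-class 1D clustering with cuts
  at class-centre midpoints); `background` (median + k*MAD on log1p, for
  markers whose positive population is too rare for any mixture to be
  identifiable; k = 11 for membrane markers, whose bleed-in tails are
  heavier, and 4.5 for nuclear markers); and `background+gmm` (background
  lo cut, then a mixture on the expressing subset for the dim/hi cut --
  used for PD-1, where the hi mode is rare overall but well represented
  among expressing cells). Because ambient staining differs strongly
  between EF, MZ and GC, the pipeline derives the mode-based cuts
  separately within each compartment context (`scopedGates = TRUE`),
  mirroring per-locality manual gating. Mixture fitting is seeded so a
  given event table always yields the same cuts.

* **Gates** (`applyGates`): a cell belongs to a node iff it satisfies the
  node's predicate and all ancestors. "+" means above the (lo) cut,
  "hi/dim" above the lo cut, lo/dim/hi refer to the 1-2 cutpoints; ties at
  a cutpoint go to the upper level (deterministic "> threshold" reading).
  Feature terms (e.g. `volume_um2 >= median`, the live-cell size filter
  used with pH2Ax) evaluate on event-table columns; the default size cut
  is the population median area. The shipped panels make B-cell gates
  exclude CD4+ events and T-cell gates exclude CD20-expressing events
  (sequential exclusion gating), which suppresses bleed-in false positives
  in crowded compartments at a modest recall cost.

* **Quantification** (`quantifyPopulations`): frequencies per (population,
  scope) with denominators "total", "parent" or any named population;
  both the whole-follicle and the GC-only CD4 denominator of the Tfh
  frequency are supported, reproducing the dual definition used for
  follicular helper cells. Densities divide by the total tissue area
  (nuclear staining density above a presence threshold). Zero denominators
  yield missing frequencies, never errors.

* **RNAscope** (`detectSpots`, `classifySpots`, `reportVrna`):
  scale-normalised difference-of-Gaussian blob detection over sigma 0.5 to
  1.2 um, response threshold 20, greedy non-maximum suppression at
  1.8 um. A spot is cell-associated when its centroid falls in a nuclear
  label dilated by 1.5 um (a cytoplasmic rim -- vRNA is cytoplasmic while
  nuclei are what is segmented), else FDC-bound when on the FDC-dense
  mask, else unassigned; cells take precedence over the mesh. A cell is
  vRNA+ when it owns at least one spot (default) or by an intensity gate
  (both modes supported and recorded). Detector defaults are
  fixture-tuned and exposed as parameters.

## Numerical choices and degenerate inputs

Scene generation, rendering, threshold derivation and the pipeline all
draw their randomness from seeds derived from one scene seed, so identical
configuration and seed give identical outputs to the byte. Blank channels
yield empty label maps, all-EF compartment maps or empty spot sets with
warnings rather than errors; constant channels direct the user to fixed
cuts; composition maps that do not sum to 1, fields too small for the
requested follicles, and mismatched channel orders raise immediate
validation errors naming the offending component. Gaussian blurring uses
FFT filtering with circular boundary handling; scenes keep dark margins so
wrap-around is immaterial.

## Problem sizes

The reference fixtures use 1.4-1.6 mm fields with ~6,000-8,000 cells and
six follicles per scene; the acceptance script runs five scenes per
fixture plus one single-stain control set per panel. These sizes were
chosen so that binomial sampling error on the rarest reported populations
(0.1-0.3% of CD4 cells) stays well inside the reporting tolerances while a
full fixture sweep remains a desk-scale computation. Unit tests use
smaller fields (0.3-1.3 mm) with the same densities.

## Known limitations

* Touching nuclei merge at a ~3-4% rate at reference densities; merged
  events carry mixed signals.
* The nuclear-label mean is a scaled-down readout for membrane markers
  (PSF bleed-in of the annulus), so absolute intensities are not
  comparable between nuclear and membrane markers; thresholds are derived
  per channel, so gating is unaffected.
* Compartment boundaries are uncertain at the density-smoothing scale;
  border-clearance erosion trades mask area for scope purity. Frequencies
  of populations that concentrate near boundaries will be biased
  accordingly; in particular the Tfh share of follicular CD4 runs
  ~2-3 pp high because mantle-zone CD4 events suffer more bleed-in
  exclusion than GC Tfh.
* The RNAscope detector cannot resolve puncta closer than roughly the
  blurred punctum diameter; the generator keeps ground-truth puncta
  separable, real clustered dots would be merged.
* Thresholds are per-scene and data-driven; they are recovery tools for
  the simulator's conditions, not calibrated absolute gates for real
  instruments.
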