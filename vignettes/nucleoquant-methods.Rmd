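---
title: "Methods and design notes for nucleoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for nucleoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nucleoquant quantifies four kinds of experiment around nucleolar biology —
DNA-damage foci in fixed nuclei, nascent-RNA signal inside nucleolar
fibrillar centres, nucleolus-to-nucleoplasm ratios in treatment time
lapses, and in vitro droplet (phase-separation) assays — plus the small
biophysical calculations that typically accompany them. This vignette
records the models, the tunable parameters and why their defaults are what
they are, the numerical decisions, and what the bundled synthetic-scene
generator does and does not establish about real data.

## Conventions

All rasters are R matrices/arrays indexed `[y, x]` (2D) or `[y, x, z]`
(3D), with 1-based indices — the package keeps R's native convention
rather than 0-based coordinates, and all reported centroids and label
positions follow it. Image stacks are canonicalised to a 5D array
`[y, x, z, channel, t]` with singleton axes, so one code path serves 2D,
3D and time-lapse data. Intensities are processed as doubles in arbitrary
units; TIFF round trips store 32-bit floats with a recorded scale and
offset, so serialisation is faithful to float32 precision (~1e-7
relative).

## Nucleus segmentation

`segment_nuclei()` is a deterministic classical segmenter: Gaussian smooth
(σ = 2 px), Otsu threshold on the min–max-normalised image, hole filling,
distance-transform watershed to split touching nuclei, and a minimum-area
filter (200 px in 2D, 2000 voxels in 3D; both configurable). Normalising
before thresholding makes label counts invariant under global intensity
rescaling. Studies of this kind typically use trained models (Cellpose,
Ilastik); trained weights are not distributable inside a source package,
so the classical path and an external-mask ingestion path
(`load_external_labels()`, integer TIFF) sit behind the same contract —
substituting the original models is a one-line change for the user.
Connectivity is 4-connected in 2D and 6-connected in 3D; watershed ties
resolve toward the lower label so results are reproducible.

## Foci detection

The focus channel's maximum projection is convolved with an analytic
Laplacian-of-Gaussian kernel (σ = 3 px, radius 4σ, forced zero-sum so a
constant image yields an exactly zero response). The raw LoG of a bright
blob is negative at its centre; the response is therefore negated by
default (`log_sign = "negated"`) so that the thresholding rule — binarise
at mean + 1.5 SD of the response over the whole image — selects spot
cores. The literal un-negated alternative is available behind the flag. A
morphological opening with a 3×3 all-ones element removes specks,
8-connected components are measured on the original projection, and a
focus belongs to a nucleus when its centroid lies inside the label
("centroid containment" is the deterministic reading of in-nucleus
restriction). Threshold statistics over the whole image are the default;
`threshold_scope = "nuclei"` restricts them to nuclear pixels.

Two properties matter for interpretation. First, the threshold is
signal-referenced: the SD of the response is dominated by the spots
themselves at realistic focus densities, which places the cut well above
the noise floor. Second, on a *signal-free* channel containing only i.i.d.
noise the same rule necessarily marks ≈ 6 % of pixels, and noise blobs at
the filter scale can survive a 3×3 opening — a limitation shared by any
global mean-plus-k·SD rule. A blank (zero-signal) channel is handled by
the degenerate path: when the response spread is numerically zero relative
to the input scale, the detector warns and returns zero foci. Nuclei
touching the image border are flagged and excluded from summaries by
default.

## Fibrillar-centre segmentation and EU quantification

The DFC is segmented by an Otsu threshold computed on fibrillarin
intensities restricted to nuclear voxels, refined by a binary opening
(6-connected cross element in 3D) and re-intersected with the nuclei. A
spatially uniform fibrillarin signal gives a degenerate histogram; the
function warns and returns an empty mask rather than inventing structure.

FC seeds are local maxima of a difference-of-Gaussians (σ = 1, 2 px —
matched to FC radii of a few pixels; configurable) inside the DFC. The
reference distribution for seed filtering is the set of DoG local-maxima
values in the nucleoplasm (nucleus minus DFC) — maxima values, not raw
voxels, so the reference has the same sampling bias as the candidates —
and seeds must exceed its mean + 1 SD. Surviving seeds grow by a seeded
watershed flooding the UBF intensity from bright to dim, confined to the
Otsu foreground of the UBF channel intersected with the DFC: the Otsu
region is the spatial stop criterion, and DFC confinement guarantees the
containment chain FC ⊆ DFC ⊆ nucleus voxelwise. Ties between basins
resolve to the lower label; the label count always equals the surviving
seed count.

Per cell, the EU (nascent RNA) readout is the mean intensity over the
union of that cell's FC voxels — one value per cell. Cells with no FC get
`NA`, not zero, so they drop out of group means instead of biasing them.
Normalisation divides by the control-group mean (the control-group mean
maps to exactly 1); the choice of mean over median is a default, recorded
here because either is defensible.

## Live-cell ratios and onset statistics

Nucleoli are detected in phase contrast as dark compact objects within
each nucleus: the nucleus crop is background-neutralised (non-nuclear
pixels set to the nuclear median so smoothing cannot bleed the background
across the boundary), smoothed (σ = 1.5 px), inverted and
Otsu-thresholded per nucleus. A contrast guard requires the dark class to
sit at least 10 % below the bright class mean — without it, Otsu happily
splits pure noise in nucleolus-free nuclei. Identity across frames is
maximum mask overlap with the previous frame (ties: larger overlap, then
lower track id); linking is not described in typical methods sections, so
this deterministic rule is the package's own.

The ratio is mean fluorescence over nucleolus pixels divided by mean
fluorescence over the parent nucleoplasm (nucleus minus all its nucleoli),
which cancels any global linear intensity change of a frame. Rule-based
`exclude_objects()` (area collapse > 40 % between frames, extreme
eccentricity, optional bounds) stands in for trained object classifiers
that remove dividing and dying cells.

`rm_anova_onset()` fits the classical split-plot ANOVA by direct
sum-of-squares arithmetic: the group effect is tested against
subjects-within-groups, time and time×group against the within-subject
residual. The implementation is the textbook decomposition (weighted cell
means, so unequal group sizes are handled); `stats::aov` serves as an
independent cross-check in the tests, and `stats::TukeyHSD` validates the
per-frame contrasts. Subjects are nucleoli with complete tracks;
incomplete tracks are dropped and counted rather than imputed. Sphericity
is uncorrected by default — for a balanced design with i.i.d. within-cell
noise the uncorrected test is exact — with Greenhouse–Geisser available
(`sphericity = "greenhouse-geisser"`, ε estimated from the pooled
within-group covariance and clamped to [1/(t−1), 1]). The onset is the
earliest frame whose Tukey-adjusted group contrast falls below α, reported
only when the interaction or group main effect is itself significant —
per-frame contrasts alone would otherwise multiply tests without a gate.
Whether ratios should enter per nucleolus or be aggregated per cell first
is genuinely open; the default is per nucleolus with `cell_id` retained so
users can aggregate.

## Droplet quantification

The adaptive threshold is the Bradley local-mean rule: a pixel is
foreground when its intensity is at least `k·μ_W`, with `μ_W` the mean
over a `neighbourhood × neighbourhood` window (99 px default, symmetric
edge padding via an integral image) and `k = 2·(1 − sensitivity)` so the
conventional sensitivity of 0.4 demands 120 % of the local mean. The
mapping of a [0, 1] "sensitivity" onto a single multiplicative factor is
the package's own calibration of a proprietary routine's parameter; both
`k` and the rule are configurable. Before thresholding, a 3×3 median
despeckle (`median_radius = 1`, 0 disables) suppresses pixel noise without
displacing droplet boundaries — an edge-preserving alternative to Gaussian
smoothing chosen so partition ratios are not diluted by blurred edge
pixels; intensities are always measured on the unfiltered image.
Foreground components and background holes below 5 px are removed (the
dual speckle cleanup), droplets are labelled 8-connected.

Condensed fraction is the exact pixel-count ratio of mask to image.
Partition ratios divide each droplet's mean intensity by the mean over all
non-droplet pixels, computed once per field; the probe channel is measured
under the protein-channel mask, so protein and probe enrichment refer to
identical regions. Any per-condition normalisation of condensed fractions
(e.g. to a within-experiment maximum) is presentation, kept separate from
the raw values.

## Biophysical utilities

* `csp()` is Δδ = √(ΔδH² + (0.2·ΔδN)²); the 0.2 factor rescales ¹⁵N
  dispersion onto the ¹H scale. Exact, vectorised, symmetric in sign.
* `flag_binding_residues()` flags volume loss strictly greater than 2/3
  and shifts strictly above the mean CSP — strict inequalities so that
  boundary cases (exactly 2/3; all shifts equal) flag nothing.
* `molar_concentration()` is c = n/(N_A·V) with V in µm³ (10⁻¹⁵ L),
  returned in µM.
* `isoelectric_point()` solves Z(pH) = 0 by bisection to |Z| < 1e-4 on
  pH ∈ [0, 14], with EMBOSS-style pKa values by default and a
  Bjellqvist-style set or a custom table selectable. Published pKa sets
  differ by tenths of a pH unit, so cross-tool comparisons of pI carry
  roughly ±0.3 tolerance.
* `scan_g4()` enumerates all windows ≤ 20 nt matching four equal-length
  G-tracts (g ≥ 2, loops ≥ 0, loops may contain G) and collapses
  overlapping candidates greedily by largest G-group, then shortest
  length, then smallest start. The deterministic collapse approximates
  highest-score-first selection of scoring-based tools; a numeric scoring
  hook (`score_fun`) can replace the ranking, but counts from external
  scorers are approximated, not guaranteed. Region counting assigns
  retained hits by start position against non-overlapping 1-based
  intervals (BED-style files are converted on read).

## The synthetic-scene generator

Every pipeline is exercised against `gen_*` scenes whose ground truth is
closed-form from the painted geometry: ellipse/ellipsoid nuclei with
smooth interior shading, Gaussian foci with SNR defined as amplitude over
noise σ, nested DFC/FC ellipsoids with programmable EU levels, time lapses
in which the nucleolar ratio follows r(t) = 1 + (r0 − 1)·e^{−(t−t0)/τ}
after onset while the total nuclear intensity of each cell is held
constant before noise (signal redistributes, it does not disappear), and
droplet fields of non-overlapping disks with programmed enrichments.
Noise is additive Gaussian by default with optional Poisson; seeds are
explicit arguments and the same seed reproduces arrays byte for byte, with
no global RNG state touched.

Defaults are chosen to emulate dense stem-cell colonies at spinning-disk
scale: nuclei with 24–30 px semi-axes, foci σ = 3 px at SNR 10, fields of
tens of nuclei. Foci within a nucleus are kept ≥ 4σ apart so that the
programmed count is resolvable — the generator defines *resolvable* truth,
and detector tests measure recovery of that truth.

What the generator does **not** emulate: realistic point-spread functions
(blur is Gaussian), camera-specific noise calibration, chromatic shifts,
autofluorescence textures, cell-to-cell expression variability, or
photobleaching. Passing recovery tests therefore demonstrates that the
algorithms are correct implementations with the claimed statistical
behaviour on data satisfying their assumptions — not that they reproduce
any particular instrument's images. The classical nucleus/nucleolus
segmenters especially will behave differently from trained models on real
micrographs.

## Problem sizes and numerical choices

The test-suite and acceptance runs use sizes chosen to finish in minutes
on one CPU while keeping estimates stable: 2 × 25 nuclei at 600² px for
foci recovery, 8 fields of 5 cells at 224×224×9 voxels for the EU
pipeline, 1000 null replicates of 2 × 10 subjects × 8 frames for the
type-I simulation, 2 × 5 cells × 48 frames at 256² px for onset
localisation, and 20–30-droplet fields at 512² px. Watershed flooding
discretises intensities into 64 level sets inside each mask component's
bounding box; Otsu uses 256 histogram bins and returns +∞ on zero-range
input so degenerate cases select nothing; bisection tolerances are stated
with each function. Components are always numbered in raster-scan order of
first occurrence, and all ties (watershed basins, overlap links, G4
collapse) break toward the smaller index, so outputs are reproducible to
the byte.

## Known limitations

* The global mean + k·SD foci threshold has no false-positive control on
  signal-free noisy channels (see above); counts from very sparse, dim
  fields should be treated with care.
* 3D nucleus splitting uses the projected 2D watershed applied slice-wise,
  adequate for monolayers but not for nuclei stacked in z.
* The RM-ANOVA assumes complete, balanced-in-time tracks and drops the
  rest; heavily incomplete tracking data would deserve a mixed-effects
  model instead.
* `scan_g4()` counts pattern matches; without the external scoring
  formula, per-region counts approximate scoring-based tools only.
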