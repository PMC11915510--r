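# nucleoquant

Quantification pipelines for studying nucleolar protein trafficking and
biomolecular condensation from fluorescence microscopy, with a
ground-truthed synthetic-scene generator that makes every stage testable
without any external imaging data.

The package is aimed at cell biologists quantifying (i) DNA-damage response
foci (γH2AX / 53BP1) in fixed cells, (ii) nascent rRNA transcription inside
nucleolar fibrillar centres (EU labelling), (iii) the redistribution of a
nucleolar protein into the nucleoplasm during drug treatment in live-cell
time lapses, and (iv) in vitro phase-separation (droplet) assays — plus the
small biophysical computations that accompany such studies (NMR chemical
shift perturbation, molecule-count → molarity conversion, protein pI, and
RNA G-quadruplex motif scanning).

## What it computes

**Foci counting.** Maximum projections of the focus channel are filtered
with a Laplacian of Gaussian (σ = 3 px), thresholded at
*t* = mean + 1.5·SD of the (negated) filter response over the whole image,
binarised, cleaned by a morphological opening with a 3×3 all-ones element,
and labelled 8-connected. Only foci whose centroid falls inside a nucleus
(Otsu/watershed segmentation of the nuclear dye, or an imported mask from an
external tool such as Cellpose) are tabulated with area and mean intensity.
Because *t* is a linear statistic of a linear filter, the detected set is
invariant under global intensity rescaling.

**Nucleolar substructure and nascent RNA.** In 3D stacks, the dense
fibrillar component (DFC) is an Otsu threshold of the fibrillarin channel
inside nuclei, refined by binary opening; fibrillar centres (FCs) are
difference-of-Gaussians seeds filtered against the distribution of
nucleoplasmic maxima (keep seeds > mean + 1·SD of that reference) and grown
by a seeded watershed confined to the UBF Otsu foreground within the DFC.
The per-cell mean EU intensity over FC voxels, normalised to the
control-group mean, reports transcriptional inhibition (a treated/control
ratio of 0.6 = a 40 % reduction in nascent RNA).

**Live-cell ratio and onset statistics.** Per frame, nuclei are segmented
from fluorescence and nucleoli as dark compact bodies in the masked phase
contrast; each nucleolus is tracked by maximal mask overlap and its
mean fluorescence is divided by the mean over the parent nucleoplasm
(nucleus minus nucleoli). Group divergence over time is tested with a
two-way repeated-measures (split-plot) ANOVA — between factor *group*,
within factor *time* — with per-frame Tukey-HSD-adjusted contrasts; the
first frame with adjusted *p* < α (gated on a significant interaction or
group effect) is the onset estimate.

**Droplet assays.** The protein channel is binarised with a Bradley-style
adaptive local-mean threshold (window 99 px, sensitivity 0.4 → pixel ≥ 120 %
of its local mean), speckles < 5 px removed in foreground and background.
Condensed fraction = droplet area / image area; partition ratio = mean
intensity inside each droplet / mean background intensity, with the probe
(647) channel measured under the protein (488) mask.

**Biophysics.** Δδ = √(ΔδH² + (0.2·ΔδN)²) for HSQC chemical-shift
perturbations with volume-loss (> 2/3) and above-mean-shift flags;
c = n/(N_A·V) molarity conversion (1 µm³ = 10⁻¹⁵ L); Henderson–Hasselbalch
pI by bisection; and a G-quadruplex scanner for G₄ motifs
`G{g} N* G{g} N* G{g} N* G{g}` with g ≥ 2 within ≤ 20 nt, with deterministic
collapse of overlapping candidates and per-region counting.

## Worked example

```r
library(nucleoquant)

# a synthetic field: 6 nuclei, 5 programmed foci each, SNR 10
f <- gen_foci_field(n_nuclei = 6, foci_per_nucleus = 5, spot_sigma = 3,
                    snr = 10, shape = c(360, 360), seed = 42)
nuclei <- segment_nuclei(get_channel(f$stack, "dye"))
foci   <- detect_foci(get_channel(f$stack, "foci"), nuclei)
summarize_foci(foci, grouping = "mock", include_border = TRUE)$per_condition
#> # A tibble: 1 × 7
#>   condition n_nuclei mean_count sd_count sem_count mean_focus_area ...
#> 1 mock             6          5        0         0            71.3

# a droplet field with programmed enrichment 5 and probe partition 3
d <- gen_droplet_field(n_droplets = 25, protein_enrichment = 5,
                       probe_partition = 3, noise_sd = 2, seed = 7)
q <- quantify_droplet_field(d$stack, probe_channel = "cy647")
q$condensed_fraction
#> [1] 0.02449226
head(q$droplets, 3)
#>   droplet_id  area protein_partition probe_partition
#> 1          1   240              5.00            3.00

csp(0.3, 1.0)                                  # 0.360555 ppm
signif(molar_concentration(0.35e6, 2425), 1)   # 0.2 uM
signif(molar_concentration(7e6, 1198), 1)      # 10  uM
```

The recovered mean count equals the programmed 5 foci per nucleus, the
condensed fraction matches the summed disk areas, and the partition ratios
reproduce the programmed enrichments — the generator records this ground
truth in a `scene_truth` object alongside every stack.

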