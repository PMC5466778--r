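---
title: "Quantifying nascent-transcript FISH dots in syncytial muscle fibres"
author: "fibreFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nascent-transcript FISH dots in syncytial muscle fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibreFISH)
```

## The measurement problem

Drosophila body-wall muscles are syncytia: a founder cell (FC) carrying a
muscle-specific identity programme fuses with naive fusion-competent
myoblasts (FCMs), whose nuclei are then reprogrammed inside the shared
cytoplasm. FISH against *intronic* probe sequences marks active
transcription as a diffraction-limited nuclear dot at the gene locus, so the
set of dots in a fibre is a snapshot of which nuclei are transcribing a gene
at fixation time. Three quantities summarise such images:

* the **number of dots per muscle** and the **integrated density**
  (IntDen, the sum of pixel intensities over the dot ROI) of each dot,
  plus their per-fibre sum (Total IntDen);
* for two-colour FISH, the per-nucleus **co-transcription table**
  (A only / B only / both / neither);
* the **position** of dots and nuclei within a standardised muscle frame,
  classified into antero-ventral, central and postero-dorsal subdomains.

fibreFISH implements this measurement chain as reusable, tested code, and
pairs it with a synthetic image generator so every stage can be validated
against ground truth without any microscopy data.

## The dot-quantification chain

The measurement follows a fixed order, mirroring the classical
ImageJ workflow (Sum-slices projection, threshold, Analyse Particles,
Image-Calculator AND with the muscle ROI):

1. `projectStack(stack, "sum")` — per-pixel sum over Z. Intensity work is
   done on the sum projection; spatial work uses the max projection.
2. `thresholdDots(projection, t)` — strict threshold (pixel kept iff
   value > t; ties at t are background, a convention that must be fixed
   one way and is logged in the mask's `threshold` attribute). `t` is an
   absolute per-probe value, or an automatic method: `"otsu"` or
   `"background_2sd"` (median + 2 SD). Automatic methods refuse constant
   images, where no dots are inferable.
3. `labelParticles(mask, minArea)` — 8-connected components (the common
   particle-analysis convention), area-filtered, deterministically ordered
   by top-most then left-most pixel. Connected-component labelling is
   implemented in-package by vectorised label-minimum propagation because
   the installed image library labels 4-connected neighbourhoods.
4. `intersectWithMuscle(regions, muscleMask)` — the "AND" of the dot mask
   with the muscle mask, resolved per dot by the membership of its
   *centroid pixel*, so a dot straddling a muscle boundary is counted in
   exactly one muscle and never twice.
5. `zFilter(regions, zExtent, stack)` — an automated proxy for the manual
   curation that removed dots above or below the muscle of interest: a
   dot's Z-peak (argmax over slices of the summed intensity on its
   footprint) must lie within the fibre's slice range ± 1 slice.
6. `measureIntDen(projection, region)` — the exact pixel sum over the
   region, on the sum projection (measurement on the projection is taken
   as written in the source workflow; per-slice measurement is not
   offered).

Two detection profiles exist because the two experimental settings used
different rules. The **standard** profile (absolute threshold, minimum area
2 px) serves single-gene stage-course quantification, where intensities
matter. The **permissive** profile (background + 2 SD, minimum area 1 px)
serves double-FISH counting, where *all* dots count, even small and weak
ones, and intensities are not analysed.

## Per-nucleus tabulation

`segmentNuclei()` thresholds the nuclear channel (Otsu by default) and
splits touching nuclei by watershed on the distance transform — the
standard DAPI recipe. `assignDots()` maps each dot to a nucleus by
containment of its centroid pixel first, otherwise to the nearest nucleus
centroid within 1.5 × the median nucleus radius (the attribution was done
by eye in the original workflow; the distance rule is this package's
explicit, configurable stand-in). A nucleus is **ON** for a gene iff at
least one dot is assigned — sister-chromatid or allelic dot pairs still
count one transcribing nucleus. `tabulateCotranscription()` returns the
exact four-way partition and the two derived fractions, `active` and
`co_given_active`.

## The standardised DA3 frame

Late stage-14 DA3 has an angled shape with stereotyped attachments, which
supports a reproducible internal frame. From the muscle region,
`computeFrame()` takes the area \(A\), the centroid \((X_c, Y_c)\) and the
bounding rectangle; the anchors BRant (bottom-left corner) and BRpost
(top-right corner) mark the anterior-ventral and posterior-dorsal limits.
Each point is centred and sign-flipped in Y (image y grows downward while
anatomical dorsal is up):

\[ \Delta X = X - X_c, \qquad \Delta Y = -(Y - Y_c), \]

then scaled to a fixed reference area, keeping the conventional factor 100:

\[ \mathrm{std}\Delta X = 100\,\Delta X / A, \qquad
   \mathrm{std}\Delta Y = 100\,\Delta Y / A . \]

Standardised units are therefore *not* scale-free: rescaling an image by
\(s\) multiplies \(\Delta\) by \(s\) and \(A\) by \(s^2\), so standardised
values scale by \(1/s\) — a property the test suite asserts explicitly.
The subdomain rule uses cut-offs at −1 and +1 standardised units:
antero-ventral when \(\mathrm{std}\Delta Y < -1\); otherwise
postero-dorsal when \(\mathrm{std}\Delta X > +1\); otherwise central.
The stated rule leaves two situations open, which this package resolves
explicitly and configurably: when both conditions hold, antero-ventral
takes priority, and boundary equalities (exactly −1 or +1) fall to central,
matching the rule's strict inequalities. Worked example: a
point at (54, 28) in a frame with centroid (50, 30) and area 200 gives
\(\Delta X = 4\), \(\Delta Y = 2\), standardised (2, 1): postero-dorsal.

`orientAndCrop()` aligns a fibre's principal axis with the X axis before
frame computation for inputs not already oriented along the
anteroposterior axis; nearly isotropic regions fall back to the identity
rotation with a warning.

## The synthetic generator

The generator emulates the *statistical* structure of the biology, not the
cell biology of fusion:

* **Geometry.** Two templates: a straight band (200 × 30 px) for
  elongated muscles whose outline enters no statistic, and an angled
  parallelogram (length 200 px, vertical rise 150 px, vertical thickness
  28.2 px) for DA3. Nuclei (radius 6 px) are placed by rejection sampling
  with a minimum centre separation of 15 px inside the radius-eroded
  outline; unsatisfiable packings fail loudly. Nuclei counts per stage
  default to 1/4/7/10/12 for stages 12–16 (a single founder nucleus
  before fusion, growing through the fusion phase; dorsolateral muscles
  get similar counts). These counts are configuration defaults calibrated
  to the qualitative growth narrative, not asserted literature values.
* **States.** Per-nucleus per-gene Bernoulli bursting with stage-specific
  probabilities models stochastic, asynchronous transcription.
  FC-restricted genes (Kr; Con in DA3) can be ON only in the FC nucleus.
  Genes in an exclusion group (the FCM gene *sns* versus *col*/*duf*) are
  never jointly ON; enforcement is sequential in gene order, so the
  first-listed gene keeps its exact marginal while later ones are
  conditionally suppressed. The *duf*/*col* pair draws from an explicit
  joint table, `{both 0.4, duf-only 0.2, col-only 0.2, neither 0.2}`:
  the reported 80% union with 50% co-transcription among active nuclei
  is infeasible under independent bursting (the marginals would need to
  sum to 1.2 while multiplying to 0.4), so a correlated joint law is the
  minimal model that reproduces both numbers — a modelling choice of this
  package, flagged as such.
* **Intensities.** Dot intensities are gamma-distributed (mean 20000
  arbitrary units, CV 0.2 by default); the FC dot mean is multiplied by
  the configured fold factor (9 for *col* at stage 14). The spot is an
  isotropic 2-D Gaussian (σ = 1.5 px, patch cut at 4σ) spread across the
  fibre's Z range with a Gaussian slice profile; the patch is normalised
  so the rendered pixel sum equals the drawn intensity exactly before
  quantisation, keeping intensity conservation testable.
* **Noise and quantisation.** Poisson shot noise and Gaussian read noise
  are available but off by default, so correctness tests run on clean
  images first and robustness can be probed separately. Channels are
  quantised to integer grey levels (as a detector would produce), which
  also makes 16-bit TIFF round trips bit-exact.
* **Lineage mixing.** Each nucleus is independently labelled with the
  configured probability (0.5 in the packaged DA3 configuration),
  emulating recruitment from a myoblast pool in which about half the
  cells carry a heritable marker. The founder nucleus participates in the
  mixing too, so the configured probability is the population fraction.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: optical aberrations and a realistic PSF,
chromatic shifts between channels, uneven illumination and embryo
autofluorescence, segmentation-hostile nuclear crowding, curved or
out-of-plane fibres, and fusion dynamics over time. Results on synthetic
data validate the *measurement chain*, not the microscope.

### Calibration of the DA3 positional model

For the Con experiment the FC position is drawn uniformly over the eroded
DA3 outline. For the parallelogram template, writing \(a\) for the
half-range of \(\Delta X\) of admissible positions, \(s\) for the slope and
\(c = A/100\) for the subdomain cut in pixels, the class probabilities have
the closed form \(P(\mathrm{AV}) = (a - c/s)/2a\),
\(P(\mathrm{PD}) = (a - c)/2a\), so
\(P(\mathrm{central}) = c(1+s)/(2as)\). The template dimensions (length
200 px, margin 10 px, slope 0.75, thickness 28.2 px, hence \(A = 5640\),
\(c = 56.4\), \(a = 94\)) were chosen so these evaluate to exactly 10%,
20% and 70% — the central fraction reported for Con — in continuous
geometry. Pixel discretisation of the mask shifts the measured area, and
hence these fractions, by well under one percentage point; the test suite
checks the pipeline's estimate against a pixel-exhaustive oracle of the
same template rather than against the closed form.

## Statistics

Summaries follow the supplementary-table convention: mean, SD (n−1), SEM,
minimum and maximum per muscle/gene/stage. Group comparisons use the
unpaired two-sample *t* test (pooled variance by default, since the
instrument the numbers came from defaults to it; Welch available by flag)
and Pearson's χ² on active/inactive counts (no continuity correction,
df = k−1), with the star convention (*** iff p < 0.001). No
multiple-testing correction is applied, matching the original analysis;
the report notes this. Both statistics are delegated to R's `t.test` and
`chisq.test` and are cross-checked in the test suite against direct
textbook-formula evaluations.

## Parameter recovery as the acceptance standard

Because the original numbers derive from proprietary confocal images, the
package's acceptance standard is *parameter recovery*: each packaged
configuration (`presetNames()`) encodes its reference summary statistics as
generator parameters, and the full pipeline — render, detect, assign,
tabulate — must recover them from the images alone. `scripts/acceptance.R`
runs cohorts of 200–400 fibres per statistic (chosen so each run completes
in well under five minutes while keeping binomial standard errors at a few
percent) and reports:

| statistic | configuration | encoded value |
|---|---|---|
| FC / syncytial col IntDen ratio, stage 14 | `da3_col_stage14` | 9-fold |
| S59 active nuclei, stage 15 | `dt1/va2/vt1_s59_stage15` | 45 / 27 / 23% |
| mean kon dots per DT1 fibre, stage 15 | `dt1_kon_stage15` | 4.35 |
| mean Pax dots per fibre, stage 15 (course maximum) | `pax_stage_course` | 2.5 |
| duf/col union; co-transcription among active | `da3_dufcol_stage14` | 80%; 50% |
| Con dots in the central subdomain | `da3_con_stage14` | ~70% |
| Kr dots per fibre | `kr_stage13` | exactly 1 |
| lineage-labelled nuclei in DA3 | `da3_rfp_stage15` | 50% |

Numerical design choices that make the recovery faithful rather than
lucky: integrated density is measured over a *thresholded* footprint, so
the sub-threshold Gaussian tail is lost; with the default bright dots
(mean 20000 AU) and a low absolute threshold (2 AU on a noise-free
background) that loss is below 1.1% and nearly cancels in the FC ratio.
The minimum nucleus separation (15 px) keeps the super-threshold
footprints of neighbouring dots disjoint, so well-separated ground-truth
dots are counted one-to-one. Both margins are derived in closed form from
the Gaussian spot model.

## Known limitations

* Dot centroids are binary-footprint centroids; no sub-pixel Gaussian
  fitting (the measured statistics do not need it).
* Nucleus segmentation is 2-D (projection plane), not volumetric.
* Threshold monotonicity of the dot count is guaranteed for isolated
  unimodal spots (and asserted on rendered fibres); on arbitrary images a
  higher threshold can split a multi-peaked blob into several components.
* The exclusion-group sampler preserves the marginal of the first-listed
  gene only; with more than two genes per group the later marginals are
  conditional quantities.
* `orientAndCrop` uses nearest-neighbour resampling; it is meant for
  frame alignment, not for intensity work after rotation.

## Session info

```{r}
sessionInfo()
```
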