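# fibreFISH

Quantification of nascent-transcript FISH signals in syncytial *Drosophila*
muscle fibres.

Body-wall muscles are syncytia: a founder cell (FC) seeds each fibre and
fuses with naive myoblasts whose nuclei are then reprogrammed to the
fibre's identity programme. FISH with intronic probes marks *active*
transcription as one nuclear dot per transcribing locus, so dot counting
and dot intensity measurements read out, nucleus by nucleus, which genes a
syncytium is transcribing. This package is for researchers who need those
read-outs as reproducible code rather than interactive image-editor
sessions. It provides:

* **dot quantification** — sum-slices projection, thresholding, 8-connected
  particle analysis, muscle-mask intersection (centroid rule), Z filtering,
  and integrated density per dot (IntDen, the pixel sum over the dot ROI)
  with its per-fibre total:
  `Total IntDen = Σ_dots IntDen(dot)`;
* **per-nucleus co-transcription** for double FISH — nucleus segmentation
  (threshold + distance-transform watershed), dot→nucleus assignment, and
  exact four-way tables (A only / B only / both / neither) with the derived
  `active` and `co_given_active` fractions;
* **spatial standardisation** in the DA3 muscle frame —
  `ΔX = X − X_c`, `ΔY = −(Y − Y_c)`, `standΔX = 100·ΔX/Area`,
  `standΔY = 100·ΔY/Area`, classified into antero-ventral
  (`standΔY < −1`), postero-dorsal (`standΔX > +1`) and central
  subdomains;
* **summary statistics** — mean ± SD, SEM, min/max per muscle/gene/stage,
  unpaired *t* tests and Pearson's χ² on transcribing-nucleus proportions;
* a **synthetic image generator** with full ground truth — stochastic
  ON/OFF bursting per nucleus, FC-restricted genes, a 9-fold FC intensity
  multiplier, mutually exclusive programmes, a correlated duf/col joint
  burst table, lineage-label mixing — so every pipeline stage is testable
  without microscopy data, and recovery of the encoded statistics is the
  package's acceptance standard.

## Worked example

Simulate a cohort of 20 stage-15 DT1 fibres with the packaged S59
configuration (burst probability 0.45 per nucleus), run the full image
pipeline, and summarise:

```r
library(fibreFISH)

cfg <- presetConfig("dt1_s59_stage15")
pl  <- runPipeline(cfg, nFibres = 20, stage = 15, seed = 7)
head(pl$fibres, 3)
#>   fibre_id gene stage n_nuclei n_dots total_intden n_active
#> 1    f0001  S59    15       10      5        96604        5
#> 2    f0002  S59    15       10      4        92968        4
#> 3    f0003  S59    15       10      2        43164        2

summarizeFibres(pl$fibres, pl$dots)
#>   gene stage     variable   n      mean        sd       sem   min    max
#> 1  S59    15       n_dots  20      5.05     1.849    0.4134     2      8
#> 2  S59    15     n_nuclei  20     10.00     0.000    0.0000    10     10
#> 3  S59    15 total_intden  20 103440.10 37633.999 8415.2180 43164 179130
#> 4  S59    15       intden 101  20483.19  3744.501  372.5917 10906  29438

fa <- fractionActive(pl$fibres, mode = "nuclei")
sprintf("active nuclei: %.1f%% +/- %.1f%% (SEM)", fa$mean_pct, fa$sem_pct)
#> [1] "active nuclei: 50.5% +/- 4.1% (SEM)"
```

Each fibre carries 10 nuclei at stage 15; about five bear an S59 dot, and
each detected dot's integrated density sits near the configured 20000 AU
mean — at this small cohort size, the 50.5% ± 4.1% active fraction is
consistent with the configured 45%. Spatial standardisation works on plain
coordinates too:

```r
fr <- new("MuscleFrame", centroid = c(x = 50, y = 30), area = 200,
          boundingRect = c(0, 0, 100, 60))
sc <- standardizeCoords(cbind(54, 28), fr)
sc
#>    x  y dX dY std_dX std_dY
#> 1 54 28  4  2      2      1
classifySubdomain(sc)
#> [1] postero-dorsal
```

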