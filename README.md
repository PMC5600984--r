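# ldpo — gray/white matter boundary width mapping

Quantifies the **blurred gray/white matter junction** in T1-weighted brain MR
volumes, the imaging hallmark of focal cortical dysplasia (FCD), a leading
cause of drug-resistant epilepsy. Instead of a unitless gradient feature, the
package assigns every voxel of the gray/white boundary (GWB) band a physical
**width in millimetres**: the distance from gray matter (GM) to white matter
(WM) along a locally optimal direction. Broadened widths flag blurred
junctions.

Intended users: neuroimaging methods researchers who want a reproducible,
testable implementation of Laplace-equation boundary-width estimation with a
synthetic ground-truth phantom suite — no clinical data required.

## Method

For skull-stripped, bias-corrected input `Y` (NIfTI-1):

1. **HMRF-EM segmentation.** Three Gaussian classes (CSF < GM < WM on T1),
   likelihood `G(y; μ_l, σ_l)` with a Potts spatial prior (clique potential
   `0.5 β` per discordant 6-neighbor pair). MAP labels via sequential ICM;
   parameters via posterior-weighted moments; per-tissue posteriors
   `p_CSF, p_GM, p_WM` normalized per voxel.
2. **Boundary labeling.** GM where `p_GM ≥ T_prob`, WM where
   `p_WM ≥ T_prob`, GWB where both lie strictly in `(0, T_prob)`
   (`T_prob = 0.9`).
3. **Laplace potential.** Solve `∇²ψ = 0` over the band by Jacobi
   relaxation with Dirichlet boundaries `ψ_GM = 50`, `ψ_WM = 150`
   (band initialized at 100), stopping when the relative change of the total
   field energy `ε_t = Σ |∇ψ|` drops below `1e-5`.
4. **Width map.** From every band voxel, greedily trace strictly
   monotone minimum-ψ steps to GM and maximum-ψ steps to WM
   (26-neighborhood); the width `D(v)` is the world-mm distance between the
   two endpoints (`D = 0` outside the band; trace failures carry status
   codes, never abort).

A 5×5×5 least-squares gradient-magnitude map (`gradientMap()`) is included as
the classical comparator feature, and `thresholdSweep()` / `bestFScore()`
provide voxelwise ROC / precision–recall / F-score evaluation against a
lesion mask.

## Worked example

Everything runs on synthetic phantoms with known ground truth:

```r
library(ldpo)

# slab phantom: 3 mm boundary band, doubled inside an 8 mm-radius "lesion"
ph <- slabPhantom(shape = c(40, 40, 40), gwbThicknessMm = 3,
                  lesion = list(radiusMm = 8, multiplier = 2), seed = 7)

field <- solveLaplace(ph@truthLabels)          # harmonic potential over the band
wmap  <- computeWidthMap(field, ph@truthLabels)
wmap
#> WidthMap: 5424 measured GWB voxels; mean 5.24 mm (sd 1.33), range [4.00, 9.95], mode 4.90

lesion   <- regionStats(wmap, ph@lesionMask)
surround <- regionStats(wmap, brainVolume(1L - volData(ph@lesionMask), role = "mask"))
sprintf("lesion mean %.2f mm vs surround mean %.2f mm", lesion$mean, surround$mean)
#> "lesion mean 6.83 mm vs surround mean 4.76 mm"

bf <- bestFScore(thresholdSweep(widthFeature(wmap), ph@lesionMask))
sprintf("best F-score %.2f at threshold %.2f mm", bf[["f_score"]], bf[["threshold"]])
#> "best F-score 0.85 at threshold 4.92 mm"
```

The 3 mm band measures ≈ 4 mm (band plus one endpoint voxel on each side),
the doubled band ≈ 7 mm away from its rim, and the best detection threshold
falls between the two width populations — a wide boundary is separable from a
normal one in physical units.

The full pipeline from intensities (segmentation included) is one call:

```r
res <- runPipeline(ph@image, outputDir = "out/")   # width_map.nii.gz, stats, provenance
```

or from a shell:

```sh
Rscript inst/scripts/ldpo.R run --input t1.nii.gz --out out/ --t-prob 0.9
Rscript inst/scripts/ldpo.R feature --input t1.nii.gz --out gradient.nii.gz
Rscript inst/scripts/ldpo.R evaluate --feature out/width_map.nii.gz \
    --truth lesion.nii.gz --out curve.csv --polarity high
```

See `vignettes/gwb-width-mapping.Rmd` for the model, parameter and design
discussion, including what phantom results do and do not say about clinical
data.

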