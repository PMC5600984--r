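---
title: "Quantifying the blurred gray/white matter junction: methods and design"
author: "ldpo package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the blurred gray/white matter junction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldpo)
```

## The problem

Focal cortical dysplasia (FCD) is a localized malformation of cortical
development and a leading cause of drug-resistant epilepsy. On T1-weighted MR
images an FCD lesion often shows a *blurred gray/white matter junction*: the
normally crisp intensity step between cortical gray matter (GM) and
subcortical white matter (WM) becomes a gradual ramp spread over several
millimetres. Classical gradient-magnitude features flag such regions (a
blurred junction has a *small* gradient) but cannot say *how wide* the
junction is in physical units. This package estimates, for every voxel of the
gray/white boundary (GWB) band, the GM-to-WM distance in millimetres along a
locally optimal direction — a quantity whose units are interpretable and
whose elevation marks a broadened junction.

## The procedure

The pipeline has four stages, each exposed as its own function and
orchestrated by `runPipeline()`:

1. **Tissue segmentation** (`emFit()`). A three-class hidden Markov random
   field model: intensities follow per-class Gaussians
   $G(y;\mu_l,\sigma_l)$, $l \in \{\mathrm{CSF,GM,WM}\}$, with
   $\mu_{CSF} < \mu_{GM} < \mu_{WM}$ (T1 ordering), and labels carry a Potts
   prior over 6-connected neighbor pairs with clique potential
   $0.5\,\beta$ per discordant pair. MAP labels are estimated by sequential
   raster-order ICM sweeps; class parameters are re-estimated by
   posterior-weighted moments; per-tissue posterior probabilities are the
   per-voxel normalization of likelihood times local Gibbs prior across the
   three classes. The normalization across labels is a deliberate modelling
   choice: the Gibbs partition constant is intractable per voxel, and
   normalizing over the three candidate labels is the standard mean-field
   reading that makes the three posterior images sum to one.
2. **Boundary labeling** (`labelRegions()`). A voxel is GM if
   $p_{GM} \ge T_{prob}$, else WM if $p_{WM} \ge T_{prob}$, else GWB if both
   $p_{GM}$ and $p_{WM}$ lie strictly inside $(0, T_{prob})$, else
   background, with $T_{prob} = 0.9$ by default. The rule is applied
   literally: GM/WM certainty wins over junction membership, and a voxel
   with an exactly-zero probability can never be GWB. CSF probability does
   not participate; a practical consequence is that voxels deep inside CSF —
   whose GM and WM posteriors are tiny but not exactly zero in floating
   point — are labeled GWB. They are harmless downstream: their WM-ward
   traces stall and they receive width 0 with an explicit status code.
3. **Potential field** (`solveLaplace()`). The band is treated as an
   electric potential field with Dirichlet boundaries
   $\psi_{GM} = 50$ on GM and $\psi_{WM} = 150$ on WM; band voxels start at
   $\psi_{GWB} = 100$ and relax by synchronous Jacobi averaging of their six
   face neighbors, solving $\nabla^2\psi = 0$ discretely. Where a neighbor
   is outside the field (CSF, background, volume edge) a mirror (zero-flux)
   condition substitutes the center's own previous value, so the potential —
   and hence the width — runs only between GM and WM, never toward CSF.
   Iteration stops when the *absolute* relative change of the total field
   energy $\varepsilon_t = \sum |\nabla \psi_t|$ over band voxels falls
   below `relTol` ($10^{-5}$ by default).
4. **Path tracing and width** (`computeWidthMap()`). From every band voxel,
   a greedy trace steps to the minimum-potential neighbor in the
   26-neighborhood until a GM-labeled voxel is reached, and symmetrically to
   the maximum-potential neighbor until WM. Only strictly monotone steps are
   taken; on a converged harmonic field the discrete maximum principle
   guarantees a strict step exists wherever the band is connected to both
   boundaries, so every trace terminates. The width at the voxel is the
   world-mm Euclidean distance between the two endpoints (`mode =
   "endpoint"`), honoring anisotropic voxel spacing through the affine.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `beta` | 1.0 | — | Potts pairwise weight; 0 reduces the model to an equal-weight Gaussian mixture. The neighborhood (6-connected pairs) and the default weight are package choices; results are insensitive for well-separated classes. |
| `tProb` | 0.9 | probability | Certainty threshold of the labeling rule; raising it can only grow the band (monotone). |
| `psiGm/psiGwb/psiWm` | 50/100/150 | arbitrary | Dirichlet constants; only their ordering matters, widths are invariant to the actual values. |
| `relTol` | 1e-5 | relative | Energy-change stopping tolerance of the Jacobi solver. |
| `neighborhood` | 26 | — | Trace search window; 26-connectivity permits diagonal descent. |
| `widthMode` | endpoint | — | `endpoint`: distance between the GM and WM endpoints. `halfpath-mean`: mean of the two origin-to-endpoint distances, which can fall below one voxel diagonal for a band voxel touching both boundaries. Both conventions are provided because sub-voxel minima reported for this class of method are only reachable under the half-path reading; the endpoint reading is the literal mean of the width definition's two terms, which share their endpoint pair. |

## Numerical choices

* **Tie-breaking.** Among equal-potential trace neighbors, the step with the
  smallest offset magnitude wins (face before edge before corner), then
  lexicographic order. A purely lexicographic rule is also deterministic but
  drifts diagonally on planar fields — on a slab every same-layer neighbor
  ties and the corner offset sorts first — inflating measured widths by up
  to a voxel diagonal per step. Magnitude-first ordering keeps descent
  axis-aligned wherever the field is symmetric.
* **Stopping by label, not by value.** Traces stop when the current voxel is
  GM/WM-*labeled*; interior potentials approach but never equal the boundary
  constants, so a floating-point equality test would never fire.
* **Energy direction.** Under the band-constant initialization the total
  gradient-magnitude energy *rises* monotonically toward the harmonic limit
  (the initial state concentrates gradient at the band faces). The stopping
  rule therefore uses the absolute relative change; the change magnitudes
  decay geometrically.
* **ICM order and determinism.** ICM sweeps are sequential in raster order
  (compiled code), so the posterior energy never increases within a sweep;
  Jacobi sweeps are synchronous, so they are independent of visitation
  order. Every stochastic step (k-means initialization, phantom noise) is
  seeded; identical configurations reproduce outputs byte-exactly.
* **Degenerate inputs.** Empty masks, constant images, label volumes without
  a band, and regions without positive widths raise typed errors naming the
  violated contract; per-voxel trace failures never abort a run and are
  returned in the status map (`statusCodes()`).

## The phantom generator

`slabPhantom()` builds a layered volume — CSF base, GM slab, a linear
partial-volume ramp of controllable physical thickness, WM slab — with
per-class Gaussian noise (defaults: means 50/110/170, SD 10, i.e. a GM/WM
separation of six noise SDs) and an optional cylindrical "lesion" footprint
where the band is locally thickened by a multiplier, emulating a broadened
junction. `shellPhantom()` provides the curved-interface analogue. The
defaults are fixed study conditions, not tuning knobs: the CSF layer exists
because the segmentation model is three-class, the linear ramp is the
simplest model of partial-volume mixing, and the noise is additive Gaussian
(Rician noise and bias fields are deliberately not modelled).

What the phantoms do *not* emulate: cortical folding, anatomical priors,
intensity non-uniformity, and the heavy preprocessing (brain extraction,
registration, histogram normalization) that real scans receive upstream of
this package. Passing phantom tests therefore validates the estimation
machinery — segmentation consistency, harmonic-field accuracy, geometric
width recovery — not clinical detection performance.

## What the width map can and cannot recover

On constructed band labels the machinery is essentially exact: slab bands of
2/3/5/8 mm (1 mm isotropic voxels) measure means of 3/4/6/9 mm — the band
plus one endpoint voxel on each side — strictly increasing in the true
thickness, and a thickness-doubled lesion separates cleanly from its
surround with the best F-score threshold between the two population means.
The test suite and `scripts/acceptance.R` recompute all of these.

When the band is instead *segmented* from intensities, its thickness is
governed by the width of the posterior-uncertain zone of the Gaussian model,
approximately $2\ln(9)\,\sigma^2/\Delta\mu$ intensity units at
$T_{prob}=0.9$ — sub-voxel at the phantom's default separation. Segmented
bands on sharp synthetic slabs are therefore thin and nearly
thickness-independent, and the measured mode sits near one voxel diagonal.
This is a property of posterior-threshold banding itself, not an
implementation artifact; real clinical blur expresses partial-volume mixing
over many voxels and a larger effective class overlap, which is where the
width map becomes informative. At very low SNR the literal labeling rule has
the opposite failure: band voxels percolate through noisy GM and widths
become unreliable. The pipeline is consequently validated end-to-end for its
contracts (determinism, bookkeeping, parameter recovery), while quantitative
width-recovery claims are made on constructed labels.

## Known limitations

* Not all FCD lesions blur the junction; the width map is one feature among
  several, not a detector on its own.
* The width depends on the upstream segmentation; comparisons are only
  meaningful when every scan is processed with the same model and settings.
* No sub-voxel interpolation: paths move voxel-to-voxel, so widths are
  quantized at the voxel-diagonal scale.
* The band labeling inherits the strict literal rule discussed above,
  including GWB labels inside CSF (width 0, flagged by status).

## Problem sizes

The shipped tests and the acceptance script use phantoms of 30–40 voxels per
side (27k–64k voxels), 8-voxel random bands for the direct-solve oracle, and
9³–12³ fixtures for the gradient and evaluation oracles; these sizes were
chosen so the full suite exercises every stage end-to-end in about a minute
on a single CPU.
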