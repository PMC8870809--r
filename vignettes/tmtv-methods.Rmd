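---
title: "Automated TMTV from PET/CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated TMTV from PET/CT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtvnet)
```

## The problem

Total metabolic tumor volume (TMTV) — the summed volume of all
tumor-classified voxels on a baseline FDG-PET — is a prognostic factor in
the FDG-avid lymphomas (Hodgkin lymphoma, DLBCL, follicular lymphoma).
Measuring it manually means delineating every uptake in a whole-body scan
and is too slow for routine use. A further complication is that no single
segmentation rule is consensual: clinics use a relative threshold (41% of
each lesion's SUVmax), fixed cutoffs (SUV > 2.5 or SUV > 4.0), or
histogram methods (Otsu). A network trained against any one rule bakes
that rule in.

`tmtvnet` implements a two-stage design that separates *detection* from
*thresholding*:

1. a 3D V-NET is trained to reproduce a **consensus probability map**
   (TMTVprob) — the voxel-wise average of the four threshold masks
   computed inside manual ROIs — rather than any single rule;
2. the predicted map, binarized at probability > 0.5, is **post-processed**
   with whichever clinical methodology is wanted: a global fixed cutoff, or
   per-lesion 41% SUVmax after connected-component isolation and watershed
   splitting of coalescent masses.

Every stage is exercisable end-to-end on synthetic phantoms with analytic
ground truth; clinical trial imaging with expert delineations is
restricted data and is not needed by any code path.

## Consensus ground truth

Inside each manual ROI the four operators produce binary masks:

* `cutoff_segment(pet, roi, c)` keeps SUV **strictly** above `c`. The
  strict inequality follows the way the rules are written ("SUV > 2.5");
  for continuous PET data the boundary set has measure zero, but the
  choice is fixed and documented.
* `percent41_segment(pet, roi)` keeps SUV **≥** 0.41 · SUVmax(ROI). The
  inclusive inequality guarantees the SUVmax voxel itself survives; with a
  strict one, a lesion whose maximum is unique would still keep it, but a
  perfectly homogeneous ROI would vanish.
* `otsu_segment(pet, roi)` maximizes the between-class variance of the
  within-ROI SUV histogram over 256 equal-width bins spanning the ROI's
  range, then keeps voxels strictly above the threshold. 256 bins is the
  conventional discretization; the brute-force definition (score every
  candidate split) is kept in the test suite as an independent oracle.
  Otsu is computed per ROI, not globally: the rules are applied to the
  manual region of interest, whose local histogram is what a physician's
  tool sees.

`build_tmtv_prob()` averages the four masks voxel-wise. Because the mean
of four indicator values is a multiple of 1/4, and quarters are exactly
representable in binary floating point, TMTVprob attains exactly
\{0, 0.25, 0.5, 0.75, 1\} — the granularity tests assert equality, not
tolerance. Overlapping ROIs are unioned **per method before averaging**,
so no voxel can exceed probability 1.

## The phantom generator

Phantoms stand in for the restricted clinical data and define the study
conditions of every stochastic test. A phantom is composed on a fixed
grid as the voxel-wise **maximum** of:

* a soft-tissue background at SUV 1.0 (typical mediastinal blood-pool
  level);
* 1–4 ellipsoidal lesions with peak SUV 5–15, half-axes 10–28 mm at
  clinical spacing (24–48 mm for the coarse training grids), flat or
  Gaussian profiles, optionally a second identical peak offset inside the
  same lesion id (a coalescent mass);
* physiological uptakes — a brain-like sphere (SUV 7) at the cranial end
  and a bladder-like sphere (SUV 12) caudally — which are *never* part of
  the truth;
* with probability 0.3, an injection-site artifact: a small SUV 10 blob
  at the lateral arm edge, also excluded from truth (the classic
  false-positive of automated TMTV).

Additive Gaussian noise (SD 0.15 SUV, clipped at zero) models measurement
noise; 15% of background is in the range of whole-body PET
reconstructions. The max-composition keeps two invariants simple and
analytic: a lesion's truth mask is exactly the set where its noise-free
profile exceeds the background, and raising a peak SUV can only grow that
set. The Gaussian profile is calibrated to decay from its peak to the
background level exactly at the ellipsoid surface, so flat and Gaussian
lesions share the same analytic truth region — the ellipsoid with volume
4/3·π·r₁r₂r₃ — and voxelized truth volumes converge to the analytic value
as spacing shrinks (asserted at two resolutions in the tests).

The CT channel is schematic: an elliptical soft-tissue body (~40 HU) in
air (−1000 HU) with two +700 HU bone rods. The pipeline only uses CT as
a second, anatomically plausible intensity channel; nothing downstream
depends on anatomical realism.

What the phantoms deliberately do **not** model: scanner point-spread
blur and reconstruction artifacts, respiratory motion, heterogeneous
background organs (liver, marrow), brown fat. Tests passing on phantoms
therefore demonstrate the pipeline's *mechanics* (thresholds, clustering,
training dynamics), not clinical accuracy on patients.

Manual ROIs are emulated as loose bounding boxes (lesion bounding box
dilated by a margin, default 8–12 mm, clipped to the grid). Clinical
delineation records do not preserve the ROI shapes physicians drew;
boxes are our assumption, chosen because box-like loose regions are what
quick manual delineation tools produce. Overlapping boxes keep distinct
ids.

## Preprocessing

The network consumes a fixed physical field: 128 × 128 × 256 voxels at
4 mm isotropic spacing (a 512 × 512 × 1024 mm box — whole-body fields up
to ~102 cm axially fit without changing the aspect ratio). Volumes are
resampled trilinearly; masks and label images use nearest-neighbour so no
label can be invented. Two conventions are ours because the source
workflow does not state them: the output field is **centred** on the
input field's centre, and out-of-field voxels take the modality
background (0 SUV, −1000 HU). Intensities are clipped-then-scaled
affinely, CT [−1000, 1000] HU → [0, 1] and PET [0, 25] SUV → [0, 1];
clipping (rather than per-case rescaling) keeps the map identical across
cases, which matters because SUV is an absolute scale the fixed cutoffs
depend on. The inverse map `unscale_pet()` recovers in-range SUV exactly.

SUV conversion from raw activity (`suv_from_activity()`) implements
body-weight SUV with decay correction to series start,
SUV = A · w·1000 / (D · 2^(−Δt/T½)), with T½ = 109.77 min for ¹⁸F. NIfTI
volumes are assumed already SUV-calibrated; there is no DICOM-series
reader in this package, so the conversion is exposed as a pure function
for callers that extract header fields themselves.

## The network

`build_vnet()` constructs a V-NET-style encoder–decoder: 4 levels, 8
channels at the first level doubling per level, residual convolution
stages, stride-2 down-convolutions, 2×2×2 transposed up-convolutions,
skip concatenation, and a single-channel 1×1×1 head with sigmoid
activation. Training uses the soft dice loss 1 − (2Σpt + ε)/(Σp + Σt + ε)
with ε = 10⁻⁶ — dice being insensitive to the overwhelming background
class — under SGD with learning rate 0.001 and momentum 0.9, with one
augmented copy per training case (random translation ±16 mm, rotation
about the axial axis ±10°, isotropic scale 0.9–1.1). Augmentation ranges,
batch size (2) and initialization are not specified by the clinical
setup and are configuration choices here: He initialization for weights,
and a head bias of −2 so the initial prediction is close to the
mostly-background target, which removes the early plateau the dice loss
otherwise shows. The truth map is continuous-valued, so augmented truth
is interpolated linearly, not re-binarized.

Implementation notes: convolutions run as im2col + GEMM through
RcppArmadillo with hand-written backward passes; a finite-difference
gradient check is part of the test suite. Convolution kernels are 3×3×3
(config-exposed) — at desk-scale grids the receptive field of a 4-level
network covers the whole volume either way. Leaky ReLU (slope 0.1)
replaces PReLU: one fewer parameter set, and slope learning adds nothing
measurable at this scale.

Desk scale means: training cases are whole phantoms generated directly
on a 16 × 16 × 32 grid at 8 mm spacing, ~20 cases, ≤30 epochs — sized so
a full train/evaluate cycle runs in minutes on one CPU. The full-scale
128 × 128 × 256 / 100-epoch configuration is reachable through
`vnet_config()` but is not exercised by the test suite. The 60/20/20
train/test/validation split (`split_dataset()`) is seed-reproducible.

## Post-processing

`binarize_prediction()` cuts the probability map strictly above 0.5.
For a fixed-cutoff methodology the final mask is simply the raw mask
intersected with SUV > c — the rule is global, so clustering would not
change it. For the 41% methodology lesion identity matters:

1. connected components of the raw mask under 26-connectivity (face,
   edge and corner neighbours — a diagonal bridge a reader would call one
   mass stays one component);
2. components over 30 mL are split by a marker-controlled watershed on
   the SUV field restricted to the component. Markers are regional maxima
   of the SUV smoothed with a 1-voxel Gaussian, merged when closer than 2
   voxels; flooding proceeds from high SUV downhill with a deterministic
   FIFO tie-break, so subparts partition the component exactly. The
   marker policy is the dominant free parameter of this stage — the
   clinical procedure is specified only as "watershed on the SUV
   values" — and both knobs are exposed as arguments;
3. each surviving sub-component is thresholded at 0.41 of its own
   SUVmax; sub-components losing all voxels are dropped silently and
   `count_rois()` counts survivors.

The 30 mL gate is evaluated on the component volume at the grid the mask
lives on (0.064 mL per voxel at 4 mm). Otsu is implemented as a
ground-truth operator but deliberately not wired as a post-processing
methodology: only the three clinical methodologies are validated
downstream, and a post-hoc Otsu on a predicted mask has no clinical
counterpart.

Properties the tests enforce: watershed subparts partition their
component exactly; every final mask is a subset of the raw mask;
SUV > 4.0 masks nest inside SUV > 2.5 masks; the 41% pipeline is
invariant to rescaling the PET.

## Validation statistics

Per case: dice, Jaccard (J = D/(2−D), an identity the tests check
exactly), and voxel-level sensitivity/specificity/PPV/NPV. Two empty
masks score dice 1 (perfect agreement on absence); a ratio with an empty
denominator is reported `NA`, never 0. Cohort level
(`cohort_report()`): per-methodology and per-subtype dice distributions,
TMTV distribution statistics (max/min/mean/median/SD reported separately),
Spearman correlation (average ranks on ties, two-sided p, asymptotic
approximation), Bland–Altman bias with 1.96·SD limits of agreement
(sample SD), and a two-sided paired t-test with the significance cut at
0.05.

## Numerical choices and degenerate inputs

* Quarter-step probabilities are exact in floating point; granularity
  tests use equality.
* Otsu on a single-valued ROI, 41% on an all-zero ROI, and phantoms with
  lesions outside the grid or peaks at/below background all raise errors
  naming the offending ROI or lesion.
* An empty raw mask post-processes to TMTV 0 with zero components — a
  valid result, not an error.
* Resampling uses voxel-centre alignment; a constant field stays
  constant in the interior, and resampling a volume already on the
  target grid is an identity up to floating point.
* Training aborts with the epoch index if the loss turns non-finite.
* All randomness (phantom noise, spec sampling, weight init, shuffling,
  augmentation) flows from explicit integer seeds through an
  RNG-state-preserving wrapper, so library calls never perturb a user's
  session RNG.

## Known limitations

* Phantom realism, as above: passing tests bound the pipeline's
  correctness, not its clinical performance; headline clinical agreement
  numbers depend on 2030 restricted PET/CTs and cannot be reproduced
  here.
* The desk-scale network sees 2-channel 16 × 16 × 32 inputs; its learned
  weights are not transferable to clinical volumes.
* No DICOM ingestion: volumes must arrive as SUV-calibrated (PET) or
  HU-calibrated (CT) NIfTI.
* The watershed marker policy is heuristic; heavily plateaued or very
  noisy components may over- or under-split, which is why both marker
  parameters are exposed.
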