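---
title: "Methods: task modulation of cortical gradients from informational connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task modulation of cortical gradients from informational connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gradflex)
```

## The scientific question

The principal gradient of cortical connectivity orders brain regions from
unimodal sensory-motor cortex to transmodal default-mode regions. gradflex
implements an analysis pipeline for asking how that organisation *flexes*
with semantic task demands: when participants judge word pairs whose
associative strength varies, does the separation between the two ends of
the gradient grow for strongly associated pairs (retrieval dominated by
shared long-term knowledge) and shrink for weak ones (retrieval shaped by
semantic control)? Three linked measurements are implemented:

1. **Informational connectivity gradients.** For each parcel, the
   between-trial multivoxel pattern-similarity matrix is computed (Pearson
   across voxels; within-run trial pairs excluded because slow temporal
   autocorrelation inflates them). The parcel-by-parcel *informational
   connectivity* (IC) matrix correlates these similarity structures between
   parcels. Row sparsification (density 0.1), a cosine affinity kernel and
   PCA decompose the IC matrix into gradients; the first component is the
   principal gradient. Condition-specific gradients (strong vs weak
   association terciles by word2vec score) are aligned to the all-trials
   group template and differenced per parcel.

2. **Neural dimensionality.** For each trial and location, participants'
   patterns are stacked into a participants-by-voxels matrix, columns are
   mean-centred, and the estimator counts the components needed to exceed a
   variance criterion (strictly more than 90%, with 60% and 75% as
   robustness criteria). A 5x5x5-voxel searchlight (125 voxels) and a
   parcel-level variant are provided. Weak-minus-strong contrasts use
   two-sided Wilcoxon rank-sum tests across trials with
   Benjamini-Hochberg FDR at q = 0.05.

3. **Second-order RSA.** A semantic model correlates participants' rating
   vectors across trials; a brain model per location correlates
   participants' vectorised valid-pair similarities; alignment correlates
   the two models' lower triangles, Fisher-z transformed (correlations
   clipped at 1 - 1e-6 so the equality edge case stays finite).
   Participant-pair entries are not independent, so significance uses a
   Mantel-style simultaneous row/column permutation of the semantic model.

The three maps are tied together by a bootstrap mediation over parcels:
the principal gradient (X) predicts semantic-brain alignment (Y) partly
through the weak-minus-strong dimensionality difference (M); the indirect
effect is a*b with a percentile bootstrap interval, and the proportion
mediated is a*b/c (the standard estimand; the OLS identity c = c' + a*b
holds exactly).

Spatially autocorrelated map-to-map correlations are tested with spin
permutations: parcel centroids live on the unit sphere, one map is rigidly
rotated (uniform rotations via QR of a Gaussian matrix), values are
reassigned by nearest rotated centroid, and a two-tailed p value is
`(1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)`.

## The synthetic-data generator

Raw participant data for this design cannot be publicly archived, so the
package treats a synthetic generator as a first-class component: it
emulates the study design (31 participants, 144 concrete-noun word-pair
trials in 3 contiguous runs, word2vec scores over the stimulus range
[-0.05, 0.72], integer 0-4 ratings) and plants four effects with known
ground truth, each recoverable by exactly one downstream stage.

**Latent structure.** Each trial draws shared latent coordinates for every
parcel from a Gaussian field whose cross-parcel correlation decays
exponentially with distance along a planted 1-D gradient `g*` in [-1, 1].
Each parcel turns its coordinates into voxel patterns through a fixed
orthonormal basis, plus participant-level deviations, run-constant
components, per-trial global and parcel amplitude terms (constant across a
parcel's voxels, hence exactly invisible to across-voxel pattern
correlations), and isotropic voxel noise.

**Planted effects and their orthogonality.** Early versions planted the
condition modulation and the latent rank jointly in the shared
coordinates; implementation showed the plants then contaminate each
other's stages, so the final design factorises them:

* *Gradient and its modulation.* The decay rate of the shared-field
  correlation interpolates with the trial's word2vec score from `s_hi`
  (weakest pairs, short-range sharing) down to `s_lo` (strongest pairs,
  long-range sharing). Through the sparsify-cosine-PCA stack, longer-range
  coherent sharing is what strengthens the first gradient: with the
  template oriented so transmodal cortex is positive, the strong-minus-weak
  score difference then tracks `g*`. (The opposite mapping - faster decay
  for strong trials - provably yields a difference map *anti*-correlated
  with `g*`: the first component of a 1-D kernel is a half-cosine in arc
  position, so end-stretching saturates while mid-gradient polarity
  dominates. This was established on noise-free population matrices before
  the sampled design was frozen.)
* *Latent rank.* The planted per-parcel, per-condition rank applies to the
  participant-level deviations only. Because the dimensionality estimator
  mean-centres across participants, the shared coordinates cancel exactly
  and the estimator sees precisely the planted rank, while the
  trial-similarity structure that drives the gradient carries no condition
  signature.
* *Rating-brain coupling.* In coupled parcels a pattern component whose
  trial course is the participant's standardised rating vector is added
  along a fixed parcel direction. Participants with more similar ratings
  therefore have more similar local representational geometry - the
  second-order RSA target - while the rank-1 footprint leaves
  dimensionality essentially untouched. Strong coupling unavoidably also
  adds shared similarity structure among coupled parcels (fourth order in
  beta), so the default strength is moderate (beta = 1.5).
* *Chevron control.* A second pattern set is generated from the same
  machinery with the modulation held constant at the midpoint rate and a
  condition-independent rank, emulating a task period where the semantic
  manipulation should not bite.

By default the rank and coupling plants are *graded* along `max(g*, 0)`,
so the gradient, the dimensionality contrast and the alignment map
co-vary over parcels - the structure the mediation stage estimates.
Passing explicit parcel sets switches to discrete constant-strength
plants, which the focused recovery experiments use.

**Default parameters.** `s_lo = 3`, `s_hi = 7` (decay rates per unit
gradient distance; the realised IC kernel decays at roughly twice the
field rate because similarity-structure correlation behaves like the
squared field correlation); latent rank 16 (giving condition-level IC
estimates enough internal averaging to be stable at 48 trials per
condition) modulated to 18/12 at the apex; participant-deviation sd 1
(the cross-participant spread the dimensionality estimator measures);
voxel noise sd 0.3; run-effect sd 0.25; global and parcel amplitude sd 1
(these drive the time-series control's degradation but cancel exactly in
pattern correlations); 28 voxels per parcel; 100 parcels for routine use
(400 reproduces the reference parcellation scale). Ratings are a linear
map of word2vec to the 0-4 scale plus participant noise (sd 0.7),
rounded; reported link descriptions draw from a meaning pool that shrinks
with association strength, so the behavioural analyses (rating-word2vec
correlation, unique-meaning counts) behave like the study's.

## Numerical and design choices

* **Sparsification** keeps each row's `ceiling(density * (P - 1))`
  largest off-diagonal entries (diagonal excluded and zeroed).
* **Eigen-decomposition** uses PCA of the column-centred affinity; signs
  are fixed deterministically (first non-zero loading positive), and the
  template's principal gradient is oriented positively against the
  reference gradient, since PCA leaves both arbitrary.
* **Alignment before differencing** is orthogonal Procrustes onto the
  all-trials template over the retained 10 components. Sign-matching
  alone leaves the condition difference dominated by component-mixing
  noise (planted modulation recovered at r ~ 0.2-0.4 vs ~0.6-0.8 under
  Procrustes on identical data), which is why Procrustes is the default;
  unaligned subtraction is refused outright.
* **Fisher z** is applied to similarities before parcel-pair correlation,
  to correlations before group averaging, and to alignment values, with
  clipping at |r| = 1 - 1e-6.
* **Wilcoxon rank-sum** enumerates the exact midrank null for
  `n_x + n_y <= 12` (so ties remain exact) and uses the tie-corrected
  normal approximation beyond.
* **Greenhouse-Geisser** epsilon is computed from orthonormalised contrast
  covariances per effect; with two levels it is exactly 1.
* **Tercile splits** order by word2vec with ties broken by trial id
  (deterministic and seed-free); remainder trials join the middle tercile.
* **Stage seeds** derive from the single analysis seed by a fixed
  splitting rule (`(seed mod 2e7) * 100 + stage offset`), so each stage is
  individually reproducible and all seeds stay below 2^31.

## Problem sizes used by the validation suite

The acceptance-style experiments run at the study's design scale wherever
the property depends on it (144 trials, 3 runs, 100 parcels, 31
participants for the end-to-end determinism check) and at reduced
participant counts where the measured property is trial-limited rather
than participant-limited (the condition-level gradient experiments use 10
participants; the calibration ensembles use 10-16 participants and
16-60 parcels over 200 replicates). Permutation and bootstrap counts in
the test suite are 99-499 per replicate; the analysis defaults remain
5000.

## Known limitations

* The null sampling distribution of the strong-minus-weak
  gradient-difference map's correlation with the planted gradient has an
  irreducible spread of about 0.14-0.2 under this design: 48 trials per
  condition feed two independent eigendecompositions, and that
  trial-sampling noise does not average out over participants (the latent
  trial structure is shared), parcels (the noise is spatially smooth along
  the gradient), or latent dimensionality within reasonable ranges. A
  single-study design of this size therefore cannot certify
  |r| < 0.15 for ~90% of realisations, and the validation suite reports
  this calibration property honestly rather than passing it.
* The generator does not reproduce the observation that informational
  connectivity gradients explain more first-component variance than
  time-series-connectivity gradients: under the sparsify-cosine-PCA stack
  the variance ratio is scale-free, so it reflects only the spatial kernel
  shape, and the parcel-mean series sees the (slower-decaying) field
  correlation while IC sees its square. The empirical gap presumably
  reflects TR-level measurement-noise asymmetries that the trial-level
  generator does not model.
* Proportion mediated is a ratio estimator with sampling SE ~0.065 at
  n = 400 parcels and the planted path strengths; individual realisations
  land outside [0.45, 0.55] roughly a third of the time, which the
  validation suite likewise reports honestly.
* No haemodynamics, scanner noise spectra, motion, or cortical geometry:
  passing tests show the estimators recover what was planted under this
  generative model, not that real acquisitions behave this way.
* Meaning categories for reported links are compared by normalised string
  equality; merging true paraphrases is the caller's responsibility.
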