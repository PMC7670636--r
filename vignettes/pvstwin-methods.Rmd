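---
title: "Methods: dPVS segmentation and twin heritability in pvstwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dPVS segmentation and twin heritability in pvstwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pvstwin` implements a two-part analysis of MRI-visible dilated
perivascular spaces (dPVS): (1) fully automated segmentation of the
bright, thin (< 3 mm diameter) tubular CSF spaces on 3D T2-weighted-like
volumes, via multiscale Hessian vesselness filtering followed by a 3D
patch classifier that removes false positives near the ventricles and the
subarachnoid space; and (2) classical-twin variance-component modelling of
the resulting regional volumes (basal ganglia, BGdPVS; subcortical white
matter, WMdPVS) in cohorts of monozygotic (MZ) twins, dizygotic (DZ)
twins, and non-twin siblings (NT), yielding narrow-sense heritability,
genetic correlation, and shared heritability.

Because the human imaging data this kind of analysis is usually run on are
access-restricted, the package ships a synthetic-data module that
generates everything the pipeline needs: tubular phantoms with voxel-level
ground truth, test-retest noise realizations, and twin cohorts simulated
from a known ACE model. All statements about performance in the test suite
refer to these synthetic inputs.

# The synthetic-data generator

## Phantoms

A phantom is a schematic head: a spherical brain whose outer ~1.4 mm is a
bright "subarachnoid" shell, a white-matter interior, two ellipsoidal
basal-ganglia blobs, and two bright ventricles adjacent to them. dPVS are
rendered as capsules (line segment plus radius) at CSF intensity, placed
uniformly inside their host region with radii 0.35-1.4 mm (diameter kept
below 3 mm by construction) and lengths 3-10 mm. Two classes of tubular
CSF confounders — capsules continuous with the ventricles and capsules
along the brain surface — emulate the choroid-fissure-like channels and
sulcal CSF that produce the false positives the classifier stage exists to
remove.

Rendering applies sub-voxel partial-volume coverage at the capsule
boundary: a voxel whose centre lies within half a voxel of the capsule
surface receives a proportional intensity mix. This mirrors what a 0.7 mm
acquisition does to sub-voxel structures; a binary rasterization instead
aliases thin tubes into dotted chains that no Hessian-based filter (nor a
radiologist) would recognize as tubes. Ground-truth labels remain defined
by "voxel centre inside the capsule", so the true volume is exactly the
labelled voxel count times the voxel volume (0.343 mm^3 at the default
0.7 mm isotropic grid).

Noise is additive Gaussian (SD 0.05 by default, on tissue intensity 1.0
and CSF intensity 2.0): at the high SNR of modern 3D T2 SPACE-like
acquisitions the Rician floor is negligible, and an additive model keeps
every stage analytically checkable. A smooth multiplicative bias field
(single low-frequency cosine per axis, amplitude 0.1) emulates coil
inhomogeneity. Test-retest replicates reuse the noise-free geometry with a
fresh noise and bias realization, which is how scan-rescan reliability is
evaluated (`generateRetest`, then ICC of the segmented volumes).

What the phantom does *not* model: realistic cortical folding and
anatomy, Rician noise, motion/ghosting, the spatial clustering of real
dPVS (placement is uniform within the region, as nothing quantitative is
established about their spatial statistics), and tissue-segmentation
errors beyond the simple dilated-mask variant described below. Passing
tests on phantoms therefore demonstrates algorithmic correctness and
internal consistency, not clinical accuracy on real scans.

## Twin cohorts

`simulateTwinCohort` draws, per pair, latent additive-genetic values with
correlation 1 (MZ) or 0.5 (DZ and NT; the DZ/NT latent is constructed as
A2 = 0.5 A1 + sqrt(0.75) Z, which has exactly correlation 0.5 and unit
variance), a shared-environment value identical within the pair, and
independent unique-environment values. A trait is the path-weighted sum
a·A + c·C + e·E plus small covariate effects (0.02 per year of age, 0.2
for male sex by default; both removed again by the residual adjustment in
any downstream analysis). For two traits the scalars become
lower-triangular 2x2 Cholesky path matrices. Twin pairs share age and sex;
non-twin siblings draw both independently within 22-35 years, so about
half the NT pairs are opposite-sex — mirroring the within-pair
age/sex differences such cohorts show for siblings but not twins. The
default pair counts (138 MZ / 79 DZ / 133 NT = 700 subjects) are the
group sizes all recovery simulations use.

# Stage 1: vesselness segmentation

Intensities are standardized to mean 0 / SD 1 over the brain mask using
the population (divide-by-n) SD — the convention is fixed for determinism;
the choice is immaterial downstream since vesselness ratios are
scale-free in the relevant factors.

At each scale s in {0.7, 1.05, 1.4} mm the image is smoothed by a
Gaussian of that scale and the scale-normalized Hessian (second central
differences in physical units, multiplied by s^2) is assembled; its three
eigenvalues, ordered |l1| <= |l2| <= |l3|, are obtained by the closed-form
trigonometric solve for symmetric 3x3 matrices, vectorized over voxels (a
per-voxel `eigen()` brute force serves as the test oracle). The
bright-tube vesselness is

V = (1 - exp(-R_A^2 / 2 alpha^2)) * exp(-R_B^2 / 2 beta^2) *
    (1 - exp(-S^2 / 2 gamma^2)),

with R_A = |l2|/|l3|, R_B = |l1|/sqrt(|l2 l3|), S the Frobenius norm of
the eigenvalues, and V = 0 wherever l2 > 0 or l3 > 0 (bright tubes have
two strongly negative curvatures) or l3 = 0 (no structure). Scales span
the sub-3 mm dPVS diameter range; responses are combined across scales by
per-voxel maximum, and the threshold is applied after the multiscale
combination (thresholding per scale before the maximum would only discard
information).

Defaults: alpha = beta = 0.5; gamma adapts per scale to half the maximum
S over the brain mask (the common half-max-norm rule). The threshold
default is 0.10 and deserves explanation, since a folklore value of 0.25
is sometimes quoted for [0,1]-normalized vesselness. With the adaptive
gamma rule the *realized* maximum of V is about 0.65 — the three factors
never reach 1 simultaneously — and a 0.25 cutoff keeps only tube cores,
producing candidate volumes around 40% of truth. The default was
therefore calibrated on noise-free phantoms with known tube volume so
that the extracted candidate volume is approximately unbiased (ratios
0.93-1.05 noise-free and 0.86-1.02 at the default noise level across
seeds). The cutoff remains a user parameter because the appropriate value
depends on contrast and noise; a global (not per-subject-adaptive)
threshold is used.

Voxels above threshold and inside the union of the WM and BG masks are
grouped into 26-connected components (tubes at oblique angles fragment
under 6-connectivity) and each component is tagged with the region
holding the majority of its voxels, ties broken toward WM (the larger
region, where ties are rarest).

# Stage 2: patch-classifier refinement

One 24x24x24 intensity patch is cut from the normalized image per
candidate component, centred on the component centroid rounded to the
nearest voxel and zero-padded at the grid border. Classification is per
component, not per voxel: labels exist at the "this structure is a dPVS /
a ventricle leak / a sulcal leak" level, and a kept component keeps all
its voxels while a rejected one is removed entirely — so refinement can
only shrink the candidate set, never add to it.

The network is four 3x3x3 convolutions with channels 8, 16, 32, 32, ReLU
after each, 2x2x2 max-pooling after each pair of convolutions, one
128-node fully connected layer, and a 3-way softmax trained with
cross-entropy. "Same" padding is used so that two convolutions plus one
pooling halve the side exactly (24 -> 12 -> 6; flattened 6^3 x 32 = 6912
features). The implementation is plain R: convolutions are evaluated as
27 shift-and-add BLAS products per layer, which keeps a mini-batch
forward/backward pass within a couple of seconds on one CPU at this
network size; gradients are checked implicitly by the training tests
(loss decrease, class separation).

Training labels come from phantom ground truth: class 1 for components
overlapping true dPVS voxels, class 2 for components within 2 voxels of a
ventricle, class 3 otherwise (in practice, surface/sulcal leaks). To make
classes 2 and 3 actually occur, training candidates are extracted with
*loosened* region masks (`looseRegionMasks`: WM/BG dilated by 3 voxels
into the ventricle boundaries and the subarachnoid shell) — real tissue
masks are imperfect in exactly this way, and it is those leaks the
classifier must learn to reject. Mini-batches draw the three classes with
equal probability regardless of their raw counts, so the (heavily
dPVS-dominated) candidate sets do not collapse the classifier onto class
1. Augmentation applies per-patch random axis flips, additive Gaussian
noise (SD 0.05), an additive bias (±0.1) and a multiplicative scale
(±10%); amplitudes are configurable and deliberately mild, since the
normalized-intensity scale is fixed. The optimizer is plain SGD with
momentum 0.9 and learning rate 0.003, seeded; with training sets of only
tens of patches, larger rates (0.01 and above) occasionally diverge into
single-class collapse, while 0.001-0.003 separates the three synthetic
classes reliably within 10-20 epochs.

# Volumetry, reliability, validity

Regional volumes are voxel counts times the voxel volume (exactly
0.7^3 = 0.343 mm^3 at default spacing). Agreement uses the one-way
random-effects single-measure ICC, (MSB - MSW)/(MSB + MSW) for two
measurements per unit: it is invariant to member order within a pair,
which makes it the right flavour both for test-retest volumes and for
within-pair twin resemblance; the two-way absolute-agreement ICC(A,1) is
available behind a flag. Validity is summarized by the false-positive
fraction (automated volume outside truth / automated volume) and
false-negative fraction (truth missed / truth volume) — the only
normalization under which "0% FP with some FN" is a coherent description
of a conservative segmenter. Fractions here are whole-volume on
phantoms, not slice-based as a radiologist would score them.

# Phenotype preparation

Traits and continuous covariates are z-scored (sample SD, n-1).
Covariate adjustment uses the residual approach: OLS of the standardized
phenotype on an intercept plus standardized covariates, pooled over all
subjects, with residuals re-standardized before model entry
(re-standardization is recorded as a package choice; heritability is
invariant to it either way). Family clustering is deliberately ignored at
this step — it enters through the twin models. Two-level categorical
covariates (sex; a White/nonWhite ethnicity dichotomy) are coded 0/1. A
phenotype perfectly explained by its covariates leaves constant
residuals, which is an error by contract.

# Twin variance-component models

For a pair with additive-genetic relatedness r_A (1 for MZ, 0.5 for DZ
and NT; shared environment fully shared in all groups), the trait vector
of the two members is bivariate normal with diagonal a^2 + c^2 + e^2 and
off-diagonal r_A a^2 + c^2. The univariate ACE fit maximizes the summed
log density over all pairs with group-specific covariance and a single
free mean (traits are standardized residuals; group-specific means are
intentionally not fitted), paths constrained nonnegative, via bounded
quasi-Newton (`nlminb`) from a moment-based (Falconer) start plus a fixed
lattice of variance-share starts — deterministic given the data, no RNG.
DZ and NT enter as separate groups sharing r_A = 0.5, which reproduces
the usual conceptual pooling while keeping per-group diagnostics
available. Submodels AE/CE/E fix the dropped path at zero;
`compareModels` reports LRT statistics (naive chi-square reference, df =
paths dropped; the boundary-mixture correction would only make the
reported p smaller, so the naive reference is conservative) and AIC.
Internally the likelihood is evaluated from per-group sufficient
statistics (scatter matrices), making each evaluation O(1) in the number
of pairs; this is what makes 200-replicate recovery and coverage studies
cheap enough to run routinely.

The bivariate Cholesky model parameterizes each component's 2x2
covariance as L L' with lower-triangular L, diagonals nonnegative,
off-diagonals free in sign (negative cross paths are a real phenomenon in
bivariate twin fits and must not be constrained away). The pair
covariance is the 4x4 matrix with within-person block A + C + E and
cross-person block r_A A + C. From the fitted paths, genetic correlation
is a12 / sqrt(a12^2 + a22^2) — identical to the correlation implied by
A = L_A L_A' whenever a11 > 0, an identity the tests enforce — and shared
heritability is |a11 a12| / (|a11 a12| + |c11 c12| + |e11 e12|). The
absolute-value convention keeps the proportion in [0, 1] when paths are
negative; when signs make the unsigned and signed versions differ, the
signed value is attached as an attribute rather than discarded.

Confidence intervals are profile-likelihood by default (the set where
twice the log-likelihood drop stays below the chi-square(1) quantile,
found by bisection; boundary estimates yield one-sided intervals clipped
to the natural range). The profile is computed under a reparameterization
that pins the quantity of interest: (V, h2, c-share) for h2; a12
expressed through r_g and a22 for the genetic correlation; |a11 a12|
solved from the fixed ratio (both a12 signs tried) for shared
heritability. A percentile bootstrap over families is available as an
alternative. Simulated coverage for h2 = 0.6 at the default group sizes
is ~96% at nominal 95%.

One caveat worth stating explicitly: at 138/79/133 pairs the ML
heritability estimate is biased downward when c^2 is near its zero
boundary, by about 3 percentage points for a true h^2 of 0.90 with
c^2 = 0.02 (simulated E[h2-hat] ~ 0.871 over 1000 replicates). The bias
is entirely the c^2 >= 0 boundary truncation: refitting the same
replicates with the shared-environment covariance allowed to go negative
returns a mean of 0.902. Because the path parameterization (the field
standard, and what this package implements) cannot represent negative
shared-environment variance, this bias is a property of the estimator,
not of the optimizer — which the tests verify is exact against an
exhaustive multistart. The Falconer moment estimator, which has no
boundary, is unbiased in the same simulations and serves as the
independent cross-check. For traits whose c^2 sits well away from zero
(e.g. the h^2 = 0.658, c^2 = 0.16 configuration) the bias is negligible.

# Pipeline and problem sizes

`runPipeline` executes simulate -> segment -> train-cnn -> volumes ->
adjust -> heritability from a plain YAML-able config, fans a single
global seed out to per-stage seeds by a fixed splitting rule, and writes
a manifest with an MD5 hash of every output file, so a rerun with the
same config and seed is verifiably bit-identical in its deterministic
outputs. The demo configuration uses 64^3 phantoms (two of them) and the
standard 350-pair cohort; the test suite mostly uses 32^3-64^3 phantoms
and the same cohort sizes, which keeps the whole suite comfortably within
a coffee break on one CPU while exercising every stage at full
algorithmic fidelity — only the grids, never the methods, are scaled
down.

# Known limitations

- Phantom anatomy is schematic; results on phantoms bound algorithmic
  correctness, not clinical performance (no FLAIR-based discrimination of
  white-matter hyperintensities, which confound real T2-only dPVS
  segmentation).
- The classifier is trained per run on synthetic labels; no pretrained
  weights are shipped or claimed.
- Heritability modelling covers pairs only (no extended pedigrees), two
  traits at most, homogeneous group means/variances, and no
  sex-limitation or age-moderation models.
- The LRT for dropping A uses the naive chi-square reference at the
  boundary (conservative).
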