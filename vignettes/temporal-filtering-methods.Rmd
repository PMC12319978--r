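---
title: "Temporal filtering of fetal multiband fMRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal filtering of fetal multiband fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalfilter)
```

## The problem

In-utero BOLD fMRI combines low SNR with three classes of structured
artefact that standard adult pipelines do not address. First, imperfect
spatial corrections leave temporal traces: residual multiband (MB) leakage
between simultaneously excited slices, distortion-correction residuals, and
low-frequency drifts. Second, motion modulates the magnetisation history of
tissue, producing spin-history intensity waves that travel along the slice
axis and defeat methods that assume spatially stationary noise sources.
Third, the sequential MB sampling scheme itself — contiguous stacks of
`n_excitations` slices acquired one excitation apart, with a gap of almost
a full TR across stack edges — imprints slab-like spatial patterns with the
period of the stack. `fetalfilter` fits, per voxel, an ordinary
least-squares model whose regressors target these classes in order
(Group 1, Group 2, Group 3), and provides the quality control,
model-selection and group-level machinery around it.

## Acquisition geometry

Everything is parameterised by an `acq_scheme(n_slices, mb_factor, tr)`.
Under the sequential rule, excitation *e* (0-based) acquires slices
*e*, *e* + n<sub>exc</sub>, *e* + 2·n<sub>exc</sub>, …, with
n<sub>exc</sub> = n_slices / mb_factor. The reference acquisition is 48
slices at MB 3 and TR 2.2 s, i.e. 16 excitations, with every slice having
two simultaneously acquired partners. The within-band ordering is fixed as
contiguous stacks because that is the only layout consistent with a
near-TR temporal gap at stack edges; interleaved-within-band schemes are
rejected rather than silently mishandled. Slice indices are 0-based in all
APIs and TSV files.

## Group 1: detrending, censoring, folding and density maps

*Detrending.* `dct_detrend_basis()` uses the orthonormal type-II discrete
cosine basis, excluding the constant term; the GLM always carries an
explicit intercept instead, which keeps "number of detrending columns"
unambiguous. The default column count is `floor(2 · T · TR / cutoff)` with
a 150 s cutoff (0.0067 Hz), giving 10 columns at T = 350, TR = 2.2 s.

*Censoring.* The per-volume statistic `d_t` is the RMS deviation from each
voxel's temporal median, as a ratio to the grand mean intensity, computed
over the brain mask. A volume is censored when `d_t − median(d) > 0.05`
(strict inequality), and the immediate follower of every above-threshold
volume is censored as well — spin history degrades the next volume — but
followers do not themselves propagate. The median of `d` is computed once
over all volumes; the alternative (recomputing after exclusions) is not
iterated because the statistic is a ratio to a median and already robust to
the small censored fraction. Censored volumes stay in the series and are
neutralised by indicator (spike) regressors, which exactly zero the
residual at those volumes; deleting volumes instead would break the DCT
basis and the slice-state differentials.

*Folding maps.* For each partner offset k, the time course of the voxel
simultaneously acquired with the target voxel (same in-plane position,
slice shifted by k·n<sub>exc</sub> modulo n_slices) is assigned to the
target's location, giving MB − 1 voxel-wise confound maps that carry
whatever leakage the reconstruction left behind. When a spatial transform
is supplied, the maps are pushed through the same pull-back resampler (and
interpolation kernel) as the data, so corrected data and confound maps stay
in register.

*Density maps.* A uniform unit image pushed through the distortion/motion
transform with Jacobian modulation; any temporal dependence the correction
introduces shows up in this map and can be regressed out. With an identity
geometry the map is constant and carries no information — it is then
dropped by rank detection rather than by special-casing.

## Group 2: motion-parameter stacks and non-GM ICA

Each excitation has its own 6 rigid parameters (3 rotations in degrees,
3 translations in mm), so MP regressors are voxel-specific: the parameter
value is broadcast to the excitation's slices. Slice differentials are
computed on the slice-state rearrangement S<sub>1</sub> …
S<sub>T·n<sub>exc</sub></sub> as the forward difference
S<sub>t+1</sub> − S<sub>t</sub> (zero at the final state), capturing
dynamics along the axis in which spin history operates. Volume
differentials Δ<sub>v</sub> and Δ²<sub>v</sub> are zero-padded backward
differences, keeping columns full length. The complete per-voxel set is 10
blocks × 6 parameters = 60 columns; columns are z-scored with statistics
from non-censored volumes, degenerate (zero-variance) columns are flagged
and left at zero, and per-voxel PCA retains the smallest component count
reaching 99 % cumulative variance on non-censored volumes, with loadings
applied to all volumes. Differencing happens in acquisition-state order
*before* any spatial transform: the differentials describe the sampling
process, not the resampled image. Without a transform all voxels of an
excitation share one design, which the fitting engine exploits by grouping.

Data-derived regressors are the time courses of a spatial ICA restricted to
the WM + CSF mask eroded by one voxel (6-connectivity cross, one
iteration) after residualisation against Group 1. Dimensionality is fixed
(6 or 24) or chosen by the Minka Laplace-evidence criterion capped at 90.
The ICA is a symmetric fixed-point stationary ICA with tanh contrast,
deterministic given its seed, with component signs fixed by positive map
skew; no claim of bit-compatibility with any external tool is made, only
the contract (dimensionality, determinism, unit-variance time courses).

## Group 3: slab components and partial regression

The Group 1 + 2 residual is smoothed with a 1 mm FWHM Gaussian (separable
kernel, truncated at 3σ, edge-renormalised) and decomposed by spatial ICA
into 30 components. Rating is deliberately manual: two raters label each
component `remove` / `equivocal` / `keep`, and a component is removed only
under the consensus rule (both `remove`, or `remove` + `equivocal`).
`slab_score()` — the fraction of a map's slice-profile spectral power at a
period of n<sub>exc</sub> slices — is provided as an advisory aid and never
removes anything by itself. Because component time courses are not
orthogonal, removal uses partial regression: coefficients for all
components are estimated jointly (plus intercept) and only the flagged
contribution is subtracted, leaving the non-flagged components' fitted
share untouched (their re-estimated coefficients are unchanged, a property
the tests assert exactly).

## The per-voxel GLM engine

`denoise_fit()` concatenates intercept, shared design and the voxel's
group-specific design and solves by pivoted QR (tolerance 1e-10), dropping
collinear columns with a warning. The decomposition
`input = residual + removed + intercept fit` holds exactly, residuals are
orthogonal to the design, and effective degrees of freedom lost per voxel
equal the design rank (intercept and spike columns included).
`denoised_series()` returns residual + intercept fit — the filtered data
with baseline level preserved, on which TSNR remains interpretable.
Per-voxel MP components are fitted jointly with shared columns rather than
pre-orthogonalised; joint estimation is the standard GLM answer and avoids
order dependence.

## Quality control

TSNR is `mean_i(M_i / SD_i)` with population SDs (divide by T) over
uncensored volumes within a tight anatomical mask; zero-variance voxels are
excluded from the spatial mean and counted. DVARS is the mean RMS frame
difference over consecutive uncensored pairs. The pass/fail rule computes
P25/P75/IQR (linear-interpolation percentiles, the common default; the
choice is configurable only by editing, as nothing in the pipeline is
sensitive to it at the IQR-fence scale) over scans with visual score > 1;
high-score scans fail only as DVARS or TSNR outliers, low-score scans are
rescued when both metrics are inside the P75/P25 bounds. The visual score
itself is consumed as an integer 0–4; its semantics are the rater's.

## Signal implanting and model selection

`implant()` adds a maps × time-courses product scaled so that the spatial
mean of its voxel-wise temporal SDs equals `scale` (3 % or 6 %) of the
data's. The scan-global normalisation (rather than voxel-wise) preserves
the maps' spatial shape; this was an open choice and is recorded as such.
`implant_test()` denoises the implanted series, estimates time courses by
spatial regression of the maps (plus an intercept map) against the
residual and against the removed component, and correlates each vectorised
product with the vectorised implant: recovery and loss statistics. Two
properties of the operating point matter for interpretation: the statistics
are invariant to global intensity scaling, and because the implant is tied
to the data SD, recovery under a weak model is limited by the ratio of the
implant scale to the spatial-regression noise floor — it rises with grid
size and with map compactness, which is why desk-scale checks use compact
maps and the full-size checks use the 24 × 24 × 48 × 120 grid.

## Group-level fusion

`age_balanced_pca_ica()` implements the two-stage compression: per-age
temporal concatenation → PCA to n<sub>pc</sub> spatial components →
z-scoring within component across voxels → concatenation across ages →
PCA to n<sub>pc</sub> → spatial ICA into n<sub>ic</sub> modes. Z-scoring
equalises each component's scale so every age contributes evenly and
factorisation attends to shared patterns; the tests assert the unit
variance property exactly. Two numerical subtleties are handled
deliberately: principal-component signs are fixed (largest-magnitude
loading positive) so the result is invariant to subject ordering, and the
second compression and the ICA whitening skip voxel-mean removal because
z-scored component rows are already centred — re-demeaning would discard
one rank per stage and, in small problems, let variance-inflated noise
components displace signal. A consequence worth knowing: with a single age
group there is no cross-age replication to re-rank z-scored components, so
the procedure equals plain PCA + ICA only when n<sub>pc</sub> matches the
dimensionality of real structure; choosing n<sub>pc</sub> far above it
dilutes the modes. n<sub>pc</sub> is configurable (1400 in the reference
setting) and auto-capped at the available rank.

Downstream, `dual_regress()` gives per-subject time courses,
`edge_age_fit()` fits each edge by OLS on demeaned age — correlations are
Fisher z-transformed by default (`fisher = FALSE` gives raw-r mode; the
transform stabilises variance across the r range and is the recorded
deviation knob) — and `embed_cluster()` zeroes negative entries, embeds on
the eigenvectors of the `n_dims = 3` smallest non-null eigenvalues of the
symmetric normalised Laplacian, and cuts a Ward (`ward.D2`) hierarchy.
Disconnected graphs are flagged; components are embedded separately and
kept apart during clustering via component indicators. Left–right
symmetrised-template analyses are out of scope: the seed-map machinery
operates in a single space.

## The synthetic generator: what it does and does not emulate

`make_scene()` fixes the study conditions: 350 volumes of 48 slices at
MB 3, TR 2.2 s; baseline 100 a.u. with white Gaussian noise SD 5, giving
TSNR ≈ 20, typical of in-utero acquisitions; K = 3 unit-norm Gaussian
network maps in a GM shell (pairwise spatial |r| < 0.3, resampled if
violated) with unit-variance smoothed time courses at amplitude 20 a.u.
(peak fluctuations ≈ 4 % of baseline); a half-cycle cosine drift of
2 a.u.; a travelling wave of 2 a.u. with a 30-volume period whose phase
advances with excitation index and motion magnitude; leakage fraction 0.1
of the mean partner-slice signal; motion as a per-excitation random walk
(step 0.02 deg/mm) with spikes at 2 % of volumes accompanied by 50 a.u.
intensity offsets (10 × noise SD); and a smooth Jacobian field within
±5 % of unity. Values the reference acquisition does not pin (noise model,
wave form, leakage level, motion scale) were chosen once as plausible for
the domain and are exposed as arguments, not revisited.

The generator is a test surface, not a physics simulation: the wave is a
sinusoidal stand-in for spin history, not a Bloch model; anatomy is an
ellipsoid with concentric tissue shells; noise is white and Gaussian,
without physiological spectra or spatial autocorrelation; leakage is a
fixed fraction of the partner mean rather than a reconstruction model.
Passing tests therefore demonstrate that every formula, rule and estimator
behaves as specified under known ground truth — they do not certify
performance on real scans, where signal and noise need not be additive and
real-data statistics (pass rates, DOF losses, component counts) live.

## Problem sizes and numerical choices

Unit tests run on a 12-slice MB-3 miniature of the geometry; end-to-end
checks use 24 × 24 × 48 grids with 120 volumes, sizes at which every stage
(including per-voxel fits at ~12 000 brain voxels) completes in seconds to
a few minutes on one core — the package's chosen desk scale. Tolerances:
QR rank tolerance 1e-10; scalar-formula oracles are matched to 1e-12;
orthonormality to 1e-10; erosion uses the 6-connectivity cross; medians are
the standard midpoint-interpolating median; percentiles are
linear-interpolation (type 7). Degenerate inputs error loudly (all volumes
censored, empty eroded mask, zero-variance seed, rank-deficient component
designs list their collinear columns) rather than returning silent
defaults.

## Known limitations

No prewhitening or low-pass filtering (left to the user by design); no
estimation of motion or distortion fields (parameters and fields are
consumed, not estimated); the resampler is a per-excitation rigid pull-back
with trilinear interpolation, adequate for applying transforms to confound
maps but not a slice-to-volume reconstructor; manual Group 3 ratings enter
via labels, so fully automated pipelines must either accept the advisory
slab score's guidance explicitly or skip Group 3; and the group-ICA stage
assumes subjects share a voxel grid — template registration is outside the
package.
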