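---
title: "connforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{connforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures `connforge` implements,
the tunable parameters and their defaults, what the synthetic generators do
and do not emulate, and the design choices made where the problem was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. Seeding masks and the GM/WM interface

Probabilistic tractography between parcellated regions needs seed and target
masks placed where fibers enter the white matter. `connforge` builds them
from co-registered tissue masks:

1. **Subcortical merge** (`merge_subcortical`): model-based subcortical
   segmentations are unioned into the gray matter (GM) mask, since
   intensity-driven tissue classification is unreliable for deep gray
   structures.
2. **Lesion reassignment** (`reassign_lesions`): white matter (WM) lesions
   misclassified as GM are removed from the GM mask, and those voxels that
   were GM are added back to WM. The operation conserves the tissue union —
   a property the tests check by set arithmetic.
3. **GM labeling** (`label_gray_matter`): each GM voxel takes the
   parcellation label at its position. `fill_radius_mm` (default **0**, i.e.
   no fill) optionally assigns unlabeled GM voxels the label of the nearest
   labeled voxel within a world-space radius; registered parcellations
   routinely miss a rim of GM voxels, but filling is opt-in because it
   extrapolates labels. Nearest is Euclidean in mm (anisotropic voxels are
   handled through the affine); at exactly equal distance the smallest label
   wins, a deterministic and test-friendly tie-break.
4. **Interface extraction** (`extract_interface`): the interface is the set
   of WM voxels with at least one GM neighbor. The neighborhood is
   configurable (6, 18, 26); the default is **26**, the most inclusive
   choice, because seeding favors not missing entry points. Voxels flagged
   both GM and WM are treated as GM (GM precedence) and excluded from the
   interface.
5. **Interface labeling** (`label_interface`): each interface voxel takes
   the majority label among its labeled GM neighbors; ties break toward the
   smallest label index; a voxel with no labeled GM neighbor stays 0.
   Drawing labels from adjacent GM (rather than from the parcellation volume
   at the WM voxel itself) keeps seeds attached to the region they abut.

Coordinates follow the NIfTI convention: voxel indices are 0-based and world
coordinates are `affine %*% (i, j, k, 1)` in RAS mm. All volumes entering an
operation must share one grid; registration is explicitly the caller's job.

The package ships a minimal NIfTI-1 reader/writer (`read_nifti`,
`write_nifti`) because no NIfTI package is available in the target
environment; it covers 3D/4D single-file images, the sform/qform affines and
the integer/float datatypes the pipeline exchanges.

## 2. Functional connectivity and functional IDPs

`extract_roi_timeseries` computes the unweighted mean BOLD signal over each
ROI's voxels (no partial-volume weighting — the natural reading of "average
response across voxels"). Empty ROIs yield all-`NA` columns flagged invalid
rather than being dropped, so FC matrices keep the parcellation's dimensions
and align with the structural connectome.

`pearson_fc` is the standard Pearson correlation between ROI time series;
pairs involving invalid or zero-variance series are `NA`, the diagonal is 1.

Functional IDPs:

* **tSNR** (`tsnr`): per voxel, temporal mean over temporal *sample* SD
  (denominator n−1; the unbiased-variance convention, chosen because runs
  are finite). Zero-variance voxels are excluded from the mask summary.
* **Framewise displacement** (`framewise_displacement`):
  FD_t = Σ|Δtranslation| + r·Σ|Δrotation| with head radius r = **50 mm**, the
  conventional small-angle arc-length approximation. The first frame is 0 by
  convention; summaries cover frames 2..T. This stands in for
  realignment-tool-specific displacement outputs, whose exact formulas are
  not public; precomputed displacement traces can be used directly.
* **FC distribution summaries** (`fc_summaries`): mean, median, SD, min,
  max, range, skewness, excess kurtosis (population moment estimators
  m₃/m₂^{3/2} and m₄/m₂²−3), proportion of positive correlations and
  proportion |r| > 0.5 over the valid upper triangle. This set reconstructs
  the "center, range, shape" summaries used for QC; it is not a published
  phenotype list, and the proportions flag the compressed,
  strongly-positive FC distributions typical of residual motion artifact.

## 3. Structural connectome and TheVirtualBrain export

`normalize_weights` divides the streamline-count matrix by the **grand
total** of streamlines successfully sent from all seed ROIs — a single
scalar, making the weights an estimate of connection probability among sent
streamlines. Because "sent from the seed ROIs" can also be read per seed,
`per_seed = TRUE` divides each row by its own waytotal; the scalar reading
is the default. No thresholding or other post-processing is applied, by
design.

`symmetrize` (default **mean**; max and sum available) combines the two
directed estimates, since tractography cannot infer fiber direction; the
diagonal is forced to 0. `symmetrize_lengths` averages the two directed
tract-length estimates when both directions produced streamlines, keeps the
single nonzero one otherwise, and zeroes lengths wherever the symmetrized
weight is zero, preserving the `weights = 0 ⇒ lengths = 0` invariant of the
`connectome` container.

`export_tvb_zip` writes the five-file TheVirtualBrain archive with one fixed
dialect: `hemispheres.txt` uses 0 = left, 1 = right (midline ROIs are
written 0 — TVB has no third code), `cortical.txt` uses 0/1, and ROI names
in `centres.txt` have whitespace replaced by underscores so the file always
has exactly four columns. Numbers are printed with `%.17g`, which
reconstructs doubles exactly: export → read → export is byte-identical, and
the tests assert it at the byte level.

## 4. Mean-centered PLS of IDPs against QC ratings

Given n subjects with p IDPs **X** and ordinal ratings (5-point scale,
1 = excellent … 5 = poor):

1. Missing IDP entries are imputed by their **column median** (robust, and
   neutral after z-scoring; missingness policy is this package's choice).
2. Columns are **z-scored over all subjects**. IDPs have wildly different
   units; without scaling, high-variance IDPs would dominate the covariance.
   Zero-variance columns become all-zero rather than NaN.
3. Per-rating-group means **G** (g × p) are formed and the unweighted grand
   mean of group means is subtracted: `M = G − 1 ḡᵀ` — mean-centered
   "task" PLS over rating groups, which directly produces the described
   outputs (a design contrast over ratings plus IDP saliences). A
   dummy-coded behavioral-PLS variant would be an alternative formulation
   but is not the default.
4. `pls_svd` takes the thin SVD `M = U S Vᵀ`. Centering removes one degree
   of freedom across the g rows, so **L = min(g − 1, p)** latent variables
   are retained, ordered by singular value. The covariance percentage of LV
   l is `100 s_l² / Σ s²` (sums to 100 within 1e−9, asserted). Sign
   convention: the largest-magnitude design salience of each LV is made
   positive (ties break to the first group), making results reproducible
   across SVD implementations.
5. **Permutation test**: ratings are shuffled without replacement (IDP rows
   fixed), steps 3–4 are re-run, and `p_l = (1 + #{s*_l ≥ s_l})/(1 + n_perm)`
   with the default n_perm = 1000. The add-one estimator avoids zero
   p-values; its floor 1/(n_perm+1) ≈ 0.001 is consistent with reporting
   p = 0.001 at 1000 permutations. Permuted singular values are compared at
   the matched LV position by default; a max-statistic variant
   (familywise-style) is available via `statistic = "max"`. Because column
   z-scores are invariant under label permutation, the z-scored matrix is
   computed once — an exact optimization, not an approximation.
6. **Bootstrap**: subjects are resampled with replacement **within** rating
   class (n_boot = 500 default); the full preparation and SVD are re-run per
   resample. Bootstrap saliences are aligned to the original solution by
   orthogonal Procrustes rotation of the design saliences — standard PLS
   practice, since reflections/rotations between resamples are arbitrary; a
   per-LV sign-flip alignment is available via `align = "sign"`. The
   bootstrap ratio is the original salience over the element-wise bootstrap
   SD; zero-SE elements get ±Inf (flagged, not an error). `reliable_idps`
   applies the conventional |BSR| ≥ 2 cutoff.

All resampling is driven by a single integer seed; identical seeds give
identical index streams and therefore identical results.

## 5. QC thresholds and the HTML report

`evaluate_thresholds` uses **inclusive** bounds (pass iff
lower ≤ value ≤ upper; an absent bound is unbounded) — the boundary
convention is this package's choice and is pinned by tests. Missing values
report `missing`; IDPs without a spec entry report `no-threshold`. Threshold
values are dataset-specific and deliberately ship without defaults.

`render_report` writes one self-contained HTML file per subject: the
color-coded IDP table plus optional panels (FC heatmap and histogram, SC
weights heatmap on a log10 scale with floor ε = smallest nonzero weight /
10 so zeros render, SC weight histogram, ROI time-series carpet plot,
framewise-displacement trace). Images are embedded as base64 PNG; the page
references no external resources, so it opens offline. Degenerate inputs
(e.g., an empty connectome) produce an explicit "no data" placeholder.
Brain-slice overlays and ICA-report reconstruction are out of scope: they
depend on external visualization tooling.

## 6. Synthetic generators: what a green test establishes

* `make_phantom`: a solid WM ellipsoid inside a GM shell, the shell
  partitioned into angular sectors split by hemisphere (x below the grid
  center = left). This geometry was chosen because ROI adjacency, hemisphere
  membership, centroids and the seeding interface are all analytically
  known, enabling exact oracles; the ground-truth interface is computed by
  direct per-voxel neighbor enumeration, independent of the package's
  shift-based implementation. Optional spherical lesion blobs live inside
  WM.
* `make_bold`: per-ROI latent signals from a multivariate normal with the
  requested correlation matrix; each voxel adds iid Gaussian noise
  (default SD 1) and a baseline offset of **100**, mimicking scanner-scaled
  data so tSNR is finite and positive.
* `make_counts`: each seed's streamlines are allocated multinomially over
  targets plus a "not accepted" bin, emulating probabilistic-tractography
  counts with waytotal = streamlines sent (default 5000 per seed, the scale
  at which empirical proportions concentrate within ±0.02 of the truth).
* `make_idp_ratings`: subject IDP vectors are
  (group score) × (effect size) × (unit salience pattern) + iid noise, with
  group scores equally spaced in [−1, 1] over the rating levels — a rank-1
  association by construction, with `effect_size = 0` an exact null. The
  default study shape used in the acceptance tests mirrors a 5-level rating
  design with equal group sizes.

These generators emulate geometry, correlation structure and sampling noise
— not MRI physics. A green test establishes that the estimators recover
planted structure under the stated noise model; it does **not** establish
robustness to distortion, motion, partial-volume effects or registration
error, which upstream tools handle in a real pipeline.

## 7. Numerical choices and limitations

* Matrix text payloads are written with `%.17g` (exact double round trip);
  masks are uint8, labels int32, BOLD float32/float64 on disk.
* Interface/label tie-breaks, the SVD sign convention and the add-one
  permutation estimator are all chosen for determinism and documented above.
* The permutation test is calibrated per matched LV position; like all
  position-matched PLS permutation schemes it is slightly conservative for
  trailing LVs.
* The exact set of 75 published pipeline phenotypes is not reproduced (the
  defining supplementary material is not public); the implemented IDP
  families (tSNR, motion, FC/SC summaries) follow the categories named in
  the main text.
* The original study's headline results require restricted subject data and
  are not reproduced; all quantitative validation here is property-based on
  synthetic data at the sizes stated in the acceptance tests.
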