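# connforge

`connforge` implements the bespoke computational stages of a
parcellation-driven MRI pipeline that prepares inputs for connectome-based
whole-brain modeling (e.g., in TheVirtualBrain) and validates their quality:

* **Seeding masks** — refine tissue masks (merge a subcortical segmentation
  into gray matter, reassign white-matter-lesion voxels), label gray matter
  with a parcellation, and extract the **gray-matter/white-matter interface**
  (white matter voxels adjacent to gray matter), labeled per ROI as the
  seed/target masks for probabilistic tractography.
* **Functional connectivity** — mean ROI BOLD time series and the Pearson
  functional connectivity (FC) matrix.
* **Structural connectivity** — streamline-count matrices normalized by the
  total number of streamlines sent (`W = C / Σ waytotal`, an estimate of
  connection probability), symmetrized together with the tract-length matrix,
  and exported as a TheVirtualBrain connectivity zip
  (`weights.txt`, `tract_lengths.txt`, `centres.txt`, `hemispheres.txt`,
  `cortical.txt`).
* **Image-derived phenotypes (IDPs)** — temporal SNR, framewise
  displacement, FC/SC distribution summaries, with pass/fail evaluation
  against user-defined thresholds and a standalone HTML QC report.
* **PLS validation of IDPs** — mean-centered partial least squares between
  the subject × IDP matrix **X** and ordinal QC ratings: with `Z` the
  column-z-scored IDPs, the cross-block matrix is the grand-mean-centered
  matrix of rating-group means, `M = G − 1 ḡᵀ`, and its SVD
  `M = U S Vᵀ` yields latent variables (IDP saliences `V`, rating design
  contrasts `U`, singular values `S`). Significance comes from rating
  permutations (`p = (1 + #{s* ≥ s}) / (1 + n_perm)`), reliability from
  within-group bootstrap resampling (bootstrap ratio = salience / bootstrap
  SE; |BSR| ≥ 2 is reliable).

Synthetic generators (phantom brain with an analytically known interface,
BOLD with planted correlations, multinomial streamline counts, IDP tables
with planted latent effects) make every stage testable without imaging data.

## Worked example

```r
library(connforge)

# synthetic phantom: WM ellipsoid in a parcellated GM shell, 8 ROIs
ph <- make_phantom(phantom_spec(seed = 1))
iface <- extract_interface(ph$gm, ph$wm, connectivity = 26)
labeled_gm <- label_gray_matter(ph$gm, ph$parcellation)
seeds <- label_interface(iface, labeled_gm)
sum(iface$data)
#> [1] 536
roi_volumes(seeds, ph$table)[1:3, ]
#>   index        name n_voxels volume_mm3
#> 1     1 sector_L_01       67         67
#> 2     2 sector_L_02       67         67
#> 3     3 sector_L_03       67         67

# PLS of a simulated QC study: 5 rating groups x 40 subjects, a planted
# effect of 1.5 noise-SD on 3 of 20 IDPs
sim <- make_idp_ratings(rep(40, 5), planted_salience = c(1, 1, 1, rep(0, 17)),
                        effect_size = 1.5, seed = 2)
model <- pls_qc(sim$idps, sim$ratings, n_perm = 1000, n_boot = 500, seed = 3)
model
#> <pls_model> 4 latent variable(s), 5 rating groups
#>  LV singular_value pct_covariance   perm_p
#>   1         2.2340           77.2 0.000999
#>   2         0.8495           11.2 0.078900
#>   3         0.7135            7.9 0.075900
#>   4         0.4910            3.7 0.401000
reliable_idps(model, lv = 1)
#>      idp   salience        bsr
#> 1 idp_03 -0.6091031 -18.031776
#> 2 idp_02 -0.5945388 -16.548058
#> 3 idp_01 -0.4592439 -10.281760
#> 4 idp_10  0.1608186   2.303878
```

The first latent variable captures the planted rating–IDP association: it is
the only one significant at the permutation floor (`p = 1/1001`), explains
77% of the cross-block covariance, and the three planted IDPs dominate its
reliable saliences (`idp_10` is a false positive at the conventional
|BSR| ≥ 2 cutoff — bootstrap ratios behave like Z-scores, so occasional
exceedances among 20 IDPs are expected).

## Command line

```sh
inst/bin/connforge simulate phantom --seed 1 --out-dir sim/
inst/bin/connforge masks --gm sim/gm.nii.gz --wm sim/wm.nii.gz \
    --parc sim/parcellation.nii.gz --lut sim/lut.tsv --out-dir out/
inst/bin/connforge pls --idps idps.tsv --n-perm 1000 --n-boot 500 \
    --seed 7 --out-dir pls_out/
```

(After installation the launcher is at
`system.file("bin/connforge", package = "connforge")`.)

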