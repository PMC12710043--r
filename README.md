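# phyllo3d

Phyllotaxy — the azimuthal arrangement of leaves around the stem — is one
of the hardest canopy-architecture traits to measure at scale. Crop
canopy models usually assume grasses alternate leaves at exactly 180°,
but testing that assumption across hundreds of genotypes requires a
measurement pipeline, not a protractor. `phyllo3d` implements that
pipeline end to end for plant phenotyping and quantitative-genetics
researchers: from calibrated multi-view binary silhouettes to voxel-carved
visual hulls, skeletons, stem/leaf segmentation, per-leaf angles in the
stem's principal-axis frame, and on to broad-sense heritability and
resampling genome-wide association.

Because real imaging data is bulky and noisy, the package ships a
procedural generator of sorghum-like plants with known ground truth, so
every stage is testable offline.

## The measurements

* For leaves ordered by attachment height with azimuths φᵢ, the
  phyllotaxic angles are φᵢ = (ϕᵢ₊₁ − ϕᵢ) mod 360 and their deviations
  from perfect alternation Φᵢ = |φᵢ − 180°|. Angles outside [90°, 270°]
  (equivalently Φ > 90°) are filtered as unreliable.
* Each angle has a conjugate 360° − φ — the same leaf pair measured from
  the other side of the plant. `align_pair()` removes this arbitrary
  side effect using the sign of the per-plant Pearson correlation, and
  `repeatability_r2()` pools aligned pairs into a squared correlation.
* Reconstruction accuracy is the Dice coefficient 2|A∩B|/(|A|+|B|)
  between reprojected hull and input silhouettes; reconstructions under
  0.70, or whose skeleton is not a tree, are rejected.
* Broad-sense heritability comes from the one-way random-effects model
  Y = μ + δᵢ + ε with H = σ²G / (σ²G + σ²R/n), n = 2.
* Associations are summarized by the resampling model inclusion
  probability (RMIP): the fraction of 100 reruns, each with 10 % of
  phenotype records masked, in which a marker beats the Bonferroni
  threshold α/Mₑ over effective markers.

## Worked example

Simulate a plant with known leaf azimuths, image it with five turntable
side views plus a top view, reconstruct at 128³ voxels, and measure:

```r
library(phyllo3d)
spec <- random_plant_spec(7)
spec
#> <plant_spec> 6 leaves, stem height 318.4 mm
#>   true phyllotaxy (deg): 174.2, 207.2, 174.9, 213.6, 180.5
out <- simulate_and_measure(spec, resolution = 128)
out
#> <plant_reconstruction> Dice = 0.972 | tree topology: TRUE | accepted: TRUE
#> <phyllotaxy_record> 6 leaves measured
#>   rank theta_deg phi_deg attach_height_mm
#> 1    1      76.0   338.8               63
#> 2    2      45.0   151.7              117
#> 3    3      54.3   358.5              153
#> 4    4      45.2   173.2              213
#> 5    5      50.5    27.8              285
#> 6    6      66.6   209.5              321
#> phyllotaxic angles (deg): 172.9, 206.8, 174.7, 214.6, 181.6
```

The reconstruction is accepted (aggregate reprojection Dice 0.972 ≥ 0.70,
tree topology), all six leaves are found, and the five measured
phyllotaxic angles track the generator's truth (174.2, 207.2, 174.9,
213.6, 180.5) to within about 1°.

The quantitative-genetics tail works the same way against simulated
populations with known variance components:

```r
pop <- make_population(200, reps = 2, h2_target = h2_for_H(0.25), seed = 1)
fit <- heritability(pop$phenotypes$value, pop$phenotypes$genotype_id)
fit
#> <heritability_fit> H = 0.225  (n = 2 , reml )
#>   sigma_G2 = 0.1268  sigma_R2 = 0.8732  genotypes: 200  plants: 400
bonferroni_threshold(0.05, 1088251.19)
#> [1] 4.59e-08
```

Here a population built to have H = 0.25 at two replicates is estimated at
0.225 from one draw, and the Bonferroni threshold over ~1.09 million
effective markers reproduces 4.59 × 10⁻⁸.

A thin command-line front end covering simulation, reconstruction,
measurement, heritability and RMIP lives at `inst/exec/phyllo3d` (run it
with `Rscript`).

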