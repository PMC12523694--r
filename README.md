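# singlestep

Single-step genomic BLUP (ssGBLUP) evaluation machinery for dairy
populations, built for studying how the construction of the hybrid
relationship matrix — blending, tuning and scaling — changes the accuracy of
genomic breeding values when only a small fraction of a large recorded
population is genotyped.

## The problem and the model

National dairy evaluations predict breeding values from lactation records
with the repeatability animal model

```
y = Xb + Za + Wpe + e,      a ~ N(0, K σ²a),  pe ~ N(0, I σ²pe),  e ~ N(0, I σ²e)
```

with herd–year–season, parity and age-at-calving fixed effects. Pedigree
BLUP (ABLUP) uses `K = A`, the numerator relationship matrix. Single-step
GBLUP evaluates genotyped and ungenotyped animals jointly by replacing
`A⁻¹` with

```
H⁻¹ = A⁻¹ + [0 0; 0 τ·Gb⁻¹ − ω·A22⁻¹]
```

where `G` is VanRaden's genomic relationship matrix for the genotyped
animals, `A22` their pedigree block, and `Gb` the genomic matrix after

* **tuning** (TG0–TG4: rebasing `G`'s diagonal/off-diagonal means to 1/0 or
  to `A22`, equal overall means, or an Fst-style rescale),
* **blending** `Gb = (1−β)·G + β·A22` (residual polygenic fraction β),
* **scaling** by the weights τ (on `Gb⁻¹`) and ω (on `A22⁻¹`).

Prediction quality is measured by forward validation: mask every record of
the *n* most recent genotyped cows, refit, and compute the realized accuracy
`cor(EBV_ABLUP_full, EBV_model_reduced)` over those cows. The package also
ships a synthetic dairy-population generator (multi-generation pedigree,
gene-dropped SNP haplotypes, repeated lactation records with
herd–year–season structure), so every stage — pedigree renumbering,
genotype QC, relationship matrices, mixed-model solving, validation sweeps —
is testable end to end without proprietary data, and estimated breeding
values can additionally be scored against the simulated truth.

## Worked example

```r
library(singlestep)

cfg <- simConfig(nFounders = 80, nGenerations = 3, nOffspringPerGen = 200,
                 nSnps = 400, nQtl = 120, nHerds = 8, nSiresPerGen = 10,
                 genotypedFraction = 0.25, seed = 2024)
bundle <- studyBundle(cfg, nValidation = 40)   # simulate, edit, group, mask
bundle$ped
#> PedigreeTable with 1100 animals ( 539 founders )
bundle$panel
#> GenotypePanel: 247 individuals x 400 loci (0.00% missing)
bundle$plan
#> ValidationPlan: 40 validation cows; 884 full / 831 reduced records

res <- runValidationStudy(cfg, nValidation = 40)
round(res$realized, 3)
#>   ablup ssgblup
#>   0.597   0.386
round(res$true, 3)
#>   ablup ssgblup
#>   0.433   0.343

sw <- runSweep(bundle, mode = "blending", traits = "milk")
sw[, c("model", "trait", "accuracy")]
#>           model trait accuracy
#> 1         ABLUP  milk    0.597
#> 2 ssGBLUP_G0.95  milk    0.386
#> 3 ssGBLUP_G0.90  milk    0.396
#> 4 ssGBLUP_G0.80  milk    0.415
#> 5 ssGBLUP_G0.70  milk    0.436
#> 6 ssGBLUP_G0.60  milk    0.457
```

`realized` is the correlation of each reduced-data model with the full-data
ABLUP reference for the 40 masked cows; `true` is the correlation with the
simulated breeding values, available only because the data are synthetic.
The blending sweep shows accuracy rising as the polygenic weight β grows
from 0.05 (`ssGBLUP_G0.95`) to 0.40 (`ssGBLUP_G0.60`) — on this toy
population the genomic matrix alone is a noisy relationship estimate, and
re-weighting the pedigree block recovers accuracy. The two metrics can rank
models differently; the methods vignette
(`vignettes/single-step-evaluation.Rmd`) explains why the shared pedigree
information pathway inflates the ABLUP-vs-ABLUP correlation and why the
truth-based metric is the better yardstick on synthetic data.

`runSweep(mode = "tuning")` and `runSweep(mode = "scaling")` run the TG0–TG4
and τ/ω grids (5 and 10 models per trait respectively), one lever at a time
with the others at the standard configuration (β = 0.05, TG2, τ = ω = 1).

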