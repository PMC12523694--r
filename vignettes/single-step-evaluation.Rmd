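---
title: "Single-step GBLUP evaluation: the hybrid relationship matrix and its levers"
author: "singlestep package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GBLUP evaluation: the hybrid relationship matrix and its levers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singlestep)
```

## The model

Dairy lactation records are analysed with a single-trait repeatability animal
model

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{Wpe} + \mathbf{e},$$

where the fixed effects **b** are herd–year–season contemporary groups,
parity, and age at calving fitted as a linear covariate nested within parity;
**a** $\sim N(0, \mathbf{K}\sigma^2_a)$ are additive genetic effects over the
*full* pedigree (ancestors without records get equations); **pe** $\sim N(0,
\mathbf{I}\sigma^2_{pe})$ is the permanent-environment effect tying a cow's
repeated lactations together; and **e** $\sim N(0, \mathbf{I}\sigma^2_e)$.
Solutions come from Henderson's mixed model equations; `solveMME()` uses a
sparse Cholesky factorisation by default (which also permits prediction-error
variances from the inverted coefficient matrix) and offers Jacobi-
preconditioned conjugate gradients (relative residual $<10^{-10}$) for large
systems where PEV is not needed.

With $\mathbf{K} = \mathbf{A}$, the pedigree numerator relationship matrix,
this is classical pedigree BLUP (ABLUP). Single-step GBLUP replaces
$\mathbf{A}^{-1}$ with

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\begin{pmatrix} \mathbf{0} & \mathbf{0} \\
\mathbf{0} & \tau\,\mathbf{G}_b^{-1} - \omega\,\mathbf{A}_{22}^{-1}
\end{pmatrix},$$

where $\mathbf{G}_b$ is the (tuned, blended) genomic relationship matrix of
the genotyped animals, $\mathbf{A}_{22}$ the pedigree block for the same
animals, and $\tau, \omega$ scalar weights. `assembleHInverse()` scatters the
genotyped-block correction into the full-pedigree matrix by animal label;
with $\tau=\omega=1$ and $\mathbf{G}_b=\mathbf{A}_{22}$ the correction
cancels exactly and ssGBLUP solutions coincide with ABLUP — a test identity
the suite exercises.

## Relationship matrices

* `buildA()` uses the tabular recursion. `buildAInverse()` builds the sparse
  inverse directly from pedigree structure with Mendelian-sampling variances
  from parental inbreeding; inbreeding itself comes from the Meuwissen–Luo
  ancestor-accumulation algorithm, so the inverse never forms **A**. The two
  routes are compared against each other (and dense inversion) in the tests.
* `extractA22()` takes the principal submatrix of the full-pedigree **A**.
  This retains relationships transmitted through ungenotyped ancestors —
  building **A** on a pruned genotyped-only pedigree loses them, and a test
  documents the difference on a half-sib counterexample. The inverse is dense
  (the intended scale is a few thousand genotyped animals).
* `buildG()` is the allele-frequency-weighted cross-product of centred
  dosages (VanRaden's first method), frequencies observed in the genotyped
  set, missing dosages mean-imputed before centring.

## The experimental levers

**Blending** (`blendG()`) gives weight $\beta$ to the pedigree block:
$\mathbf{G}_b = (1-\beta)\mathbf{G} + \beta\mathbf{A}_{22}$, guaranteeing a
nonsingular genomic matrix and reintroducing residual polygenic variance.
The default acts on the matrices before inversion — the behaviour of the
standard evaluation software — while a `literal_inverse` mode blends the
inverses directly, since the formula is sometimes written that way; the two
coincide exactly when $\mathbf{G} = \mathbf{A}_{22}$ and differ measurably
otherwise.

**Tuning** (`tuneG()`) rebases **G** so that it refers to the same genetic
base as $\mathbf{A}_{22}$:

| option | identity enforced |
|--------|-------------------|
| TG0 | none (no adjustment) |
| TG1 | mean(diag) = 1, mean(offdiag) = 0 |
| TG2 | both means matched to $\mathbf{A}_{22}$ (the software default) |
| TG3 | overall mean matched to $\mathbf{A}_{22}$ (additive shift) |
| TG4 | Fst-style rescale |

TG1/TG2 solve a 2×2 linear system for an affine map $a + b\mathbf{G}$ and
are undefined when mean(diag) = mean(offdiag) (a monomorphic-looking **G**);
this raises an error rather than dividing by ~0. TG3 is implemented as an
additive shift $\mathbf{G} + a\mathbf{J}$, which satisfies the equal-means
identity without sign problems when mean(**G**) is near zero. For TG4 the
source description is by citation only; we implement $s =
\overline{\mathbf{A}_{22}} - \overline{\mathbf{G}}$, $\mathbf{G}^* = (1 -
s/2)\,\mathbf{G} + s\mathbf{J}$, reading $s$ as the drift correction between
the genomic and pedigree bases.

**Scaling** multiplies $\mathbf{G}_b^{-1}$ by $\tau$ and
$\mathbf{A}_{22}^{-1}$ by $\omega$ inside $\mathbf{H}^{-1}$, the classical
remedy for inflated or deflated genomic breeding values. `runSweep()` varies
one lever at a time over the standard grids ($\beta \in \{0.05, 0.10, 0.20,
0.30, 0.40\}$, TG0–TG4, $\tau$ or $\omega \in \{0.60, \dots, 1.0\}$) while
holding the others at the defaults ($\beta = 0.05$, TG2, $\tau=\omega=1$),
and labels models `ssGBLUP_G0.95` … `ssGBLUP_G0.60` (the `G` value is
$1-\beta$), `ssGBLUP_TG0` … `ssGBLUP_TG4`, and `ssGBLUP_tau0.60` /
`ssGBLUP_omega0.60` (ASCII for τ/ω).

## Forward validation and realized accuracy

`selectValidationCows()` masks the *n* most recently born genotyped cows
that have at least one lactation record (ties broken lexicographically for
determinism); every record of a masked cow is removed, and the default *n*
is about 0.32 of the eligible genotyped cows. Realized accuracy is the
Pearson correlation, over the validation cows only, between the full-data
**pedigree-BLUP** solutions and the reduced-data solutions of the model
under test:

$$\mathrm{RA} = \mathrm{cor}\!\left(\widehat{EBV}^{\,full}_{ABLUP},\;
\widehat{EBV}^{\,reduced}_{model}\right).$$

The full-data side is deliberately always the ABLUP fit — that is the
published definition — and `runSweep(fullReference = "same")` offers
same-model references as a sensitivity analysis. In simulation,
`trueAccuracy()` additionally correlates estimates with the simulated
breeding values.

### What the two metrics do and do not measure

These two metrics can disagree, and on this package's synthetic populations
they systematically do: the acceptance suite finds that ssGBLUP beats ABLUP
on *true* accuracy for the validation cows in every replicate, while ABLUP
tends to win on *realized* accuracy. The reason is structural. The ABLUP
full and reduced fits share the same pedigree information pathway — the
parent-average component of a validation cow's EBV, with the *same*
estimation errors on both sides — so their correlation is inflated beyond
either fit's accuracy against the truth. The genomic deviations that make
ssGBLUP genuinely more accurate appear, from the viewpoint of a
pedigree-only reference, partly as noise. The published near-zero ABLUP
baselines that make the realized-accuracy comparison flatter for ssGBLUP
arise in populations whose validation cows carry almost no usable parent
information (heavily selected, elite-sired, weakly connected recent
animals); our generator mates at random — selection is deliberately out of
scope — so its validation cows always retain real parent-average
information. Users comparing models on synthetic data should therefore read
`trueAccuracy()` as the primary yardstick and realized accuracy as the
field-data surrogate it is.

## The synthetic population

`simulatePopulation()` builds a multi-generation random-mating population:

* defaults of 300 founders plus 5 × 640 offspring, 85% female (dairy
  recording keeps few males), 25 service sires per generation giving
  paternal half-sib families;
* 1,000 unlinked SNPs with founder frequencies Uniform(0.05, 0.95),
  gene-dropped as explicit haplotypes; 200 of them are QTL;
* true breeding values = marker part (scaled so it explains 70% of
  $\sigma^2_a$ among founders, leaving a genuine optimum for the blending
  sweep to find) + residual polygenic part transmitted as parent average
  plus Mendelian sampling;
* variance components $\sigma^2_a = 0.28$, $\sigma^2_{pe} = 0.17$,
  $\sigma^2_e = 0.55$ on the standardised scale: heritability 0.28 (the
  upper end of the published milk-yield estimates) and repeatability 0.45
  (an assumption — repeatability is rarely reported — chosen as typical for
  305-day yields);
* about 10% of cows genotyped, biased towards recent generations, plus all
  service sires (national genomic programmes genotype the proven bulls);
* structural realism for a smallholder-of-genotypes population: parents of
  non-genotyped animals go unrecorded at rate 0.3, and 60% of
  final-generation matings use imported founder sires (half of those also
  imported dams), mirroring the dominance of foreign AI semen and embryo
  imports in the breed — this is what leaves the youngest cows relatively
  weakly connected to the phenotyped pedigree.

`simulatePhenotypes()` mirrors the repeatability model: herd–year–season
effect (SD 0.5), parity effects, a linear age covariate, the true breeding
value, a cow-constant permanent-environment term, and residual noise, mapped
to kg of milk (mean 7,940, SD 2,615) and clamped into the legal editing
window; fat and protein yields derive from milk through truncated-normal
percentage draws, so every simulated record passes the standard edits
unchanged (a round-trip the tests assert). Because fat and protein are
derived from the same genetic factor as milk, their heritabilities are
approximate rather than targeted — the parameter-recovery checks run on
milk. Ages at calving are drawn inside the legal windows per parity
(20–42, 30–54, 40–67 months, inclusive).

What the generator does **not** emulate: linkage and LD between loci (loci
are unlinked, so genomic prediction of unrelated animals is weaker than with
a dense real chip), selection and non-random mating, genotyping errors, and
informative missingness. Passing tests on this generator therefore show the
machinery is correct and the qualitative information flow is right, not that
field accuracies will match.

## Data editing

`editLactations()` applies, in a fixed attribution order (missing dates →
age window → milk 1,000–30,000 kg → fat/protein 2–9% → first-lactation
requirement), the standard edits; all windows are read inclusively, and a
record failing several rules is counted at the first, so report counts sum
exactly to the rows dropped. `formContemporaryGroups()` labels herd ×
calving-year × season (summer = October–March; the two halves of a summer
keep their own calendar years) and removes groups with fewer than five cows
or fewer than two distinct known sires.

## Numerical choices and problem sizes

Tuning identities hold to ~1e−12; relationship-inverse oracles are checked
at 1e−8 over random pedigrees up to 200 animals; MME solutions are checked
against a dense GLS oracle at 1e−8. The default test run uses reduced
problem sizes — populations of a few hundred animals for machinery checks,
and ten replicates of the full default population (~3,500 animals, ~3,000
recorded cows, ~300 genotyped cows, 100 masked) for the parameter-recovery
checks — sizes chosen so the whole suite runs comfortably on a laptop while
keeping the Monte-Carlo error of each asserted quantity well inside its
tolerance.

## Known limitations

Variance components are inputs, never estimated (REML is out of scope).
A22 inversion is dense, capping the genotyped set at desk scale. No
unknown-parent groups or metafounders: unknown parents are unrelated base
animals. PEV (and hence individual accuracy) requires the direct solver and
a full coefficient-matrix inverse, which is only sensible for moderate
system sizes.
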