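---
title: "Metafounder-based multibreed single-step evaluation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metafounder-based multibreed single-step evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfssgblup)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one defensible option existed.

## 1. Why metafounders

In multibreed evaluations with incomplete pedigrees, animals with unknown
parents are conventionally assigned to an unrelated, non-inbred base.
Two things go wrong.  First, base animals drawn from the same finite
ancestral pool *are* related, and base animals of different pools may be
related too when the pools share ancestry; ignoring this biases both
relationships and variance components.  Second, in single-step GBLUP the
genomic matrix **G** and the pedigree matrix **A** refer to different
genetic bases, and the usual repair work (frequency choice, tuning of
**G** toward **A**₂₂) treats the symptom rather than the cause.

A metafounder is a pseudo-individual standing for the ancestral gamete
pool of one base population.  Founders of pool *b* get the metafounder of
*b* as both parents; ordinary tabular rules then give them diagonal
1 + γ_b/2 and mutual relationship γ_b, and cross-pool base relationships
γ_bb′.  The matrix Γ = (γ_bb′) is the only new parameter, and it is
estimable from markers.  On the Γ-augmented base, the natural reference
population for **G** is the maximum-heterozygosity population (allele
frequencies 0.5), which removes the base-incompatibility by construction
instead of by tuning.

## 2. Estimating Γ from gene contents

For locus $i$, the gene contents $m_i \in \{0,1,2\}$ of genotyped animals
follow a linear model with the per-pool means $\mu_i$ as fixed effects
(design $Q$ = breed-ancestry fractions, rows summing to 1) and polygenic
terms whose covariance structures are the breed-of-origin partial
relationship matrices $A^b$ and segregation matrices $A^{(b,b')}$.  The
BLUE is $\hat\mu_i = (Q'V^{-1}Q)^{-1}Q'V^{-1}m_i$, and
$\hat\Gamma = 2\,\widehat{\mathrm{Cov}}_i(\hat\mu_i)$.

Choices made here:

* **One shared V for all loci.**  The per-locus genetic scale
  $2p_i(1-p_i)$ multiplies every covariance identically, so it cancels
  from the BLUE.  We therefore factorise
  $V = \sum_b A^b + \sum_{b<b'} A^{(b,b')} + \lambda I$ once.  The ridge
  $\lambda$ (default $10^{-3}$ of the mean diagonal) stands in for the
  residual-to-genetic variance ratio, which the model cannot identify
  per locus; sensitivity to $\lambda$ is small because $Q$ varies little
  within families (tested).
* **Covariance across loci with divisor $s-1$ and mean-centred means.**
  Centring matters only when pool mean frequencies differ from 0.5 on
  average; the generator draws ancestral frequencies symmetrically
  around 0.5, where centred and uncentred versions coincide in
  expectation.
* **PSD projection as a guard, not a step.**  The estimator itself is a
  sample covariance and hence PSD by construction; eigenvalue clipping
  (`psd_project`) exists for externally supplied or edited Γ matrices and
  is never silent.
* **Groups without genotyped ancestry are an error**, with the advice to
  merge groups: their Γ rows are simply not estimable from markers.

A naive cross-check estimator (`naive_gamma`: observed within-group
means of genotyped purebreds) agrees with the GLS on deep, completely
genotyped pedigrees and is used as an independent oracle in the tests.

## 3. Relationship algebra

`build_A` is the tabular method with the metafounder block initialised to
Γ.  `partial_matrices` implements the breed-of-origin decomposition with
off-diagonals following the parent-average recursion and diagonals

$$a^b_{ii} = \tfrac{1}{2}\big[(f^b_s)^2 + (f^b_d)^2\big] + \tfrac12 a^b_{sd},
\qquad
a^{(bb')}_{ii} = f^b_s f^{b'}_s + f^b_d f^{b'}_d + \tfrac12 a^{(bb')}_{sd},$$

with $f^b$ the parental pool fractions.  These are exactly the
coefficients for which the sum identity
$\sum_b A^b + \sum_{b<b'} A^{(b,b')} = A$ holds elementwise (the package
verifies it to $10^{-8}$ on every call, as a bug trap).  Correctness is
defined by that identity plus a gene-dropping oracle: IBD sharing
restricted to pool-$b$ founder alleles equals $A^b$ on pedigrees without
post-F1 crosses, and hand-enumerated backcross coefficients (e.g.
$A^H_{ii} = 0.625$ for an F1 × Hereford backcross) cover the rest.

Two inversion routes are provided on purpose.  `invert_relationship` is
the generic dense Cholesky route with an explicit jitter option.
`ainverse` exploits the generalised decomposition
$A = T\,\tilde D\,T'$ ($\tilde D$ block-diagonal: Γ on the metafounder
block, Mendelian-sampling variances elsewhere) to build the sparse
inverse $(I-P)'\tilde D^{-1}(I-P)$ used inside the mixed-model
equations; the two agree to machine precision (tested), and `ainverse`
also yields $\log|A(\Gamma)|$ for the restricted likelihood.

A property worth stating: the diagonal band
$[1, 1+\max(\Gamma)/2]$ for $A(\Gamma)$ holds for pedigrees whose
parents are related only through the pools; with within-pedigree
inbreeding the diagonal may exceed it, which is correct behaviour, so the
test suite asserts the band only on inbreeding-free pedigrees and asserts
monotonicity of $A(\Gamma)$ over $A$ in general.

## 4. Genomic matrices and H⁻¹

`build_G` is the VanRaden form.  `mode = "observed"` uses realised
frequencies (ssGBLUP); `mode = "half"` fixes all frequencies at 0.5
(ssGBLUPm), giving diagonal $2\times$(proportion of homozygous loci) — a
closed form the tests check exactly.  `build_Hinv` places
$(0.95G + 0.05A_{22})^{-1} - A_{22}^{-1}$ on the genotyped block; the
blending weights are fixed defaults (configurable) because the method
hard-codes them, and positive-definiteness failures report the offending
eigenvalue rather than repairing silently.

Quality control (`qc_filter`) implements the panel rules: marker call
rate 0.98, MAF 0.03, a 1-df chi-square Hardy–Weinberg test at $10^{-7}$
(the test's exact form is our choice; only the threshold is given),
duplicate physical positions, and collinearity restricted to exact
duplicate columns plus adjacent pairs with $|r|>0.98$ — a documented
deviation from an exhaustive pairwise screen, which is quadratic in the
marker count and not needed on simulated panels.  Sample rules: call rate
0.90, heterozygosity beyond 3 SD, near-duplicate similarity 0.995.
Missing genotypes (≈0.9% after QC) are filled with the rounded per-marker
mean gene content — a deliberately simple rule chosen because the
generator produces low, random missingness; it is *not* a substitute for
haplotype-based imputation on real panels and is flagged as such.

## 5. The bivariate repeatability model and AI-REML

The evaluation model treats the purebred (H) and crossbred (B)
expressions of tick resistance as two traits on animals recorded in one
breed each: contemporary groups as cross-classified fixed effects,
Zebu-fraction, heterozygosity and recombination-loss covariates (fitted
only for the trait in which they vary), age as centred linear and
quadratic covariates, additive effects with covariance
$G_0 \otimes K$ ($K$ = A, H or H(Γ)), permanent-environment effects for
repeated records, and trait-specific residuals with zero cross-breed
residual covariance (each animal is recorded in one breed).  The
permanent-environment cross-breed covariance is likewise fixed at zero:
with one trait per animal it is not identifiable, and the package warns
when even the variances are weakly identified (single records).

`aireml` maximises the restricted likelihood with average-information
updates; the score uses exact traces obtained from the full inverse of
the coefficient matrix (problem sizes here stay below ~8000 equations,
where a single dense solve per iteration is cheaper and more transparent
than selected-inversion machinery), and every AI step that leaves the
parameter space or decreases the likelihood falls back to step-halving
and then to an EM update, which cannot decrease the likelihood — the
trace records which step each iteration took, and the tests assert
monotonicity across the EM path.  Convergence is the maximum relative
parameter change (default $10^{-8}$); standard errors come from the
inverse AI matrix, and heritability SEs by the delta method (`h2_se`).
Starting values default to a half/quarter/quarter split of the raw
phenotypic variance with genetic correlation 0.3; any starts can be
supplied.  Contemporary groups are fitted fixed throughout: the
Gibbs-sampling stage that elsewhere treats them as random is out of
scope here, and the fixed-CG two-trait model is the one whose estimates
we report.

Genetic parameters (`genetic_params`) apply the metafounder rescaling
$k_b = 1-\gamma_b/2$ to additive variances (and $1-\gamma_{bb'}/2$ to the
covariance) before forming $h^2$, repeatability and $r_a$; with no
metafounder set all factors are 1, so the same code path serves all three
models.

## 6. What the generator emulates — and what it does not

`sim_config` defaults *are* the study conditions: two founder pools
drifted from one ancestral population (Balding–Nichols with pool-specific
F, ancestral frequencies uniform on [0.1, 0.9]), crossbreds capped at 3/4
Zebu ancestry, per-animal parent masking with probabilities 0.44 (both),
0.20 (sire), 0.0024 (dam), 28% of animals genotyped with 0.9% missing
calls, 1–3 records per animal in proportions 5.5/44.3/50.2%, recording
ages uniform on [326, 729] days, and variance components giving
heritability 0.25 and repeatability 0.40 per trait with genetic
correlation 0.5.  Contemporary groups of ~25 animals within trait × year
carry fixed effects with SD 0.45.  The true Γ is computable in closed
form as 8 × the covariance (across markers) of the pool frequency
vectors, which is precisely the target of the GLS estimator — that is
why Balding–Nichols drift was chosen as the generative model.

One design decision deserves emphasis.  Drawing true breeding values
from $N(0, G_0\otimes A)$ with *unrelated* founders would contradict the
generator's own premise that the pools are related (true Γ > 0): the
marker structure would say "related base" while the trait said
"unrelated base", and metafounders could not help by construction — we
verified empirically that the three models then tie.  The default
(`bv_base = "gamma"`) therefore draws breeding values from
$N(0, G_0\otimes A(\Gamma_{\text{true}}))$ on the true pedigree with the
founder pools as metafounders, making trait and marker architecture
consistent.  The literal unrelated-base variant is kept
(`bv_base = "plain"`) and is the right choice for model-matched estimator
checks (AI-REML recovery, bias).

What the generator does **not** emulate: linkage and genotyping error
(markers are unlinked and error-free, so the recombination-loss covariate
comes from pedigree breed fractions, not simulated linkage — the
evaluation model never uses linkage), selection and non-random mating,
real SNP-panel merging, and the heavy-tailed contemporary-group
structure of field data.  Passing tests therefore demonstrate internal
consistency of the estimators under the stated architecture, not
performance on real panels.

## 7. Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, chosen as the sizes at
which every estimate is still well-conditioned: Γ recovery uses 5000
markers and ~1000 genotyped animals in a ~1300-animal pedigree (the GLS
recovers the true founder-pool Γ to well within 0.1 elementwise, max
error ~0.01 on the default configuration); AI-REML recovery uses ~1800–
2000 phenotyped animals × 3 records; forward validation uses 20
replicates of ~1200-animal populations with the masking and genotyping
rates above.  Dense tabular matrices are used up to a few thousand
animals; the mixed-model equations are sparse throughout, with the dense
genotyped-block correction carried as such.  Degenerate inputs are
handled explicitly: singular Γ blocks receive a logged jitter, non-PD
blends and coefficient matrices report their smallest eigenvalue, a
variance component statistically indistinguishable from zero is flagged
as a boundary estimate, and ties in pedigree ordering are broken by
birth year then input order so all outputs are permutation-invariant
(tested).

## 8. Known limitations

* The GLS covariance ignores per-locus heteroskedasticity
  ($2p_i(1-p_i)$ is treated as a common factor) and the ridge λ is a
  fixed ratio, not estimated.
* Mode/mean imputation is only adequate for low, random missingness.
* Reliabilities from the MME inverse, SNP-effect backsolving, and
  alternative validation statistics (e.g. slope-corrected accuracies)
  are intentionally out of scope.
* With a single record per animal the permanent-environment variance is
  unidentifiable; the package warns and the residual absorbs it.
* The bias regression is reported per breed on the validation cohort;
  with small cohorts (tens of animals) its SE is large, and single
  replicates can sit far from 1 without indicating model failure.
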