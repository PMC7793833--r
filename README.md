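# mfssgblup

Multibreed genomic evaluation with **metafounders**: estimation of
ancestral relationships from SNP gene contents, metafounder-augmented
pedigree relationship matrices, single-step GBLUP, AI-REML variance
components, and forward validation — with a synthetic multibreed
population generator so the whole pipeline is testable end to end.

## The problem

Beef-cattle evaluations routinely pool purebred and crossbred animals
(here: Hereford, Zebu and their Braford-type composites scored for tick
resistance) whose pedigrees are badly incomplete — roughly 44% of animals
have both parents unknown.  Classical BLUP treats such base animals as
unrelated, which misstates relationships and biases breeding values, and
it also leaves the pedigree and genomic relationship matrices on
incompatible bases in single-step GBLUP (ssGBLUP).

Metafounders address both issues.  Each base population *b* is
represented by a pseudo-individual whose self-relationship γ_b (and
cross-relationships γ_bb′) describe the finite ancestral gamete pool.
Founders with unknown parents are linked to their pool's metafounder, and
the usual tabular rules then produce the augmented matrix **A**(Γ), with
founder diagonals 1 + γ/2.

The Γ matrix is estimated from the markers themselves.  For each locus
*i* the gene contents **m**_i (coded 0/1/2) of genotyped animals follow

    m_i = Q μ_i + Σ_b W u_i^b + Σ_{b<b′} W u_i^(b,b′) + e_i ,

where Q holds breed-ancestry fractions and the random terms have the
breed-of-origin partial relationship matrices A^b and segregation
matrices A^(b,b′) as covariance structures (their sum is exactly **A**).
With the GLS estimates μ̂_i of the per-pool gene-content means,

    Γ̂ = 2 Σ̂,   Σ̂ = Cov across loci of μ̂ .

Single-step evaluation combines pedigree and genomic information through

    H⁻¹ = A⁻¹ + [0 0; 0 (0.95 G + 0.05 A₂₂)⁻¹ − A₂₂⁻¹] ,

with the VanRaden genomic matrix G = (M−P)(M−P)′ / (2Σ p_j(1−p_j)).  In
the metafounder variant (ssGBLUPm), A and A₂₂ are replaced by their
Γ-augmented versions and G uses allele frequencies of 0.5 — the
maximum-heterozygosity reference on which Γ is defined — which makes the
two information sources compatible without tuning.

Variance components from the metafounder model are rescaled to the
unrelated-base scale by k_b = 1 − γ_b/2 (covariances by 1 − γ_bb′/2)
before computing heritability h² = k σ²_a / σ²_p, repeatability
r = (k σ²_a + σ²_d)/σ²_p and the cross-breed genetic correlation.

## Worked example

```r
library(mfssgblup)

ped <- as_ped_table(
  data.frame(id   = c("F1", "F2", "X"),
             sire = c("0", "0", "F1"),
             dam  = c("0", "0", "F2"),
             breed_code = c("HH", "ZZ", "HZ")),
  mf_rules = c(HH = "H", ZZ = "Z"))

mfs <- metafounder_set(c("H", "Z"), matrix(c(0.61, 0.34, 0.34, 0.96), 2))
Ag  <- build_A(ped, mfs)
Ag["F1", "F1"]
#> [1] 1.305            # founder diagonal 1 + gamma_H/2 with gamma_H = 0.61
inbreeding(Ag)[["F1"]]
#> [1] 0.305            # founders are inbred relative to the ancestral pool

g <- read_gamma(system.file("extdata", "gamma_hereford_braford.csv",
                            package = "mfssgblup"))
gamma_summary(g)[c("mean", "min", "max")]
#> $mean [1] 0.549      # average ancestral relationship across the 4 groups
#> $min  [1] 0.34
#> $max  [1] 0.96
```

A positive average relationship of ~0.55 between the four founder groups
says their ancestral pools overlap substantially — exactly the situation
in which treating base animals as unrelated is wrong and metafounders pay
off.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on a synthetic
population and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the masked multibreed population with known truth |
| `02_gamma.R` | GLS estimate of Γ, moment cross-check, error vs truth |
| `03_relationships.R` | A, A(Γ), A₂₂, G (observed/0.5), H⁻¹; element summaries |
| `04_variance_components.R` | bivariate AI-REML; (1−γ/2)-rescaled parameters |
| `05_validation.R` | forward validation of BLUP / ssGBLUP / ssGBLUPm |

Run them in order with `Rscript analysis/01_simulate.R` etc.  On the
default configuration, stage 2 recovers the true founder-pool Γ to within
~0.01, and stage 3 shows the compatibility the method is built for: the
mean diagonals of A₂₂(Γ) and of the 0.5-frequency G agree to ~0.02 while
the unaugmented A₂₂ and observed-frequency G sit on a different base.

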