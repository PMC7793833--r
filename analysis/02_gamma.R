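#!/usr/bin/env Rscript
# Stage 2: estimate the metafounder relationship matrix Gamma from gene
# contents by GLS, cross-check against the naive within-group moment
# estimator, and compare with the generator's truth.

library(mfssgblup)

sim <- readRDS("results/data/sim.rds")
ped <- read_pedigree("results/data/pedigree.csv", mf_rules = sim$mf_rules)
geno <- impute_simple(read_genotypes("results/data/genotypes.txt"))

comp <- breed_composition(ped)
partials <- partial_matrices(ped, comp)
means <- gls_gene_content_means(geno, ped, comp, partials)
gamma_hat <- estimate_gamma(means)
write_gamma(gamma_hat, "results/gamma_hat.csv")

cat("GLS estimate of Gamma:\n")
print(round(gamma_hat$gamma, 3))
gs <- gamma_summary(gamma_hat)
cat(sprintf("unique elements: mean %.3f, range %.3f-%.3f\n",
            gs$mean, gs$min, gs$max))

true_g <- read_gamma("results/data/true_gamma.csv")
pool_rows <- intersect(gamma_hat$labels, true_g$labels)
err <- gamma_hat$gamma[pool_rows, pool_rows] - true_g$gamma[pool_rows, pool_rows]
cat(sprintf("max abs error vs true founder-pool Gamma: %.3f\n", max(abs(err))))

# moment cross-check on genotyped purebreds
pure <- comp$ids[comp$fractions[, "H"] == 1 | comp$fractions[, "Z"] == 1]
pure <- intersect(pure, geno$ids)
grp <- setNames(ifelse(comp$fractions[match(pure, comp$ids), "H"] == 1, "H", "Z"),
                pure)
if (min(table(grp)) >= 2) {
  mom <- naive_gamma(geno, grp)
  cat("naive moment estimator (genotyped purebreds):\n")
  print(round(mom$gamma, 3))
}
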