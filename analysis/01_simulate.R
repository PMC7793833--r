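#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic multibreed population.
#
# Two purebred founder pools (Hereford-like and Zebu-like) drift from one
# ancestral population, so the true ancestral relationship matrix Gamma is
# positive; crossbred descendants are capped at 3/4 Zebu ancestry.  The
# released pedigree masks parents (both ~44%, sire ~20%, dam ~0.24% of
# non-founders), 28% of animals are genotyped, and phenotyped animals have
# 1-3 repeated records.  Output: the file formats the pipeline reads, plus
# the truth record for later stages.

library(mfssgblup)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 2026

cfg <- sim_config(n_founders = c(H = 100, Z = 70), n_markers = 1500,
                  n_gen = 4, n_per_gen = 250)
pools <- simulate_founder_pools(cfg, seed = seed)
sim <- simulate_population(cfg, pools, seed = seed)

write_pedigree(sim$ped, "results/data/pedigree.csv")
write_genotypes(sim$genotypes, "results/data/genotypes.txt")
write_phenotypes(sim$phenotypes, "results/data/phenotypes.csv")
write_gamma(pools$true_gamma, "results/data/true_gamma.csv")
saveRDS(sim, "results/data/sim.rds")   # truth record for stages 2-5

cat(sprintf("pedigree: %d animals (%.1f%% of non-founders with both parents masked)\n",
            nrow(sim$ped), 100 * sim$truth$masking[["both"]]))
cat(sprintf("genotyped: %d animals x %d markers (%.2f%% missing calls)\n",
            length(sim$genotypes$ids), cfg$n_markers,
            100 * mean(is.na(sim$genotypes$M))))
cat(sprintf("phenotypes: %d records on %d animals (traits: %s)\n",
            nrow(sim$phenotypes), length(unique(sim$phenotypes$animal)),
            paste(names(table(sim$phenotypes$trait)),
                  table(sim$phenotypes$trait), collapse = ", ")))
cat("true gamma:\n")
print(round(pools$true_gamma$gamma, 3))
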