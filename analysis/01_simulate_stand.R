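#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic study stand.
#
# Two interfertile oak species share a ~5 ha mapped plot; adults descend
# from an unobserved founder cohort, saplings arise from dispersal-limited
# mating and are sampled on a 3-6 m jittered grid.  The stand map, trait
# and environment tables are written out; genotype matrices are large and
# deterministic from the seed, so they are regenerated on demand instead.

source("analysis/_settings.R")

sim <- study_stand()

write_tsv(sim$stand, results_path("stand.tsv"))
write_tsv(sim$traits, results_path("traits.tsv"))
write_tsv(sim$env, results_path("environment.tsv"))
write_tsv(sim$truth$pedigree, results_path("true_pedigree.tsv"))

g1 <- sim$stand[sim$stand$generation == "G1", ]
g2 <- sim$stand[sim$stand$generation == "G2", ]
message(sprintf("stand: %d adults (%s), %d saplings; plot %.0f x %.0f m",
                nrow(g1), paste(table(g1$species), collapse = "/"),
                nrow(g2), max(sim$stand$x), max(sim$stand$y)))
d <- sqrt((g2$x - g1$x[match(sim$truth$pedigree$mother, g1$tree_id)])^2 +
            (g2$y - g1$y[match(sim$truth$pedigree$mother, g1$tree_id)])^2)
message(sprintf("median mother-sapling distance: %.1f m (seed kernel %d m)",
                median(d, na.rm = TRUE), study_config()$seed_kernel_scale))
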