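#!/usr/bin/env Rscript
# Step 4 -- reproductive success and relative fitness.
#
# Two routes to per-adult reproductive success, per species:
# (a) realized RS from categorical parentage of the saplings on the 82-SNP
#     panel, and (b) effective fecundities from the spatially explicit
#     mating-model ECM.  Both are converted to relative fitness (mean 1 per
#     species); the variance of relative fitness is the opportunity for
#     selection I.

source("analysis/_settings.R")

sim <- study_stand()
st <- sim$stand
cfg <- study_config()
out <- list(); summ <- list()
for (sp in c("petraea", "robur")) {
  g1 <- st$tree_id[st$generation == "G1" & st$species == sp]
  ped <- sim$truth$pedigree[sim$truth$pedigree$species == sp, ]
  g2 <- ped$id
  xy1 <- st[match(g1, st$tree_id), c("x", "y")]
  xy2 <- st[match(g2, st$tree_id), c("x", "y")]

  asg <- categorical_parentage(sim$geno_small[g2, ], sim$geno_small[g1, ],
                               error_rate = 0.01)
  truthpair <- t(apply(cbind(ped$mother, ped$father), 1, sort))
  acc <- mean(asg$parent1 == truthpair[, 1] &
                asg$parent2 == truthpair[, 2], na.rm = TRUE)
  realized <- realized_rs(asg, g1)

  em <- effective_fecundities_em(
    sim$geno_small[g2, ], sim$geno_small[g1, ], xy2, xy1,
    seed_kernel_scale = cfg$seed_kernel_scale,
    pollen_kernel_scale = cfg$pollen_kernel_scale,
    error_rate = 0, max_iter = 300)

  ft <- relative_fitness(cbind(em$fec, species = sp),
                         delta = 1 / (2 * length(g2)))
  ft$RS_realized <- realized$RS_female + realized$RS_male
  out[[sp]] <- ft
  summ[[sp]] <- data.frame(
    species = sp, I = unname(attr(ft, "I")),
    parentage_accuracy = acc,
    cor_effective_realized = cor(ft$RS, ft$RS_realized,
                                 method = "spearman"),
    em_converged = em$converged)
  message(sprintf(
    "%s: I = %.2f; parentage accuracy %.2f; eff-vs-realized rho = %.2f",
    sp, attr(ft, "I"), acc, summ[[sp]]$cor_effective_realized))
}
write_tsv(do.call(rbind, out), results_path("fitness.tsv"))
write_tsv(do.call(rbind, summ), results_path("fitness_summary.tsv"))
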