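# Shared settings for the analysis workflow.  Every numbered script sources
# this file; the stand is regenerated deterministically from `study_seed`,
# so no intermediate data need to be stored.

library(oakqg)

study_seed <- 20260924L

# A two-species stand sized for a readable end-to-end walk-through:
# 50 adults per species descending from a 25-strong founder pool (so the
# adult generation carries the sibship structure genomic REML needs),
# 500 systematically sampled saplings, the 82-SNP parentage panel and a
# 2,000-SNP relatedness panel.
study_config <- function() {
  sim_config(
    n_parents_per_species = 50,
    species = c("petraea", "robur"),
    n_snps_small = 82,
    n_snps_large = 2000,
    n_offspring = 500,
    g1_founders = 25,
    fecundity_cv = 1,
    rng_seed = study_seed)
}

study_stand <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_stand(study_config())
    cache
  }
})

results_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path, " (", nrow(d), " rows)")
}
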