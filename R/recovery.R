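## Parameter-recovery experiments ------------------------------------------
##
## Repeatable simulation experiments used both by the test suite and by the
## reproducibility script: each runs the generator with known truth, pushes
## the data through the estimation path, and reports recovery statistics.

## compact generator settings for recovery runs: tiny SNP panels (genotypes
## are not used by the REML path), one species, unit phenotypic variance
recovery_config <- function(h2, n_parents, n_offspring, seed,
                            trait_name = "x") {
  ts <- data.frame(name = trait_name, mean = 0, va = h2, ve = 1 - h2,
                   r_gw = 0)
  sim_config(n_parents_per_species = n_parents, species = "petraea",
             n_snps_small = 4, n_snps_large = 4, n_offspring = n_offspring,
             trait_specs = ts, rng_seed = seed)
}

#' Heritability recovery by REML on simulated sib-structured cohorts
#'
#' For each true heritability, simulates a stand (dispersal-limited mating
#' among `n_parents` adults produces a sib-structured sapling cohort of
#' `n_offspring`), computes the pedigree relationship matrix of the cohort
#' from the true pedigree, fits the univariate animal model by REML and
#' records the estimated heritability.
#'
#' @param h2_values True heritabilities to scan.
#' @param n_seeds Replicates per heritability level.
#' @param n_parents,n_offspring Stand composition per replicate.
#' @param base_seed Seed offsetting the replicate streams.
#' @return `data.frame` with `h2_true`, `seed`, `h2_hat`.
#' @export
h2_recovery_experiment <- function(h2_values = c(0.2, 0.5, 0.8),
                                   n_seeds = 20, n_parents = 50,
                                   n_offspring = 400, base_seed = 1) {
  out <- list()
  for (h2t in h2_values) {
    for (s in seq_len(n_seeds)) {
      seed <- (base_seed + s * 7919L + round(1000 * h2t)) %% .Machine$integer.max
      sim <- simulate_stand(recovery_config(h2t, n_parents, n_offspring, seed))
      A <- pedigree_nrm(sim$truth$pedigree)
      offs <- sim$truth$pedigree$id
      d <- sim$traits[sim$traits$generation == "G2", ]
      fit <- reml_fit(d, "x", G = A[offs, offs])
      out[[length(out) + 1L]] <- data.frame(h2_true = h2t, seed = seed,
                                            h2_hat = h2(fit))
    }
  }
  do.call(rbind, out)
}

#' Bivariate genetic-covariance recovery by REML
#'
#' Simulates pairs of traits with known additive covariance on the pedigree
#' relationship structure of a simulated sapling cohort, fits the bivariate
#' animal model and records the estimated additive covariance.
#'
#' @param cov_a True additive covariance between the two traits.
#' @param h2_each Heritability of each trait (phenotypic variance 1).
#' @param n_seeds Replicates.
#' @param n_parents,n_offspring Stand composition.
#' @param base_seed Seed offset.
#' @return `data.frame` with `seed`, `cov_a_hat`, `converged`.
#' @export
cova_recovery_experiment <- function(cov_a = 0.3, h2_each = 0.5,
                                     n_seeds = 20, n_parents = 50,
                                     n_offspring = 400, base_seed = 1) {
  G0 <- matrix(c(h2_each, cov_a, cov_a, h2_each), 2)
  R0 <- diag(1 - h2_each, 2)
  out <- list()
  for (s in seq_len(n_seeds)) {
    seed <- (base_seed + s * 104729L) %% .Machine$integer.max
    sim <- simulate_stand(recovery_config(0.5, n_parents, n_offspring, seed))
    offs <- sim$truth$pedigree$id
    A <- pedigree_nrm(sim$truth$pedigree)[offs, offs]
    set.seed(seed + 1L)
    tr <- simulate_genetic_traits(A, G0, R0)
    d <- data.frame(tree_id = offs, w = tr$y[, 1], x = tr$y[, 2])
    fit <- reml_fit(d, c("w", "x"), G = A)
    out[[s]] <- data.frame(seed = seed, cov_a_hat = fit$G0[1, 2],
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Null calibration and power of the selection-gradient test
#'
#' Monte-Carlo calibration of the OLS selection-gradient t-test: under the
#' null the trait is independent of fitness (type-I error should match the
#' nominal level); under the alternative a linear gradient `beta` is
#' planted and recovery and power are recorded.
#'
#' @param n_reps Replicates.
#' @param n Trees per replicate.
#' @param beta Planted gradient (0 for the null).
#' @param sigma Residual SD of relative fitness.
#' @param alpha Nominal test level.
#' @param base_seed Seed.
#' @return List with `reject_rate`, `mean_beta`, `cover3se` (share of
#'   replicates with the estimate within 3 SE of truth), `n_reps`.
#' @export
gradient_calibration_experiment <- function(n_reps = 1000, n = 200,
                                            beta = 0, sigma = 1,
                                            alpha = 0.05, base_seed = 1) {
  set.seed(base_seed)
  rej <- logical(n_reps); bhat <- numeric(n_reps); cov3 <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    d <- data.frame(C = rnorm(n), E = rnorm(n), P = rnorm(n),
                    x = rnorm(n))
    d$w <- 1 + 0.1 * d$C - 0.1 * d$E + 0.1 * d$P +
      beta * scale(d$x)[, 1] + rnorm(n, 0, sigma)
    g <- fit_selection_gradient(d, "x")
    rej[r] <- g$p_beta < alpha
    bhat[r] <- g$beta
    cov3[r] <- abs(g$beta - beta) < 3 * g$se_beta
  }
  list(reject_rate = mean(rej), mean_beta = mean(bhat),
       cover3se = mean(cov3), n_reps = n_reps)
}

#' GRM sanity statistics on a Hardy-Weinberg panel of unrelated individuals
#'
#' @param n,m Individuals and loci.
#' @param seed Seed.
#' @return List with `mean_diag`, `mean_offdiag`.
#' @export
grm_hwe_experiment <- function(n = 200, m = 5000, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  rownames(g) <- sprintf("i%03d", seq_len(n))
  G <- vanraden_grm(g)
  list(mean_diag = mean(diag(G)),
       mean_offdiag = mean(G[lower.tri(G)]))
}

#' Genomic-versus-pedigree relatedness agreement on family data
#'
#' Simulates a stand whose sapling cohort carries dense marker genotypes,
#' computes the marker-based (VanRaden) matrix and the pedigree relationship
#' matrix over the same saplings, and correlates their off-diagonal entries.
#'
#' @param n_parents,n_offspring Stand composition.
#' @param m Markers on the dense panel.
#' @param seed Seed.
#' @return List with `correlation` and both matrices' relatedness variances.
#' @export
grm_vs_nrm_experiment <- function(n_parents = 25, n_offspring = 200,
                                  m = 5000, seed = 1) {
  cfg <- sim_config(n_parents_per_species = n_parents, species = "petraea",
                    n_snps_small = 4, n_snps_large = m,
                    n_offspring = n_offspring,
                    trait_specs = data.frame(name = "x", mean = 0, va = 0.5,
                                             ve = 0.5, r_gw = 0),
                    rng_seed = seed)
  sim <- simulate_stand(cfg)
  offs <- sim$truth$pedigree$id
  Gg <- vanraden_grm(sim$geno_large[offs, ])
  Ap <- pedigree_nrm(sim$truth$pedigree)[offs, offs]
  lt <- lower.tri(Gg)
  list(correlation = cor(Gg[lt], Ap[lt]),
       grm_offdiag_var = var(Gg[lt]), nrm_offdiag_var = var(Ap[lt]))
}

#' Inject genotyping errors
#'
#' Replaces each genotype, independently with probability `rate`, by a draw
#' from Hardy-Weinberg proportions at that locus -- the same error model the
#' parentage likelihood allows for.
#'
#' @param geno 0/1/2 dosage matrix.
#' @param allele_freqs Per-locus allele frequencies.
#' @param rate Error rate.
#' @return Corrupted genotype matrix.
#' @export
add_genotyping_errors <- function(geno, allele_freqs, rate) {
  if (rate == 0) return(geno)
  n <- nrow(geno); m <- ncol(geno)
  hit <- matrix(runif(n * m) < rate, n, m)
  repl <- matrix(rbinom(n * m, 2, rep(allele_freqs, each = n)), n, m)
  geno[hit] <- repl[hit]
  geno
}

#' Parentage-assignment accuracy on a simulated stand
#'
#' Simulates a stand, corrupts the sapling genotypes at the stated error
#' rate, runs the categorical parentage assignment on the small SNP panel
#' and scores assignments against the true pedigree (unordered pairs).
#'
#' @param n_parents,n_offspring Stand composition.
#' @param n_snps Loci on the parentage panel.
#' @param error_rate Genotyping error injected and modelled.
#' @param seed Seed.
#' @return List with `accuracy` (share of assignments matching truth),
#'   `assignment_rate`, `n_assigned`.
#' @export
parentage_experiment <- function(n_parents = 60, n_offspring = 500,
                                 n_snps = 82, error_rate = 0.01, seed = 1) {
  cfg <- sim_config(n_parents_per_species = n_parents, species = "petraea",
                    n_snps_small = n_snps, n_snps_large = 4,
                    n_offspring = n_offspring, rng_seed = seed)
  sim <- simulate_stand(cfg)
  g1 <- sim$stand$tree_id[sim$stand$generation == "G1"]
  g2 <- sim$truth$pedigree$id
  set.seed(seed + 1L)
  obs <- add_genotyping_errors(sim$geno_small[g2, ],
                               attr(sim$geno_small, "allele_freqs"),
                               error_rate)
  asg <- categorical_parentage(obs, sim$geno_small[g1, ],
                               error_rate = error_rate)
  truthpair <- t(apply(cbind(sim$truth$pedigree$mother,
                             sim$truth$pedigree$father), 1, sort))
  ok <- asg$assigned &
    asg$parent1 == truthpair[, 1] & asg$parent2 == truthpair[, 2]
  list(accuracy = sum(ok, na.rm = TRUE) / sum(asg$assigned),
       assignment_rate = mean(asg$assigned),
       n_assigned = sum(asg$assigned))
}

#' Effective-fecundity recovery by the mating-model ECM
#'
#' Simulates a stand with variable fecundities, estimates effective female
#' and male fecundities from sapling genotypes and locations with the true
#' kernel scales, and reports the Spearman correlation between estimated and
#' true mean fecundities.
#'
#' @param n_parents,n_offspring Stand composition.
#' @param fecundity_cv True fecundity coefficient of variation.
#' @param seed Seed.
#' @return List with `spearman`, `converged`, `n_iter`, `fit` (the ECM
#'   result) and `truth` fecundities.
#' @export
em_fecundity_experiment <- function(n_parents = 60, n_offspring = 1000,
                                    fecundity_cv = 1, seed = 1) {
  cfg <- sim_config(n_parents_per_species = n_parents, species = "petraea",
                    n_snps_small = 82, n_snps_large = 4,
                    n_offspring = n_offspring, fecundity_cv = fecundity_cv,
                    rng_seed = seed)
  sim <- simulate_stand(cfg)
  g1 <- sim$stand$tree_id[sim$stand$generation == "G1"]
  g2 <- sim$truth$pedigree$id
  st <- sim$stand
  em <- effective_fecundities_em(
    sim$geno_small[g2, ], sim$geno_small[g1, ],
    st[match(g2, st$tree_id), c("x", "y")],
    st[match(g1, st$tree_id), c("x", "y")],
    seed_kernel_scale = cfg$seed_kernel_scale,
    pollen_kernel_scale = cfg$pollen_kernel_scale,
    error_rate = 0, max_iter = 300)
  est <- (em$fec$RS_female + em$fec$RS_male) / 2
  tru <- (sim$truth$fec_female[g1] + sim$truth$fec_male[g1]) / 2
  list(spearman = cor(est, tru, method = "spearman"),
       converged = em$converged, n_iter = em$n_iter, fit = em,
       truth_fec = tru, est_fec = est)
}
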