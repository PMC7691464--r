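test_that("config validation rejects infeasible parameter combinations", {
  expect_error(sim_config(seed_kernel_scale = 0), "seed_kernel_scale")
  expect_error(sim_config(allele_freq_range = c(0, 0.9)), "allele_freq_range")
  expect_error(sim_config(trait_specs = data.frame(
    name = "x", mean = 0, va = -1, ve = 1, r_gw = 0)), "variances")
  expect_error(sim_config(trait_specs = data.frame(
    name = "x", mean = 0, va = 1, ve = 1, r_gw = 1.5)), "correlations")
  # zero kernels are allowed when nothing is mated
  expect_s3_class(sim_config(seed_kernel_scale = 0, n_offspring = 0),
                  "oakqg_sim_config")
})

test_that("simulation is bit-reproducible from the seed and keyed by id", {
  s1 <- quick_sim(seed = 7, n_off = 50)
  s2 <- quick_sim(seed = 7, n_off = 50)
  expect_identical(s1$geno_small, s2$geno_small)
  expect_identical(s1$stand, s2$stand)
  expect_identical(s1$truth$pedigree, s2$truth$pedigree)
  expect_false(identical(quick_sim(seed = 8, n_off = 50)$stand$x, s1$stand$x))
  expect_false(anyDuplicated(s1$stand$tree_id) > 0)
  expect_true(all(s1$stand$x >= 0 & s1$stand$x <= 228))
  expect_true(all(s1$stand$dbh > 0))
})

test_that("offspring genotypes are Mendelian-consistent with the pedigree", {
  sim <- quick_sim(seed = 3, n_par = 15, n_off = 80, snps = 60)
  g <- sim$geno_small
  ped <- sim$truth$pedigree
  conflicts <- 0L
  for (i in seq_len(nrow(ped))) {
    go <- g[ped$id[i], ]; gm <- g[ped$mother[i], ]; gf <- g[ped$father[i], ]
    conflicts <- conflicts +
      sum((go == 0 & (gm == 2 | gf == 2)) | (go == 2 & (gm == 0 | gf == 0)) |
            (go == 1 & ((gm == 0 & gf == 0) | (gm == 2 & gf == 2))))
  }
  expect_identical(conflicts, 0L)
  # realized offspring counts sum to the cohort size
  expect_equal(sum(sim$truth$realized_female), nrow(ped))
  expect_equal(sum(sim$truth$realized_male), nrow(ped))
})

test_that("equal fecundities and flat kernels give uniform expected counts", {
  # enormous kernel scales make the spatial weights effectively flat
  cfg <- sim_config(n_parents_per_species = 20, species = "petraea",
                    n_snps_small = 4, n_snps_large = 4, n_offspring = 600,
                    fecundity_cv = 0, seed_kernel_scale = 1e6,
                    pollen_kernel_scale = 1e6,
                    trait_specs = data.frame(name = "x", mean = 0, va = 0.5,
                                             ve = 0.5, r_gw = 0),
                    rng_seed = 11)
  sim <- simulate_stand(cfg)
  counts <- sim$truth$realized_female
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("a trait with zero additive variance shows no parent-offspring slope", {
  sim <- quick_sim(seed = 5, n_par = 25, n_off = 250,
                   trait_specs = data.frame(name = "x", mean = 10, va = 0,
                                            ve = 1, r_gw = 0))
  ped <- sim$truth$pedigree
  tr <- setNames(sim$traits$x, sim$traits$tree_id)
  midp <- (tr[ped$mother] + tr[ped$father]) / 2
  fit <- summary(lm(tr[ped$id] ~ midp))
  expect_lt(abs(fit$coefficients["midp", 1]),
            3 * fit$coefficients["midp", 2])
})

test_that("mother-offspring distance grows with the seed kernel scale", {
  mean_dist <- function(scale, seed) {
    sim <- quick_sim(seed = seed, n_par = 20, n_off = 80, snps = 4,
                     seed_scale = scale)
    st <- sim$stand; ped <- sim$truth$pedigree
    xo <- st[match(ped$id, st$tree_id), c("x", "y")]
    xm <- st[match(ped$mother, st$tree_id), c("x", "y")]
    mean(sqrt(rowSums((xo - xm)^2)))
  }
  scales <- c(5, 25, 120)
  d <- sapply(scales, function(sc)
    mean(sapply(1:10, function(s) mean_dist(sc, s))))
  expect_true(all(diff(d) > 0))
})

test_that("fitness-correlated traits transmit a genetic fitness signal", {
  sim <- quick_sim(seed = 13, n_par = 30, n_off = 200,
                   trait_specs = data.frame(name = "x", mean = 0, va = 0.5,
                                            ve = 0.5, r_gw = 0.8))
  tru <- sim$truth
  # truth covariance between fitness and trait breeding values matches spec
  expect_equal(tru$sigma_g["w", "x"],
               0.8 * sqrt(tru$va_fitness * 0.5))
  g1 <- rownames(tru$bv)[seq_len(30)]
  expect_gt(cor(tru$bv[g1, "w"], tru$bv[g1, "x"]), 0.3)
})

test_that("resilience indices follow their ratio definitions", {
  # constant growth: no stress signal
  rw <- setNames(rep(2, 11), 2000:2010)
  r <- resilience_indices(rw, pointer_years = 2005, window = 3)
  expect_equal(unlist(r[, c("RET", "REC", "REL")]),
               c(RET = 1, REC = 1, REL = 1))
  # worked ratios with window 1
  rw2 <- setNames(c(2, 1, 2), 2001:2003)
  r2 <- resilience_indices(rw2, pointer_years = 2002, window = 1)
  expect_equal(r2$RET, 0.5)
  expect_equal(r2$REC, 2)
  expect_equal(r2$REL, 1)
  # multiplicative identity on arbitrary series
  set.seed(1)
  rw3 <- setNames(runif(21, 0.5, 3), 1990:2010)
  r3 <- resilience_indices(rw3, pointer_years = c(1995, 2000, 2005),
                           window = 4)
  expect_equal(r3$REL, r3$RET * r3$REC, tolerance = 1e-12)
  # edge pointer years are skipped with a warning
  expect_warning(
    out <- resilience_indices(rw3, pointer_years = c(1991, 2000), window = 3),
    "edge")
  expect_equal(out$pointer_year, 2000)
})
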