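test_that("relative fitness follows the pinned averaging and variance conventions", {
  rs <- data.frame(tree_id = c("a", "b"), species = "petraea",
                   RS = c(1, 3))
  ft <- relative_fitness(rs)
  expect_equal(ft$w, c(0.5, 1.5))
  expect_equal(unname(attr(ft, "I")), 0.5)        # sample (n-1) variance
  # equal success: no opportunity for selection
  ft2 <- relative_fitness(data.frame(tree_id = letters[1:4],
                                     species = "robur", RS = 2))
  expect_true(all(ft2$w == 1))
  expect_equal(unname(attr(ft2, "I")), 0)
  # female/male averaging and per-species normalization
  rs3 <- data.frame(tree_id = letters[1:4],
                    species = rep(c("petraea", "robur"), each = 2),
                    RS_female = c(2, 0, 1, 3), RS_male = c(0, 2, 3, 1))
  ft3 <- relative_fitness(rs3)
  expect_equal(ft3$RS, c(1, 1, 2, 2))
  for (s in c("petraea", "robur"))
    expect_equal(mean(ft3$w[ft3$species == s]), 1, tolerance = 1e-10)
})

test_that("relative fitness is scale-invariant and guards the log transform", {
  rs <- data.frame(tree_id = letters[1:5], species = "petraea",
                   RS = c(0.5, 1, 2, 4, 8))
  f1 <- relative_fitness(rs)
  rs2 <- rs; rs2$RS <- rs$RS * 37
  f2 <- relative_fitness(rs2)
  expect_equal(f1$w, f2$w)
  expect_equal(attr(f1, "I"), attr(f2, "I"))
  rs0 <- data.frame(tree_id = letters[1:3], species = "petraea",
                    RS = c(0, 1, 2))
  expect_error(relative_fitness(rs0), "delta")
  expect_silent(relative_fitness(rs0, delta = 1 / (2 * 3)))
})

test_that("parentage assigns the unique compatible pair under zero error", {
  # parents with contrasting homozygous profiles: only (p1, p2) can yield o1
  par <- rbind(p1 = c(2L, 2L, 0L, 0L, 2L, 0L),
               p2 = c(0L, 0L, 2L, 2L, 2L, 0L),
               p3 = c(0L, 0L, 0L, 0L, 0L, 2L))
  colnames(par) <- sprintf("s%d", 1:6)
  off <- rbind(o1 = c(1L, 1L, 1L, 1L, 2L, 0L))
  colnames(off) <- colnames(par)
  asg <- categorical_parentage(off, par, error_rate = 0,
                               allele_freqs = rep(0.5, 6), max_mismatch = 0)
  expect_true(asg$assigned)
  expect_equal(sort(c(asg$parent1, asg$parent2)), c("p1", "p2"))
  expect_equal(asg$n_mismatches, 0L)
  # an opposing-homozygote conflict zeroes a pair's likelihood
  off2 <- rbind(o2 = c(0L, 1L, 1L, 1L, 2L, 0L))  # locus 1 conflicts with p1
  colnames(off2) <- colnames(par)
  asg2 <- categorical_parentage(off2, par, error_rate = 0,
                                allele_freqs = rep(0.5, 6))
  bad <- asg2$assigned && all(sort(c(asg2$parent1, asg2$parent2)) ==
                                c("p1", "p2"))
  expect_false(bad)
})

test_that("the mating-model ECM finds the symmetric fixed point", {
  sym <- symmetric_stand()
  em <- effective_fecundities_em(
    sym$offspring_geno, sym$parent_geno, sym$offspring_coords,
    sym$parent_coords, seed_kernel_scale = 20, pollen_kernel_scale = 40,
    error_rate = 0, allele_freqs = rep(0.5, 20))
  expect_true(em$converged)
  expect_equal(em$fec$RS_female, rep(1, 8), tolerance = 1e-8)
  expect_equal(em$fec$RS_male, rep(1, 8), tolerance = 1e-8)
})

test_that("the ECM log-likelihood never decreases", {
  sim <- quick_sim(seed = 21, n_par = 15, n_off = 120, snps = 50,
                   fecundity_cv = 1.5)
  g1 <- sim$stand$tree_id[sim$stand$generation == "G1"]
  g2 <- sim$truth$pedigree$id
  st <- sim$stand
  em <- effective_fecundities_em(
    sim$geno_small[g2, ], sim$geno_small[g1, ],
    st[match(g2, st$tree_id), c("x", "y")],
    st[match(g1, st$tree_id), c("x", "y")],
    seed_kernel_scale = 20, pollen_kernel_scale = 60, error_rate = 0,
    max_iter = 150)
  expect_gt(length(em$loglik_trace), 3)
  expect_true(all(diff(em$loglik_trace) > -1e-8))
})

test_that("the ECM is equivariant under parent relabelling", {
  sim <- quick_sim(seed = 22, n_par = 12, n_off = 80, snps = 40)
  g1 <- sim$stand$tree_id[sim$stand$generation == "G1"]
  g2 <- sim$truth$pedigree$id
  st <- sim$stand
  run <- function(idx) {
    suppressWarnings(effective_fecundities_em(
      sim$geno_small[g2, ], sim$geno_small[g1[idx], ],
      st[match(g2, st$tree_id), c("x", "y")],
      st[match(g1[idx], st$tree_id), c("x", "y")],
      seed_kernel_scale = 20, pollen_kernel_scale = 60, error_rate = 0,
      max_iter = 80))$fec
  }
  f0 <- run(seq_along(g1))
  p <- c(5, 1, 7, 2, 12, 3, 11, 4, 9, 6, 10, 8)
  fp <- run(p)
  expect_equal(fp$RS_female, f0$RS_female[p], tolerance = 1e-10)
  expect_equal(fp$RS_male, f0$RS_male[p], tolerance = 1e-10)
})

test_that("effective and realized reproductive success are positively correlated", {
  sim <- quick_sim(seed = 23, n_par = 20, n_off = 250, snps = 60,
                   fecundity_cv = 1.5)
  g1 <- sim$stand$tree_id[sim$stand$generation == "G1"]
  g2 <- sim$truth$pedigree$id
  st <- sim$stand
  em <- effective_fecundities_em(
    sim$geno_small[g2, ], sim$geno_small[g1, ],
    st[match(g2, st$tree_id), c("x", "y")],
    st[match(g1, st$tree_id), c("x", "y")],
    seed_kernel_scale = 20, pollen_kernel_scale = 60, error_rate = 0,
    max_iter = 150)
  realized <- sim$truth$realized_female + sim$truth$realized_male
  effective <- em$fec$RS_female + em$fec$RS_male
  expect_gt(cor(effective, realized, method = "spearman"), 0.3)
})
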