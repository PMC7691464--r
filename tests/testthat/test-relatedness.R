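test_that("VanRaden GRM matches hand evaluation on one-locus cases", {
  # two heterozygotes at p = 0.5: recoded 0, 0 -> all entries 0
  g <- rbind(a = 1L, b = 1L)
  G <- vanraden_grm(g, allele_freqs = 0.5)
  expect_equal(unname(G), matrix(0, 2, 2), ignore_attr = TRUE)
  # homozygous alternate at p = 0.5: Z = 2 - 1 = 1, denom = 0.5 -> diag 2
  g2 <- rbind(a = 2L, b = 0L)
  G2 <- vanraden_grm(g2, allele_freqs = 0.5)
  expect_equal(unname(diag(G2)), c(2, 2))
  expect_equal(G2["a", "b"], -2)
})

test_that("GRM drops monomorphic loci and fails when none remain", {
  g <- cbind(l1 = c(2L, 2L, 2L), l2 = c(0L, 1L, 2L))
  rownames(g) <- letters[1:3]
  expect_message(G <- vanraden_grm(g), "monomorphic")
  expect_equal(attr(G, "n_loci_used"), 1L)
  expect_error(vanraden_grm(cbind(c(2L, 2L))), "monomorphic")
})

test_that("GRM is equivariant under permutation and flags missingness", {
  set.seed(2)
  g <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50,
              dimnames = list(sprintf("i%02d", 1:20), NULL))
  G <- vanraden_grm(g)
  p <- sample(20)
  Gp <- vanraden_grm(g[p, ])
  expect_equal(Gp, G[p, p], ignore_attr = TRUE)
  gm <- g; gm[1, 1:30] <- NA            # 60% missing for individual 1
  Gm <- vanraden_grm(gm)
  expect_identical(attr(Gm, "flagged_individuals"), "i01")
})

test_that("pedigree NRM reproduces textbook relationships", {
  ped <- data.frame(
    id     = c("o1", "o2", "o3"),
    mother = c("m",  "m",  "m2"),
    father = c("f",  "f",  "f"))
  A <- pedigree_nrm(ped)
  expect_equal(A["m", "o1"], 0.5)          # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)         # full sibs
  expect_equal(A["o1", "o3"], 0.25)        # paternal half sibs
  expect_equal(unname(diag(A)), rep(1, nrow(A)))  # founders non-inbred
  expect_equal(A["m", "f"], 0)
})

test_that("pedigree NRM equals the kinship-recursion oracle on a 3-generation pedigree", {
  ped <- data.frame(
    id     = c("c1", "c2", "d1", "d2"),
    mother = c("a1", "a1", "c1", "c1"),
    father = c("b1", "b1", "c2", "b2"))  # d1 inbred (full-sib mating)
  A <- pedigree_nrm(ped)
  O <- kinship_oracle(ped)
  expect_equal(A[rownames(O), colnames(O)], O, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(A["d1", "d1"], 1.25)        # offspring of full sibs
})

test_that("pedigree errors name the offending record", {
  expect_error(pedigree_nrm(data.frame(id = c("a", "b"),
                                       mother = c("b", "a"),
                                       father = c(NA, NA))), "cycle")
})

test_that("hybrid relatedness propagates genomic founder blocks", {
  Gg <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("p1", "p2"),
                                                 c("p1", "p2")))
  ped <- data.frame(id = "o1", mother = "p1", father = "p2")
  H <- hybrid_relatedness(Gg, ped)
  expect_equal(H["p1", "o1"], 0.5)
  expect_equal(H["o1", "o1"], 1)
  # genomically related pair a = 0.5 -> offspring self-relatedness 1.25
  Gg2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = dimnames(Gg))
  H2 <- hybrid_relatedness(Gg2, ped)
  expect_equal(H2["o1", "o1"], 1.25)
  expect_equal(H2["p1", "o1"], 0.75)
  expect_error(hybrid_relatedness(Gg, data.frame(
    id = "o2", mother = "p1", father = "zz")), "absent")
})

test_that("hybrid relatedness equals the pedigree NRM when founders carry pedigree values", {
  # two G1 full sibs expressed genomically, then mated: equivalent to the
  # explicit 3-generation pedigree
  Gfs <- matrix(c(1, 0.5, 0.5, 1), 2,
                dimnames = list(c("s1", "s2"), c("s1", "s2")))
  H <- hybrid_relatedness(Gfs, data.frame(id = "o", mother = "s1",
                                          father = "s2"))
  ped_full <- data.frame(
    id     = c("s1", "s2", "o"),
    mother = c("gm", "gm", "s1"),
    father = c("gf", "gf", "s2"))
  A <- pedigree_nrm(ped_full)
  expect_equal(H[c("s1", "s2", "o"), c("s1", "s2", "o")],
               A[c("s1", "s2", "o"), c("s1", "s2", "o")],
               ignore_attr = TRUE)
})

test_that("conditioning bends only when needed and leaves off-diagonals", {
  G <- diag(2)
  expect_false(attr(condition_matrix(G), "bending_applied"))
  S <- matrix(1, 2, 2)
  Sc <- condition_matrix(S, eps = 1e-6)
  expect_true(attr(Sc, "bending_applied"))
  expect_gte(min(eigen(Sc, symmetric = TRUE)$values), 1e-6 - 1e-12)
  expect_equal(Sc[1, 2], 1)               # off-diagonal untouched
})

test_that("stronger family structure raises the reported relatedness variance", {
  # high fecundity variance concentrates parentage -> more sibs -> larger
  # variance of off-diagonal relatedness
  v_off <- function(cv, seed) {
    sim <- quick_sim(seed = seed, n_par = 20, n_off = 100, snps = 300,
                     fecundity_cv = cv)
    offs <- sim$truth$pedigree$id
    attr(vanraden_grm(sim$geno_small[offs, ]), "relatedness_variance")
  }
  expect_gt(mean(sapply(1:3, function(s) v_off(2, s))),
            mean(sapply(1:3, function(s) v_off(0, s))))
})
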