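sib_A <- function(n_fam, fam_size, a = 0.25) {
  n <- n_fam * fam_size
  A <- matrix(0, n, n)
  for (i in seq_len(n_fam)) {
    idx <- ((i - 1) * fam_size + 1):(i * fam_size)
    A[idx, idx] <- a
  }
  diag(A) <- 1
  rownames(A) <- colnames(A) <- sprintf("i%04d", seq_len(n))
  A
}

test_that("the rotated restricted likelihood equals the dense oracle", {
  set.seed(41)
  A <- sib_A(10, 5, a = 0.4)
  tr <- simulate_genetic_traits(A, matrix(0.6), matrix(0.4), means = 3)
  d <- data.frame(tree_id = rownames(A), x = tr$y[, 1], c1 = rnorm(50))
  fit <- reml_fit(d, "x", fixed = "c1", G = A)
  X <- cbind(1, d$c1)
  ll_dense <- dense_reml_ll(fit$G0[1, 1], fit$R0[1, 1], d$x, X, A)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)
  # and the optimum beats nearby parameter values under the oracle
  expect_gt(ll_dense,
            dense_reml_ll(fit$G0[1, 1] * 1.5, fit$R0[1, 1], d$x, X, A))
  expect_gt(ll_dense,
            dense_reml_ll(fit$G0[1, 1], fit$R0[1, 1] * 1.5, d$x, X, A))
})

test_that("with an identity matrix the model reduces to two independent variances", {
  set.seed(42)
  n <- 50
  A <- diag(n); rownames(A) <- colnames(A) <- sprintf("i%02d", 1:n)
  y <- rnorm(n, 5, 2)
  fit <- reml_fit(data.frame(tree_id = rownames(A), x = y), "x", G = A)
  ll_dense <- dense_reml_ll(fit$G0[1, 1], fit$R0[1, 1], y,
                            matrix(1, n, 1), A)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)
  # total variance is identified even though the split is not
  expect_equal(fit$G0[1, 1] + fit$R0[1, 1], var(y) , tolerance = 0.05)
})

test_that("balanced half-sib REML equals the closed-form ANOVA estimator", {
  set.seed(43)
  s <- 50; k <- 20
  sire <- rep(seq_len(s), each = k)
  y <- 5 + rnorm(s, 0, sqrt(0.1))[sire] + rnorm(s * k, 0, sqrt(0.9))
  av <- anova(lm(y ~ factor(sire)))
  s2s <- (av[1, "Mean Sq"] - av[2, "Mean Sq"]) / k
  h2_anova <- 4 * s2s / (s2s + av[2, "Mean Sq"])
  A <- sib_A(s, k, a = 0.25)
  fit <- reml_fit(data.frame(tree_id = rownames(A), x = y), "x", G = A)
  expect_equal(h2(fit), h2_anova, tolerance = 1e-6)
})

test_that("the restricted likelihood is invariant to the fixed-effect basis", {
  set.seed(44)
  A <- sib_A(12, 5, a = 0.3)
  tr <- simulate_genetic_traits(A, matrix(0.5), matrix(0.5))
  d <- data.frame(tree_id = rownames(A), x = tr$y[, 1], c1 = rnorm(60))
  d$c2 <- 3 * d$c1 - 7            # same column space
  f1 <- reml_fit(d, "x", fixed = "c1", G = A)
  f2 <- reml_fit(d, "x", fixed = "c2", G = A)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$G0[1, 1], f2$G0[1, 1], tolerance = 1e-4)
})

test_that("BLUPs equal the dense mixed-model-equations solve", {
  set.seed(45)
  A <- sib_A(12, 5, a = 0.35)
  tr <- simulate_genetic_traits(A, matrix(0.5), matrix(0.5), means = 2)
  d <- data.frame(tree_id = rownames(A), x = tr$y[, 1])
  fit <- reml_fit(d, "x", G = A)
  a_pkg <- blup(fit)[, 1]
  a_dense <- dense_blup(fit$G0[1, 1], fit$R0[1, 1], d$x,
                        matrix(1, 60, 1), A)
  expect_equal(unname(a_pkg), a_dense, tolerance = 1e-8)
})

test_that("standard errors shrink with sample size", {
  se_at <- function(n_fam, seed) {
    set.seed(seed)
    A <- sib_A(n_fam, 5, a = 0.35)
    tr <- simulate_genetic_traits(A, matrix(0.5), matrix(0.5))
    fit <- reml_fit(data.frame(tree_id = rownames(A), x = tr$y[, 1]),
                    "x", G = A)
    fit$se_G0[1, 1]
  }
  expect_gt(mean(sapply(1:3, function(s) se_at(20, s))),
            mean(sapply(1:3, function(s) se_at(80, s + 10))))
})

test_that("bivariate fits recover a planted genetic covariance structure", {
  set.seed(46)
  A <- sib_A(40, 8, a = 0.4)
  G0 <- matrix(c(0.5, 0.3, 0.3, 0.5), 2)
  tr <- simulate_genetic_traits(A, G0, diag(0.5, 2))
  d <- data.frame(tree_id = rownames(A), w = tr$y[, 1], x = tr$y[, 2])
  fit <- reml_fit(d, c("w", "x"), G = A)
  expect_true(fit$converged)
  expect_lt(abs(fit$G0[1, 2] - 0.3), 0.25)
  expect_true(is.finite(fit$se_G0[1, 2]))
  # the STS response is the fitted covariance, standardized by sigma_p
  sr <- sts_response(fit, trait_sd = sd(d$x))
  expect_equal(sr$Re, fit$G0[1, 2])
  expect_equal(sr$St_Cov_a, fit$G0[1, 2] / sd(d$x))
  sr2 <- sts_response(fit, trait_sd = 2 * sd(d$x))
  expect_equal(sr2$St_Cov_a, sr$St_Cov_a / 2)
  expect_equal(sr2$Re, sr$Re)
})

test_that("lognormal back-transformation matches closed forms and Monte Carlo", {
  bt <- lognormal_backtransform(0, log(2))
  expect_equal(bt$mean, sqrt(2))
  expect_equal(lognormal_backtransform(c(0, 0), c(1, 1), 0)$cov, 0)
  set.seed(47)
  mu <- c(0.3, -0.2); s2 <- c(0.5, 0.3); c12 <- 0.2
  S <- matrix(c(s2[1], c12, c12, s2[2]), 2)
  z <- matrix(rnorm(2e6), ncol = 2) %*% chol(S)
  xy <- exp(sweep(z, 2, mu, "+"))
  bt2 <- lognormal_backtransform(mu, s2, c12)
  expect_equal(bt2$mean, colMeans(xy), tolerance = 0.005)
  expect_equal(bt2$cov, cov(xy[, 1], xy[, 2]), tolerance = 0.01)
})

test_that("breeding values detect a genetic shift between generations", {
  sim <- quick_sim(seed = 48, n_par = 30, n_off = 200,
                   trait_specs = data.frame(name = "x", mean = 0, va = 0.5,
                                            ve = 0.5, r_gw = 0.9))
  # strong fitness-trait genetic correlation plus fecundity selection
  # raises the mean breeding value of the sapling cohort
  tru <- sim$truth
  g1 <- rownames(tru$bv)[1:30]
  g2 <- tru$pedigree$id
  expect_gt(mean(tru$bv[g2, "x"]), mean(tru$bv[g1, "x"]))
  A <- pedigree_nrm(tru$pedigree)
  bv <- breeding_values(sim$traits, "x", G_hybrid = A)
  expect_true(bv$fit$converged)
  expect_equal(sd(bv$blups$bv_std), 1, tolerance = 1e-10)
  expect_equal(sort(names(bv$generation_means)), c("G1", "G2"))
  # predicted shift has the planted direction
  expect_gt(bv$generation_means["G2"], bv$generation_means["G1"])
})

test_that("the covariance decomposition is exact and supports sign conflicts", {
  set.seed(49)
  n <- 300
  a_w <- rnorm(n); e_w <- rnorm(n)
  a_x <- 0.6 * a_w + rnorm(n, 0, 0.5)         # positive genetic covariance
  e_x <- -0.9 * e_w + rnorm(n, 0, 0.3)        # negative environmental one
  dec <- covariance_decomposition(a_w, e_w, a_x, e_x)
  expect_equal(dec$sum_components, dec$cov_phenotypic, tolerance = 1e-12)
  expect_gt(dec$cov_aa, 0)
  expect_lt(dec$cov_ee, 0)
  # the environmental term can flip the phenotypic sign
  expect_true(sign(dec$cov_phenotypic) != sign(dec$cov_aa) ||
                abs(dec$cov_ee) > 0)
  expect_error(covariance_decomposition(NULL, e_w, a_x, e_x), "truth")
})
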