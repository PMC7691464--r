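# Independent oracles used across the suite.  These deliberately use
# different algorithms from the package implementation.

# Dense restricted log-likelihood of y = Xb + a + e, a ~ N(0, va*A),
# e ~ N(0, ve*I), evaluated by brute force (full n x n solves).
dense_reml_ll <- function(va, ve, y, X, A) {
  V <- va * A + ve * diag(nrow(A))
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  b <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(M)$modulus -
                       determinant(crossprod(X))$modulus +
                       t(r) %*% Vi %*% r))
}

# Dense BLUP oracle: a_hat = va * A V^{-1} (y - X b) at given components.
dense_blup <- function(va, ve, y, X, A) {
  V <- va * A + ve * diag(nrow(A))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  as.numeric(va * A %*% Vi %*% (y - X %*% b))
}

# Kinship-recursion oracle for additive relationship (Karigl-style):
# phi(i, i) = (1 + phi(m_i, f_i)) / 2, phi(i, j) = (phi(m_i, j) +
# phi(f_i, j)) / 2 for i not an ancestor of j; a_ij = 2 phi(i, j).
kinship_oracle <- function(pedigree) {
  ids <- pedigree$id
  mo <- setNames(pedigree$mother, ids)
  fa <- setNames(pedigree$father, ids)
  depth <- function(i) {
    if (is.na(i) || !(i %in% ids)) return(0L)
    1L + max(depth(mo[[i]]), depth(fa[[i]]))
  }
  dep <- vapply(ids, depth, integer(1))
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (identical(i, j)) {
      m <- if (i %in% ids) mo[[i]] else NA
      f <- if (i %in% ids) fa[[i]] else NA
      return((1 + phi(m, f)) / 2)
    }
    di <- if (i %in% ids) dep[[i]] else 0L
    dj <- if (j %in% ids) dep[[j]] else 0L
    if (di < dj) { tmp <- i; i <- j; j <- tmp }
    m <- if (i %in% ids) mo[[i]] else NA
    f <- if (i %in% ids) fa[[i]] else NA
    if (is.na(m) && is.na(f)) return(0)
    (phi(m, j) + phi(f, j)) / 2
  }
  all_ids <- unique(c(ids, stats::na.omit(c(pedigree$mother, pedigree$father))))
  A <- matrix(0, length(all_ids), length(all_ids),
              dimnames = list(all_ids, all_ids))
  for (i in all_ids) for (j in all_ids) A[i, j] <- 2 * phi(i, j)
  A
}

# Perfectly symmetric mating configuration: parents on a regular polygon,
# identical genotypes, saplings at the centre -- every parent is
# exchangeable, so uniform fecundities are the fixed point.
symmetric_stand <- function(n_par = 8, n_off = 40, m = 20) {
  ang <- 2 * pi * (seq_len(n_par) - 1) / n_par
  pc <- data.frame(x = 50 + 30 * cos(ang), y = 50 + 30 * sin(ang))
  oc <- data.frame(x = rep(50, n_off), y = rep(50, n_off))
  gp <- matrix(1L, n_par, m,
               dimnames = list(sprintf("p%02d", seq_len(n_par)),
                               sprintf("s%03d", seq_len(m))))
  go <- matrix(1L, n_off, m,
               dimnames = list(sprintf("o%03d", seq_len(n_off)),
                               sprintf("s%03d", seq_len(m))))
  list(parent_geno = gp, offspring_geno = go,
       parent_coords = pc, offspring_coords = oc)
}

# small stand simulation reused by several tests
quick_sim <- function(seed = 1, n_par = 20, n_off = 120, snps = 40,
                      fecundity_cv = 1, seed_scale = 20, trait_specs = NULL) {
  cfg <- sim_config(
    n_parents_per_species = n_par, species = "petraea",
    n_snps_small = snps, n_snps_large = 4, n_offspring = n_off,
    fecundity_cv = fecundity_cv, seed_kernel_scale = seed_scale,
    trait_specs = trait_specs %||%
      data.frame(name = "x", mean = 0, va = 0.5, ve = 0.5, r_gw = 0.3),
    rng_seed = seed)
  simulate_stand(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
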