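## Per-locus log transmission tables --------------------------------------
##
## P_obs(g_o | g_m, g_f) = (1 - e) * P_mendel + e * P_HWE(g_o; p_l):
## a fraction e of offspring genotypes is read as a random population
## genotype, which absorbs genotyping error without zero likelihoods.
mendel_logtable <- function(allele_freqs, error_rate) {
  if (error_rate < 0 || error_rate > 0.1)
    stop("'error_rate' must be in [0, 0.1]")
  g <- 0:2
  trans1 <- g / 2                          # P(transmit alternate | dosage)
  base <- array(0, c(3, 3, 3))
  for (g1 in g) for (g2 in g) {
    p1 <- trans1[g1 + 1]; p2 <- trans1[g2 + 1]
    base[g1 + 1, g2 + 1, 1] <- (1 - p1) * (1 - p2)
    base[g1 + 1, g2 + 1, 3] <- p1 * p2
    base[g1 + 1, g2 + 1, 2] <- p1 * (1 - p2) + (1 - p1) * p2
  }
  m <- length(allele_freqs)
  hwe <- rbind((1 - allele_freqs)^2,
               2 * allele_freqs * (1 - allele_freqs),
               allele_freqs^2)             # 3 x m
  go_idx <- rep(1:3, each = 9)             # row index -> offspring genotype
  out <- log((1 - error_rate) * as.numeric(base) +
               error_rate * hwe[go_idx, , drop = FALSE])
  dim(out) <- c(27, m)
  out
}

## log P(offspring genotypes) under HWE: the "both parents unknown" model
hwe_logliks <- function(geno, allele_freqs) {
  lp <- log(rbind((1 - allele_freqs)^2,
                  2 * allele_freqs * (1 - allele_freqs),
                  allele_freqs^2))
  apply(geno, 1, function(g) {
    ok <- !is.na(g)
    sum(lp[cbind(g[ok] + 1, which(ok))])
  })
}

align_panels <- function(offspring_geno, parent_geno) {
  offspring_geno <- as.matrix(offspring_geno)
  parent_geno <- as.matrix(parent_geno)
  if (!is.null(colnames(offspring_geno)) && !is.null(colnames(parent_geno))) {
    shared <- intersect(colnames(offspring_geno), colnames(parent_geno))
    if (!length(shared)) stop("no shared loci between the two panels")
    offspring_geno <- offspring_geno[, shared, drop = FALSE]
    parent_geno <- parent_geno[, shared, drop = FALSE]
  } else if (ncol(offspring_geno) != ncol(parent_geno)) {
    stop("locus counts differ and no locus names to align on")
  }
  list(off = offspring_geno, par = parent_geno)
}

#' Likelihood-based categorical parentage assignment
#'
#' Evaluates, for every offspring, the Mendelian transmission likelihood of
#' every unordered candidate parent pair (selfing excluded) across the
#' shared locus set, with a genotyping-error allowance. The maximum-
#' likelihood pair is assigned when its log-likelihood ratio against the
#' "both parents unknown" (HWE background) model exceeds `min_lod` and its
#' count of strict Mendelian exclusions does not exceed `max_mismatch`.
#' Since oaks are monoecious, every adult is a candidate for both parental
#' roles and the returned pair is unordered (`parent1` < `parent2` by id).
#'
#' @param offspring_geno,parent_geno 0/1/2 dosage matrices with ids in
#'   rownames and loci in colnames.
#' @param error_rate Genotyping error rate in `[0, 0.1]`.
#' @param allele_freqs Background allele frequencies (default: observed in
#'   the parents).
#' @param min_lod Assignment threshold on the log-likelihood ratio.
#' @param max_mismatch Ceiling on strict Mendelian exclusions (default 5%
#'   of loci).
#' @return `data.frame` with `offspring_id`, `parent1`, `parent2` (NA when
#'   unassigned), `lod`, `n_mismatches` and `assigned`.
#' @export
categorical_parentage <- function(offspring_geno, parent_geno,
                                  error_rate = 0.01, allele_freqs = NULL,
                                  min_lod = 0, max_mismatch = NULL) {
  g <- align_panels(offspring_geno, parent_geno)
  m <- ncol(g$par)
  np <- nrow(g$par)
  if (np < 2) stop("need at least two candidate parents")
  if (is.null(max_mismatch)) max_mismatch <- ceiling(0.05 * m)
  p <- allele_freqs %||% (colMeans(g$par, na.rm = TRUE) / 2)
  logT <- mendel_logtable(p, error_rate)
  ll <- pair_logliks_cpp(g$par, g$off, logT)
  mm <- pair_mismatch_cpp(g$par, g$off)
  self <- (seq_len(np) - 1) * np + seq_len(np)   # columns of pairs (j, j)
  ll[, self] <- -Inf
  bg <- hwe_logliks(g$off, p)
  best <- max.col(ll, ties.method = "first")
  j <- (best - 1) %% np + 1
  k <- (best - 1) %/% np + 1
  pid <- rownames(g$par)
  pair <- t(apply(cbind(pid[j], pid[k]), 1, sort))
  lod <- ll[cbind(seq_len(nrow(ll)), best)] - bg
  nmm <- mm[cbind(seq_len(nrow(mm)), best)]
  assigned <- is.finite(lod) & lod > min_lod & nmm <= max_mismatch
  data.frame(offspring_id = rownames(g$off),
             parent1 = ifelse(assigned, pair[, 1], NA_character_),
             parent2 = ifelse(assigned, pair[, 2], NA_character_),
             lod = lod, n_mismatches = nmm, assigned = assigned,
             stringsAsFactors = FALSE)
}

#' Effective fecundities by a spatially explicit mating-model ECM
#'
#' Fits a fixed-kernel mixture model for the sampled sapling cohort: a
#' sapling at site `y` arises from mother `j` and father `k` with
#' probability proportional to `f_j K_s(d(j, y)) m_k K_p(d(j, k))`, and its
#' genotype follows Mendelian transmission from the pair (with a
#' genotyping-error allowance). Female (`f`) and male (`m`) effective
#' fecundities are estimated by an expectation/conditional-maximization
#' algorithm whose two conditional M-steps (f given m, m given f) are exact,
#' so the observed-data log-likelihood is non-decreasing at every iteration.
#' Kernels are exponential, `K(d) = exp(-d / scale)`; selfing is excluded.
#'
#' This is a deliberately simplified, fixed-kernel analogue of full Bayesian
#' spatially explicit mating models: dispersal parameters are inputs, not
#' estimated.
#'
#' @param offspring_geno,parent_geno 0/1/2 dosage matrices, ids in rownames.
#' @param offspring_coords,parent_coords Tables with `x`, `y` (rows aligned
#'   with the genotype matrices).
#' @param seed_kernel_scale,pollen_kernel_scale Kernel scales in metres.
#' @param error_rate Genotyping error allowance.
#' @param allele_freqs Background allele frequencies (default observed in
#'   parents).
#' @param max_iter,tol ECM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return List with `fec` (`data.frame`: `tree_id`, `RS_female`,
#'   `RS_male`, both normalized to mean 1), `loglik_trace`, `converged`,
#'   `n_iter`.
#' @export
effective_fecundities_em <- function(offspring_geno, parent_geno,
                                     offspring_coords, parent_coords,
                                     seed_kernel_scale, pollen_kernel_scale,
                                     error_rate = 0.01, allele_freqs = NULL,
                                     max_iter = 500, tol = 1e-6) {
  stop_if_not_scalar_pos(seed_kernel_scale, "seed_kernel_scale")
  stop_if_not_scalar_pos(pollen_kernel_scale, "pollen_kernel_scale")
  g <- align_panels(offspring_geno, parent_geno)
  np <- nrow(g$par); ns <- nrow(g$off)
  pc <- as.matrix(as.data.frame(parent_coords)[, c("x", "y")])
  oc <- as.matrix(as.data.frame(offspring_coords)[, c("x", "y")])
  stopifnot(nrow(pc) == np, nrow(oc) == ns)
  p <- allele_freqs %||% (colMeans(g$par, na.rm = TRUE) / 2)
  logT <- mendel_logtable(p, error_rate)
  logM <- pair_logliks_cpp(g$par, g$off, logT)      # ns x np^2

  dpp <- as.matrix(dist(pc))
  B <- exp(-dpp / pollen_kernel_scale)
  diag(B) <- 0                                       # no selfing
  dso <- sqrt(outer(oc[, 1], pc[, 1], "-")^2 + outer(oc[, 2], pc[, 2], "-")^2)
  logA <- -dso / seed_kernel_scale
  jj <- rep(seq_len(np), times = np)                 # mother index per column
  logB_vec <- log(B)[cbind(jj, rep(seq_len(np), each = np))]
  logK <- logM + logA[, jj, drop = FALSE] +
    matrix(logB_vec, ns, np * np, byrow = TRUE)
  shift <- apply(logK, 1, max)
  K <- exp(logK - shift)

  f <- rep(1, np); m <- rep(1, np)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    fm <- f[jj] * m[rep(seq_len(np), each = np)]
    W <- sweep(K, 2, fm, "*")
    Ls <- rowSums(W)
    C <- as.numeric(crossprod(f, B %*% m))
    ll <- sum(log(Ls) + shift) - ns * log(C)
    trace <- c(trace, ll)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    r <- colSums(W / Ls)                             # responsibilities by pair
    R <- matrix(r, np, np)                           # [mother, father]
    Rm <- rowSums(R); Rf <- colSums(R)
    sj <- as.numeric(B %*% m)
    f <- Rm / pmax(sj, 1e-300)
    tk <- as.numeric(crossprod(B, f))
    m <- Rf / pmax(tk, 1e-300)
  }
  if (!converged)
    warning("ECM did not converge in ", max_iter, " iterations")
  f <- f / mean(f); m <- m / mean(m)
  list(fec = data.frame(tree_id = rownames(g$par),
                        RS_female = f, RS_male = m,
                        stringsAsFactors = FALSE),
       loglik_trace = trace, converged = converged, n_iter = it)
}

#' Realized reproductive success from parentage assignments
#'
#' Counts, per adult, the assigned offspring in each parental role. Because
#' genotype likelihoods cannot orient a monoecious pair, each assignment
#' credits half an offspring to each parent's female count and half to each
#' parent's male count.
#'
#' @param assignments Output of [categorical_parentage()].
#' @param parent_ids All candidate parent ids (parents with no assignment
#'   get zero counts).
#' @return `data.frame` with `tree_id`, `RS_female`, `RS_male`.
#' @export
realized_rs <- function(assignments, parent_ids) {
  ok <- assignments$assigned
  cnt <- table(factor(c(assignments$parent1[ok], assignments$parent2[ok]),
                      levels = parent_ids))
  data.frame(tree_id = parent_ids,
             RS_female = as.numeric(cnt) / 2,
             RS_male = as.numeric(cnt) / 2,
             stringsAsFactors = FALSE)
}

#' Relative fitness and the opportunity for selection
#'
#' Averages female and male reproductive success with equal weights,
#' `RS = (RS_female + RS_male) / 2`, scales to relative fitness
#' `w = RS / mean(RS)` within each species (so mean `w` is 1 per species),
#' and reports the opportunity for selection `I = var(w)` (sample variance,
#' n - 1 denominator) per species. `log_w = log(w + delta)`; for strictly
#' positive effective fecundities the default `delta = 0` applies, while
#' count-based realized fitness needs a small positive `delta` (e.g.
#' `1 / (2 * n_offspring)`).
#'
#' @param rs `data.frame` with `tree_id`, `species`, and either `RS` or
#'   `RS_female` + `RS_male`.
#' @param delta Offset for the log transform.
#' @return `data.frame` with `tree_id`, `species`, `RS_female`, `RS_male`,
#'   `RS`, `w`, `log_w`; attribute `I` (named per-species vector).
#' @export
relative_fitness <- function(rs, delta = 0) {
  rs <- as.data.frame(rs)
  stopifnot(all(c("tree_id", "species") %in% names(rs)))
  if (!"RS" %in% names(rs)) {
    stopifnot(all(c("RS_female", "RS_male") %in% names(rs)))
    rs$RS <- (rs$RS_female + rs$RS_male) / 2
  } else {
    rs$RS_female <- rs$RS_female %||% rs$RS
    rs$RS_male <- rs$RS_male %||% rs$RS
  }
  if (any(rs$RS < 0)) stop("reproductive success must be >= 0")
  rs$w <- NA_real_
  I <- c()
  for (s in unique(rs$species)) {
    i <- rs$species == s
    mu <- mean(rs$RS[i])
    if (mu <= 0) stop("mean RS is zero in species '", s, "'")
    rs$w[i] <- rs$RS[i] / mu
    I[s] <- var(rs$w[i])
  }
  if (any(rs$w + delta <= 0))
    stop("w + delta must be positive for the log transform; ",
         "set 'delta' (e.g. 1 / (2 * n_offspring)) for count-based fitness")
  rs$log_w <- log(rs$w + delta)
  structure(rs[, c("tree_id", "species", "RS_female", "RS_male",
                   "RS", "w", "log_w")], I = I)
}
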