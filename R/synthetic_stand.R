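#' Configuration for a synthetic two-species oak stand
#'
#' Bundles and validates every parameter of the stand generator. Defaults
#' describe a mixed sessile/pedunculate oak stand of roughly 5 ha with
#' dispersal-limited mating, a systematically sampled sapling cohort, and
#' heritable traits genetically correlated with fecundity.
#'
#' @param n_parents_per_species Number of adult (G1) trees per species.
#' @param species Character vector of species labels (one or two of
#'   `"petraea"`, `"robur"`).
#' @param plot_width,plot_height Plot dimensions in metres.
#' @param n_snps_small,n_snps_large Sizes of the parentage and relatedness
#'   SNP panels.
#' @param allele_freq_range Interval in (0, 1) from which founding allele
#'   frequencies are drawn, independently per locus.
#' @param seed_kernel_scale,pollen_kernel_scale Scale (metres) of the
#'   exponential seed and pollen dispersal kernels `exp(-d / scale)`.
#' @param fecundity_cv Coefficient of variation of individual fecundities
#'   (lognormal with unit mean).
#' @param h2_fitness Heritability of log fecundity: the share of the
#'   log-fecundity variance attributed to the additive fitness component.
#' @param n_offspring Number of G2 saplings sampled.
#' @param sapling_spacing Length-2 band (metres) of the systematic sapling
#'   sampling grid spacing; sites are jittered uniformly within the band.
#' @param trait_specs `data.frame` with columns `name`, `mean`, `va`
#'   (additive variance), `ve` (residual variance) and `r_gw` (genetic
#'   correlation of the trait with latent fitness).
#' @param env_autocorr_range Length scale (metres) of the smooth simulated
#'   micro-environmental surface.
#' @param g1_founders Size of an (unobserved) G0 founder pool per species.
#'   When positive, G1 adults are simulated as offspring of random G0 pairs,
#'   giving the adult generation the sibship structure real stands inherit
#'   from earlier regeneration cycles (needed for genomic REML on G1);
#'   0 (default) makes G1 adults unrelated founders.
#' @param immigration Fraction of offspring with both parents outside the
#'   plot (default 0; external parents are recorded as unknown).
#' @param rng_seed Integer seed; a single seed governs every draw through a
#'   fixed stream order, so output is bit-reproducible.
#'
#' @return A list of class `oakqg_sim_config`.
#' @export
sim_config <- function(n_parents_per_species = 30,
                       species = c("petraea", "robur"),
                       plot_width = 228, plot_height = 228,
                       n_snps_small = 82, n_snps_large = 15000,
                       allele_freq_range = c(0.1, 0.9),
                       seed_kernel_scale = 20, pollen_kernel_scale = 60,
                       fecundity_cv = 1, h2_fitness = 0.6,
                       n_offspring = 400, sapling_spacing = c(3, 6),
                       trait_specs = default_trait_specs(),
                       env_autocorr_range = 50,
                       g1_founders = 0,
                       immigration = 0,
                       rng_seed = 1L) {
  species <- match.arg(species, c("petraea", "robur"), several.ok = TRUE)
  stop_if_not_scalar_pos(plot_width, "plot_width")
  stop_if_not_scalar_pos(plot_height, "plot_height")
  if (n_offspring > 0) {
    stop_if_not_scalar_pos(seed_kernel_scale, "seed_kernel_scale")
    stop_if_not_scalar_pos(pollen_kernel_scale, "pollen_kernel_scale")
  }
  if (length(allele_freq_range) != 2L || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) < 0)
    stop("'allele_freq_range' must be an increasing interval inside (0, 1)")
  if (length(sapling_spacing) != 2L || any(sapling_spacing <= 0) ||
      diff(sapling_spacing) < 0)
    stop("'sapling_spacing' must be an increasing positive band")
  if (fecundity_cv < 0) stop("'fecundity_cv' must be >= 0")
  if (h2_fitness < 0 || h2_fitness > 1) stop("'h2_fitness' must be in [0, 1]")
  if (immigration < 0 || immigration >= 1) stop("'immigration' must be in [0, 1)")
  if (g1_founders < 0 || (g1_founders > 0 && g1_founders < 2))
    stop("'g1_founders' must be 0 or >= 2")
  req <- c("name", "mean", "va", "ve", "r_gw")
  if (!all(req %in% names(trait_specs)))
    stop("'trait_specs' needs columns ", paste(req, collapse = ", "))
  if (any(trait_specs$va < 0) || any(trait_specs$ve < 0))
    stop("trait variances must be >= 0")
  if (any(abs(trait_specs$r_gw) > 1))
    stop("genetic correlations 'r_gw' must lie in [-1, 1]")
  structure(list(
    n_parents_per_species = as.integer(n_parents_per_species),
    species = species, plot_width = plot_width, plot_height = plot_height,
    n_snps_small = as.integer(n_snps_small),
    n_snps_large = as.integer(n_snps_large),
    allele_freq_range = allele_freq_range,
    seed_kernel_scale = seed_kernel_scale,
    pollen_kernel_scale = pollen_kernel_scale,
    fecundity_cv = fecundity_cv, h2_fitness = h2_fitness,
    n_offspring = as.integer(n_offspring),
    sapling_spacing = sapling_spacing, trait_specs = trait_specs,
    env_autocorr_range = env_autocorr_range,
    g1_founders = as.integer(g1_founders), immigration = immigration,
    rng_seed = as.integer(rng_seed)), class = "oakqg_sim_config")
}

#' Default trait architecture of the synthetic stand
#'
#' Stem circumference and total height with phenotypic variances on the
#' scale of a mature oak stand, heritability 0.5 each, and moderate positive
#' genetic correlations with fitness.
#'
#' @return A `data.frame` usable as `trait_specs` in [sim_config()].
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("CIRC", "HGHT"),
    mean = c(190, 2650),
    va   = c(430, 11000),
    ve   = c(430, 11000),
    r_gw = c(0.4, 0.3))
}

## Additive covariance over (latent fitness, traits): single-factor
## structure through fitness, guaranteed positive semi-definite.
sim_sigma_g <- function(config) {
  ts <- config$trait_specs
  va_w <- config$h2_fitness * log(1 + config$fecundity_cv^2)
  k <- nrow(ts) + 1L
  S <- matrix(0, k, k, dimnames = rep(list(c("w", ts$name)), 2))
  S[1, 1] <- va_w
  for (i in seq_len(nrow(ts))) {
    S[1, i + 1] <- S[i + 1, 1] <- ts$r_gw[i] * sqrt(va_w * ts$va[i])
    S[i + 1, i + 1] <- ts$va[i]
    for (j in seq_len(i - 1L))
      S[i + 1, j + 1] <- S[j + 1, i + 1] <-
        ts$r_gw[i] * ts$r_gw[j] * sqrt(ts$va[i] * ts$va[j])
  }
  S
}

## square root of a PSD matrix (eigen form, tolerant of zero variances)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

rmvn_psd <- function(n, S) {
  matrix(rnorm(n * ncol(S)), n) %*% psd_sqrt(S)
}

#' Simulate a mapped two-species oak stand with genotypes, traits and truth
#'
#' Generates the complete data a contemporary-selection analysis consumes:
#' a mapped adult (G1) generation with mild spatial clustering, two SNP
#' panels, lognormal female/male fecundities tied to a heritable latent
#' fitness, a sapling (G2) cohort produced by dispersal-limited mating and
#' sampled on a jittered systematic grid, additive-genetic trait values,
#' a smooth spatially autocorrelated micro-environment, and the full ground
#' truth (pedigree, breeding values, fecundities) for recovery tests.
#'
#' Mating is within species; the father is never the mother (no selfing).
#' Offspring genotypes are Mendelian at every locus. All randomness derives
#' from `config$rng_seed` through a fixed draw order (placement, allele
#' frequencies, parent genotypes, fecundities, breeding values, environment,
#' sapling sites, pedigree/gametes, residuals).
#'
#' @param config An [sim_config()] object.
#' @return A list with elements `stand`, `geno_small`, `geno_large`,
#'   `traits`, `env` and `truth`.
#' @export
simulate_stand <- function(config) {
  stopifnot(inherits(config, "oakqg_sim_config"))
  set.seed(config$rng_seed)
  sp <- config$species
  npar <- config$n_parents_per_species * length(sp)
  ts <- config$trait_specs
  ntr <- nrow(ts)

  ## 1. parent placement: a few cluster seeds per species, Gaussian scatter
  par_sp <- rep(sp, each = config$n_parents_per_species)
  xy <- matrix(NA_real_, npar, 2)
  for (s in sp) {
    idx <- which(par_sp == s)
    ncl <- max(2L, round(length(idx) / 12))
    cx <- runif(ncl, 0, config$plot_width)
    cy <- runif(ncl, 0, config$plot_height)
    cl <- sample.int(ncl, length(idx), replace = TRUE)
    sdxy <- min(config$plot_width, config$plot_height) / 6
    ## reflect overshoot back into the plot (clamping would stack trees on
    ## the boundary at identical coordinates)
    reflect <- function(v, hi) hi - abs(hi - (abs(v) %% (2 * hi)))
    xy[idx, 1] <- reflect(rnorm(length(idx), cx[cl], sdxy), config$plot_width)
    xy[idx, 2] <- reflect(rnorm(length(idx), cy[cl], sdxy), config$plot_height)
  }
  par_id <- sprintf("G1_%s_%03d", substr(par_sp, 1, 3), seq_len(npar))
  dbh_g1 <- rlnorm(npar, log(60), 0.25)

  ## 2. optional G0 founder pool: gives G1 the sibship structure of a stand
  ##    regenerated from a previous cohort (relatedness among adults)
  g1_ped <- NULL
  f_id <- character(0)
  if (config$g1_founders > 0) {
    f_sp <- rep(sp, each = config$g1_founders)
    f_id <- sprintf("G0_%s_%03d", substr(f_sp, 1, 3), seq_along(f_sp))
    mo_g1 <- fa_g1 <- character(npar)
    for (s in sp) {
      pool <- f_id[f_sp == s]
      for (i in which(par_sp == s)) {
        pr <- sample(pool, 2)
        mo_g1[i] <- pr[1]; fa_g1[i] <- pr[2]
      }
    }
    g1_ped <- data.frame(id = par_id, mother = mo_g1, father = fa_g1,
                         stringsAsFactors = FALSE)
  }

  ## 3. SNP panels: founding frequencies; HWE draws for founders, Mendelian
  ##    transmission down to G1 when a G0 pool is present
  draw_panel <- function(m) {
    p <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
    loci <- sprintf("snp%05d", seq_len(m))
    if (is.null(g1_ped)) {
      g <- matrix(rbinom(npar * m, 2, rep(p, each = npar)), npar, m,
                  dimnames = list(par_id, loci))
    } else {
      g0 <- matrix(rbinom(length(f_id) * m, 2, rep(p, each = length(f_id))),
                   length(f_id), m, dimnames = list(f_id, loci))
      g <- matrix(NA_integer_, npar, m, dimnames = list(par_id, loci))
      for (i in seq_len(npar))
        g[i, ] <- rbinom(m, 1, g0[mo_g1[i], ] / 2) +
          rbinom(m, 1, g0[fa_g1[i], ] / 2)
    }
    attr(g, "allele_freqs") <- p
    g
  }
  geno_small <- draw_panel(config$n_snps_small)
  geno_large <- draw_panel(config$n_snps_large)

  ## 4. latent fitness + fecundities (lognormal, unit mean), breeding values
  Sg <- sim_sigma_g(config)
  s2_logfec <- log(1 + config$fecundity_cv^2)
  va_w <- Sg[1, 1]
  ve_w <- s2_logfec - va_w
  if (is.null(g1_ped)) {
    bv_par <- rmvn_psd(npar, Sg)          # founders unrelated, non-inbred
  } else {
    bv_g0 <- rmvn_psd(length(f_id), Sg)
    rownames(bv_g0) <- f_id
    bv_par <- (bv_g0[g1_ped$mother, , drop = FALSE] +
                 bv_g0[g1_ped$father, , drop = FALSE]) / 2 +
      rmvn_psd(npar, Sg / 2)
  }
  rownames(bv_par) <- par_id
  ew_f <- rnorm(npar, 0, sqrt(ve_w))
  ew_m <- rnorm(npar, 0, sqrt(ve_w))
  fec_f <- exp(bv_par[, 1] + ew_f - s2_logfec / 2)
  fec_m <- exp(bv_par[, 1] + ew_m - s2_logfec / 2)

  ## 5. smooth environment: shared latent bump surface per variable family
  env_surface <- make_bump_surface(config)
  env_extra <- replicate(5, make_bump_surface(config))

  ## 6. sapling sites: systematic grid jittered inside the spacing band
  noff <- config$n_offspring
  off_xy <- sample_sapling_sites(config, noff)

  ## 7. mating: mother ~ female fecundity x seed kernel to the site,
  ##    father ~ male fecundity x pollen kernel from the mother
  ks <- config$seed_kernel_scale; kp <- config$pollen_kernel_scale
  off_sp <- sample(sp, noff, replace = TRUE)
  mother <- father <- character(noff)
  n_mig <- if (config$immigration > 0)
    rbinom(1, noff, config$immigration) else 0L
  migrant <- rep(FALSE, noff)
  if (n_mig > 0) migrant[sample.int(noff, n_mig)] <- TRUE
  for (o in seq_len(noff)) {
    if (migrant[o]) { mother[o] <- father[o] <- NA_character_; next }
    cand <- which(par_sp == off_sp[o])
    dm <- sqrt((xy[cand, 1] - off_xy[o, 1])^2 + (xy[cand, 2] - off_xy[o, 2])^2)
    pm <- fec_f[cand] * exp(-dm / ks)
    mo <- cand[sample.int(length(cand), 1, prob = pm)]
    dp <- sqrt((xy[cand, 1] - xy[mo, 1])^2 + (xy[cand, 2] - xy[mo, 2])^2)
    pf <- fec_m[cand] * exp(-dp / kp)
    pf[cand == mo] <- 0                   # no selfing
    fa <- cand[sample.int(length(cand), 1, prob = pf)]
    mother[o] <- par_id[mo]; father[o] <- par_id[fa]
  }
  off_id <- sprintf("G2_%s_%04d", substr(off_sp, 1, 3), seq_len(noff))

  ## 8. offspring genotypes (Mendelian) and breeding values (midparent +
  ##    Mendelian-sampling deviation with covariance Sg/2)
  inherit <- function(geno) {
    m <- ncol(geno)
    out <- matrix(NA_integer_, noff, m,
                  dimnames = list(off_id, colnames(geno)))
    known <- !is.na(mother)
    for (o in which(known)) {
      gm <- geno[mother[o], ]; gf <- geno[father[o], ]
      out[o, ] <- rbinom(m, 1, gm / 2) + rbinom(m, 1, gf / 2)
    }
    if (any(!known)) {       # immigrant parents: HWE draws at founder freqs
      p <- attr(geno, "allele_freqs")
      for (o in which(!known))
        out[o, ] <- rbinom(m, 2, p)
    }
    out
  }
  geno_small_off <- inherit(geno_small)
  geno_large_off <- inherit(geno_large)
  ms <- rmvn_psd(noff, Sg / 2)
  bv_off <- matrix(0, noff, ncol(Sg), dimnames = list(off_id, colnames(Sg)))
  for (o in seq_len(noff)) {
    mid <- if (is.na(mother[o])) rmvn_psd(1, Sg / 2)[1, ] else
      (bv_par[mother[o], ] + bv_par[father[o], ]) / 2
    bv_off[o, ] <- mid + ms[o, ]
  }

  ## 9. phenotypes for all trees
  all_id <- c(par_id, off_id)
  bv <- rbind(bv_par, bv_off)
  resid <- matrix(rnorm(length(all_id) * ntr), ncol = ntr) %*%
    diag(sqrt(ts$ve), ntr)
  colnames(resid) <- ts$name; rownames(resid) <- all_id
  traits <- data.frame(tree_id = all_id,
                       species = c(par_sp, off_sp),
                       generation = rep(c("G1", "G2"), c(npar, noff)),
                       stringsAsFactors = FALSE)
  for (i in seq_len(ntr))
    traits[[ts$name[i]]] <- ts$mean[i] + bv[, i + 1] + resid[, i]

  stand <- data.frame(
    tree_id = all_id, species = c(par_sp, off_sp),
    generation = rep(c("G1", "G2"), c(npar, noff)),
    x = c(xy[, 1], off_xy[, 1]), y = c(xy[, 2], off_xy[, 2]),
    dbh = c(dbh_g1, rlnorm(noff, log(10), 0.3)),
    stringsAsFactors = FALSE)

  env <- data.frame(
    tree_id = all_id,
    altitude = 120 + 15 * env_surface(stand$x, stand$y) +
      2 * env_extra[[1]](stand$x, stand$y),
    ph = 5.5 + 0.4 * env_surface(stand$x, stand$y) +
      0.2 * env_extra[[2]](stand$x, stand$y),
    soil_moisture = 30 - 5 * env_surface(stand$x, stand$y) +
      2 * env_extra[[3]](stand$x, stand$y),
    cn_ratio = 15 + 2 * env_surface(stand$x, stand$y) +
      env_extra[[4]](stand$x, stand$y),
    organic_matter = 8 + 1.5 * env_surface(stand$x, stand$y) +
      0.5 * env_extra[[5]](stand$x, stand$y),
    stringsAsFactors = FALSE)

  pedigree <- data.frame(id = off_id, mother = mother, father = father,
                         species = off_sp, stringsAsFactors = FALSE)
  rs_f <- table(factor(mother, levels = par_id))
  rs_m <- table(factor(father, levels = par_id))

  truth <- list(
    bv = bv, resid_traits = resid,
    e_w = setNames(ew_f, par_id),         # female-path residual of log fitness
    fec_female = fec_f, fec_male = fec_m,
    realized_female = as.numeric(rs_f), realized_male = as.numeric(rs_m),
    pedigree = pedigree, g1_pedigree = g1_ped, sigma_g = Sg,
    va_fitness = va_w, ve_fitness = ve_w,
    trait_specs = ts, config = config)

  geno_small_all <- rbind(geno_small, geno_small_off)
  attr(geno_small_all, "allele_freqs") <- attr(geno_small, "allele_freqs")
  geno_large_all <- rbind(geno_large, geno_large_off)
  attr(geno_large_all, "allele_freqs") <- attr(geno_large, "allele_freqs")

  list(stand = stand, geno_small = geno_small_all,
       geno_large = geno_large_all, traits = traits, env = env,
       truth = truth)
}

## smooth surface as a sum of ~10 Gaussian bumps, standardized to sd 1
make_bump_surface <- function(config) {
  nb <- 10L
  bx <- runif(nb, 0, config$plot_width)
  by <- runif(nb, 0, config$plot_height)
  bw <- runif(nb, 0.5, 1.5) * config$env_autocorr_range
  ba <- rnorm(nb)
  f <- function(x, y) {
    v <- numeric(length(x))
    for (b in seq_len(nb))
      v <- v + ba[b] * exp(-((x - bx[b])^2 + (y - by[b])^2) / (2 * bw[b]^2))
    v
  }
  ## calibrate scale on a reference grid so variables have stable units
  gx <- seq(0, config$plot_width, length.out = 20)
  gy <- seq(0, config$plot_height, length.out = 20)
  gr <- expand.grid(x = gx, y = gy)
  s <- sd(f(gr$x, gr$y))
  if (s < 1e-12) s <- 1
  function(x, y) f(x, y) / s
}

sample_sapling_sites <- function(config, noff) {
  if (noff == 0) return(matrix(numeric(0), 0, 2))
  spacing <- mean(config$sapling_spacing)
  gx <- seq(spacing / 2, config$plot_width, by = spacing)
  gy <- seq(spacing / 2, config$plot_height, by = spacing)
  grid <- as.matrix(expand.grid(gx, gy))
  if (nrow(grid) < noff)
    stop("plot too small for ", noff, " saplings at spacing ", spacing, " m")
  sel <- grid[sample.int(nrow(grid), noff), , drop = FALSE]
  jit <- (config$sapling_spacing[2] - config$sapling_spacing[1]) / 2
  sel[, 1] <- pmin(pmax(sel[, 1] + runif(noff, -jit, jit), 0), config$plot_width)
  sel[, 2] <- pmin(pmax(sel[, 2] + runif(noff, -jit, jit), 0), config$plot_height)
  sel
}

#' Simulate correlated genetic traits on a given relatedness structure
#'
#' Draws `t` phenotypes `y = mean + a + e` with breeding values following a
#' matrix-normal distribution `a ~ MN(0, A, G0)` and independent residuals
#' `e ~ MN(0, I, R0)`. Used by the parameter-recovery experiments.
#'
#' @param A Additive relationship matrix (ids in dimnames).
#' @param G0 Additive covariance among traits (t x t).
#' @param R0 Residual covariance among traits (t x t).
#' @param means Trait means (recycled to t).
#' @return List with `y` (n x t phenotype matrix), `a`, `e`.
#' @export
simulate_genetic_traits <- function(A, G0, R0, means = 0) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  t <- ncol(G0)
  n <- nrow(A)
  La <- psd_sqrt(as.matrix(A))
  a <- La %*% matrix(rnorm(n * t), n) %*% chol_psd(G0)
  e <- matrix(rnorm(n * t), n) %*% chol_psd(R0)
  y <- sweep(a + e, 2, rep_len(means, t), "+")
  rownames(y) <- rownames(a) <- rownames(e) <- rownames(A)
  list(y = y, a = a, e = e)
}

chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(S, symmetric = TRUE)
    out <- diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  }
  out
}

#' Lloret resilience indices around stress (pointer) years
#'
#' For each pointer year, resistance `RET` is the ratio of growth in the
#' stress year to mean growth in the preceding window, recovery `REC` the
#' ratio of mean post-window growth to stress-year growth, and resilience
#' `REL` the ratio of post-window to pre-window mean growth, so that
#' `REL = RET * REC` exactly.
#'
#' @param ring_widths Numeric series of annual ring widths.
#' @param years Calendar years of the series (defaults to names or index).
#' @param pointer_years Years of the stress episodes.
#' @param window Number of years in the pre- and post-stress windows.
#' @return A `data.frame` with one row per usable pointer year.
#' @export
resilience_indices <- function(ring_widths, years = NULL, pointer_years,
                               window = 3) {
  if (window < 1) stop("'window' must be >= 1")
  if (is.null(years))
    years <- if (!is.null(names(ring_widths)))
      as.numeric(names(ring_widths)) else seq_along(ring_widths)
  stopifnot(length(years) == length(ring_widths))
  out <- data.frame(pointer_year = numeric(0), RET = numeric(0),
                    REC = numeric(0), REL = numeric(0))
  for (py in pointer_years) {
    i <- match(py, years)
    pre <- match(py - seq_len(window), years)
    post <- match(py + seq_len(window), years)
    if (is.na(i) || anyNA(pre) || anyNA(post)) {
      warning("pointer year ", py,
              " too close to the series edge; skipped")
      next
    }
    g0 <- ring_widths[i]
    gpre <- mean(ring_widths[pre])
    gpost <- mean(ring_widths[post])
    out <- rbind(out, data.frame(pointer_year = py, RET = g0 / gpre,
                                 REC = gpost / g0, REL = gpost / gpre))
  }
  out
}
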