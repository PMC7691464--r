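## REML machinery -----------------------------------------------------------
##
## Model: y (1 or 2 traits, trait-stacked) = X b + a + e, with
## a ~ N(0, G0 kron G) and e ~ N(0, R0 kron I).  Writing G = U diag(d) U'
## and rotating every trait by U' makes the covariance block diagonal: at
## rotated coordinate i the t x t block is  B_i = G0 d_i + R0.  The
## restricted likelihood then costs O(n) per evaluation, so a direct
## Cholesky-parameterized maximization is cheap even for bivariate fits.

## restricted log-likelihood (up to an additive constant) for t = 1;
## the log|X'X| term that makes the value invariant to the fixed-effect
## basis is constant in the variance parameters and added once at the end
reml_ll_uni <- function(va, ve, d, ys, Xs) {
  vi <- va * d + ve
  if (any(vi <= 0)) return(-Inf)
  w <- 1 / vi
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  M <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(M)) return(-Inf)
  beta <- backsolve(M, forwardsolve(t(M), XtWy))
  yPy <- sum(ys^2 * w) - sum(XtWy * beta)
  -0.5 * (sum(log(vi)) + 2 * sum(log(diag(M))) + yPy)
}

## restricted log-likelihood for t = 2, fully vectorized over the n blocks
reml_ll_biv <- function(G0, R0, d, ys, Xs) {
  b11 <- G0[1, 1] * d + R0[1, 1]
  b12 <- G0[1, 2] * d + R0[1, 2]
  b22 <- G0[2, 2] * d + R0[2, 2]
  det_i <- b11 * b22 - b12^2
  if (any(det_i <= 0) || any(b11 <= 0) || any(b22 <= 0)) return(-Inf)
  i11 <- b22 / det_i; i12 <- -b12 / det_i; i22 <- b11 / det_i
  y1 <- ys[, 1]; y2 <- ys[, 2]
  A11 <- crossprod(Xs, Xs * i11)
  A12 <- crossprod(Xs, Xs * i12)
  A22 <- crossprod(Xs, Xs * i22)
  M <- rbind(cbind(A11, A12), cbind(A12, A22))
  u <- c(crossprod(Xs, i11 * y1 + i12 * y2),
         crossprod(Xs, i12 * y1 + i22 * y2))
  Mc <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(Mc)) return(-Inf)
  beta <- backsolve(Mc, forwardsolve(t(Mc), u))
  yVy <- sum(i11 * y1^2 + 2 * i12 * y1 * y2 + i22 * y2^2)
  yPy <- yVy - sum(u * beta)
  -0.5 * (sum(log(det_i)) + 2 * sum(log(diag(Mc))) + yPy)
}

theta_to_cov <- function(theta) {
  ## 2x2 covariance from (log l11, l21, log l22)
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  tcrossprod(L)
}

gls_beta <- function(G0, R0, d, ys, Xs, t) {
  if (t == 1) {
    vi <- as.numeric(G0) * d + as.numeric(R0)
    w <- 1 / vi
    solve(crossprod(Xs, Xs * w), crossprod(Xs, ys * w))
  } else {
    b11 <- G0[1, 1] * d + R0[1, 1]
    b12 <- G0[1, 2] * d + R0[1, 2]
    b22 <- G0[2, 2] * d + R0[2, 2]
    det_i <- b11 * b22 - b12^2
    i11 <- b22 / det_i; i12 <- -b12 / det_i; i22 <- b11 / det_i
    y1 <- ys[, 1]; y2 <- ys[, 2]
    M <- rbind(cbind(crossprod(Xs, Xs * i11), crossprod(Xs, Xs * i12)),
               cbind(crossprod(Xs, Xs * i12), crossprod(Xs, Xs * i22)))
    u <- c(crossprod(Xs, i11 * y1 + i12 * y2),
           crossprod(Xs, i12 * y1 + i22 * y2))
    solve(M, u)
  }
}

#' REML fit of a uni- or bivariate animal model
#'
#' Restricted maximum likelihood for a linear mixed model with an individual
#' additive genetic effect structured by a relatedness matrix: one trait, or
#' two traits jointly with a full 2 x 2 additive and residual covariance
#' block (the configuration used to estimate the genetic covariance between
#' relative fitness and a trait). The optimizer is a Cholesky-parameterized
#' direct maximization (Nelder-Mead from three deterministic starts, BFGS
#' polish) on an eigen-rotated likelihood; standard errors come from the
#' numerically evaluated observed-information matrix at the optimum.
#' Deterministic given the data.
#'
#' @param data `data.frame` with the response(s), fixed-effect columns and
#'   an id column matching `G`.
#' @param response One or two response column names (for the bivariate
#'   fitness-trait model, fitness first).
#' @param fixed Fixed-effect column names (intercept always included;
#'   factors allowed). `NULL` for intercept only.
#' @param G Relatedness matrix with ids in dimnames.
#' @param id Name of the id column (default `"tree_id"`).
#' @param tol Relative convergence tolerance of the optimizer.
#' @param maxit Iteration cap per start.
#' @param condition_eps Eigenvalue floor applied to `G` via
#'   [condition_matrix()].
#' @return An object of class `oakqg_varcomp`: `G0`, `R0` (t x t additive /
#'   residual covariance), `se_G0`, `se_R0`, `beta`, `loglik`, `converged`,
#'   `boundary`, `n`, `n_iter`, `method`.
#' @export
reml_fit <- function(data, response, fixed = NULL, G, id = "tree_id",
                     tol = 1e-8, maxit = 4000, condition_eps = 1e-8) {
  data <- as.data.frame(data)
  t <- length(response)
  stopifnot(t %in% 1:2)
  need <- c(id, response, fixed)
  stopifnot(all(need %in% names(data)))
  d0 <- data[complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  n <- nrow(d0)
  if (n < 30) stop("fewer than 30 complete cases")
  ids <- as.character(d0[[id]])
  if (!all(ids %in% rownames(G)))
    stop("ids missing from the relatedness matrix: ",
         paste(head(setdiff(ids, rownames(G)), 3), collapse = ", "))
  Gs <- condition_matrix(G[ids, ids], eps = condition_eps)
  eg <- eigen(Gs, symmetric = TRUE)
  U <- eg$vectors; dvals <- pmax(eg$values, condition_eps)
  X <- if (is.null(fixed)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else model.matrix(stats::reformulate(fixed), d0)
  y <- as.matrix(d0[, response, drop = FALSE])
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  ## phenotypic covariance of OLS residuals for starting values
  res <- y - X %*% solve(crossprod(X), crossprod(X, y))
  S <- crossprod(res) / (n - ncol(X))

  evals <- 0L
  if (t == 1) {
    obj <- function(th) {
      evals <<- evals + 1L
      -reml_ll_uni(exp(th[1]), exp(th[2]), dvals, ys[, 1], Xs)
    }
    starts <- lapply(c(0.5, 0.2, 0.8),
                     function(p) log(c(p * S[1, 1], (1 - p) * S[1, 1])))
  } else {
    obj <- function(th) {
      evals <<- evals + 1L
      -reml_ll_biv(theta_to_cov(th[1:3]), theta_to_cov(th[4:6]), dvals, ys, Xs)
    }
    starts <- lapply(c(0.5, 0.2, 0.8), function(p) {
      Lg <- chol_psd(p * S); Lr <- chol_psd((1 - p) * S)
      c(log(max(Lg[1, 1], 1e-8)), Lg[1, 2], log(max(Lg[2, 2], 1e-8)),
        log(max(Lr[1, 1], 1e-8)), Lr[1, 2], log(max(Lr[2, 2], 1e-8)))
    })
  }
  best <- NULL
  for (st in starts) {
    o <- optim(st, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = tol * 1e-2))
    o <- tryCatch(
      optim(o$par, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) o)
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- best$par
  if (t == 1) {
    G0 <- matrix(exp(th[1])); R0 <- matrix(exp(th[2]))
    vpar <- c(Va = G0[1, 1], Ve = R0[1, 1])
    llv <- function(v) reml_ll_uni(v[1], v[2], dvals, ys[, 1], Xs)
  } else {
    G0 <- theta_to_cov(th[1:3]); R0 <- theta_to_cov(th[4:6])
    vpar <- c(Va1 = G0[1, 1], Ca = G0[1, 2], Va2 = G0[2, 2],
              Ve1 = R0[1, 1], Ce = R0[1, 2], Ve2 = R0[2, 2])
    llv <- function(v) {
      reml_ll_biv(matrix(v[c(1, 2, 2, 3)], 2), matrix(v[c(4, 5, 5, 6)], 2),
                  dvals, ys, Xs)
    }
  }
  dimnames(G0) <- dimnames(R0) <- rep(list(response), 2)

  se <- rep(NA_real_, length(vpar))
  names(se) <- names(vpar)
  H <- tryCatch(pracma::hessian(llv, vpar), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  se_G0 <- matrix(NA_real_, t, t, dimnames = dimnames(G0))
  se_R0 <- se_G0
  if (t == 1) {
    se_G0[1, 1] <- se["Va"]; se_R0[1, 1] <- se["Ve"]
  } else {
    se_G0[1, 1] <- se["Va1"]; se_G0[2, 2] <- se["Va2"]
    se_G0[1, 2] <- se_G0[2, 1] <- se["Ca"]
    se_R0[1, 1] <- se["Ve1"]; se_R0[2, 2] <- se["Ve2"]
    se_R0[1, 2] <- se_R0[2, 1] <- se["Ce"]
  }
  ## basis-invariance constant: + t/2 * log|X'X| per trait block
  ldXtX <- as.numeric(determinant(crossprod(Xs))$modulus)
  loglik <- -best$value + t * 0.5 * ldXtX

  beta <- gls_beta(G0, R0, dvals, ys, Xs, t)
  bnames <- colnames(X)
  if (t == 2) bnames <- c(paste0(response[1], ":", bnames),
                          paste0(response[2], ":", bnames))
  phen_var <- diag(S)
  structure(list(
    G0 = G0, R0 = R0, se_G0 = se_G0, se_R0 = se_R0,
    beta = setNames(as.numeric(beta), bnames),
    loglik = loglik, converged = best$convergence == 0,
    boundary = any(diag(G0) < 1e-6 * phen_var),
    n = n, n_iter = evals, response = response,
    method = "eigen-rotated REML, Cholesky-parameterized Nelder-Mead + BFGS",
    .internal = list(U = U, d = dvals, ys = ys, Xs = Xs, ids = ids,
                     X = X, y = y)),
    class = "oakqg_varcomp")
}

#' @export
print.oakqg_varcomp <- function(x, ...) {
  cat("Animal-model REML fit (", paste(x$response, collapse = ", "),
      "), n = ", x$n, "\n", sep = "")
  cat("Additive covariance (G0):\n"); print(round(x$G0, 4))
  cat("Residual covariance (R0):\n"); print(round(x$R0, 4))
  cat("logLik:", format(x$loglik), " converged:", x$converged,
      if (x$boundary) " [boundary]" else "", "\n")
  invisible(x)
}

#' Narrow-sense heritability from a univariate fit
#'
#' @param fit A univariate `oakqg_varcomp` object.
#' @return `Va / (Va + Ve)`.
#' @export
h2 <- function(fit) {
  stopifnot(inherits(fit, "oakqg_varcomp"), length(fit$response) == 1)
  fit$G0[1, 1] / (fit$G0[1, 1] + fit$R0[1, 1])
}

#' Best linear unbiased predictions of breeding values
#'
#' Solves the mixed-model equations at the REML estimates in the
#' eigen-rotated space and rotates back; equals the direct dense solve
#' `a = (G0 kron G) V^{-1} (y - X beta)`.
#'
#' @param fit An `oakqg_varcomp` object.
#' @return n x t matrix of predicted breeding values (rownames = ids).
#' @export
blup <- function(fit) {
  z <- fit$.internal
  t <- length(fit$response)
  r <- z$ys - z$Xs %*% matrix(fit$beta, ncol = t)
  if (t == 1) {
    vi <- fit$G0[1, 1] * z$d + fit$R0[1, 1]
    astar <- (fit$G0[1, 1] * z$d / vi) * r[, 1]
    a <- z$U %*% astar
  } else {
    G0 <- fit$G0; R0 <- fit$R0; d <- z$d
    b11 <- G0[1, 1] * d + R0[1, 1]
    b12 <- G0[1, 2] * d + R0[1, 2]
    b22 <- G0[2, 2] * d + R0[2, 2]
    det_i <- b11 * b22 - b12^2
    i11 <- b22 / det_i; i12 <- -b12 / det_i; i22 <- b11 / det_i
    w1 <- i11 * r[, 1] + i12 * r[, 2]
    w2 <- i12 * r[, 1] + i22 * r[, 2]
    a1 <- d * (G0[1, 1] * w1 + G0[1, 2] * w2)
    a2 <- d * (G0[1, 2] * w1 + G0[2, 2] * w2)
    a <- cbind(z$U %*% a1, z$U %*% a2)
  }
  a <- as.matrix(a)
  rownames(a) <- z$ids
  colnames(a) <- fit$response
  a
}

#' Predicted selection response of a trait (secondary theorem of selection)
#'
#' The expected per-generation genetic change of a trait equals its additive
#' genetic covariance with relative fitness. Extracts that covariance from a
#' bivariate (fitness, trait) REML fit, standardizes it by the phenotypic SD
#' and flags significance by a Wald criterion (|estimate| > 1.96 SE).
#'
#' @param fit Bivariate `oakqg_varcomp` with fitness as the first response.
#' @param trait_sd Phenotypic standard deviation of the trait.
#' @return One-row `data.frame`: `Re`, `St_Cov_a`, `se_Re`, `significant`,
#'   `converged`. Non-converged fits propagate `NA` estimates.
#' @export
sts_response <- function(fit, trait_sd) {
  stopifnot(inherits(fit, "oakqg_varcomp"), length(fit$response) == 2)
  stop_if_not_scalar_pos(trait_sd, "trait_sd")
  if (!fit$converged)
    return(data.frame(trait = fit$response[2], Re = NA_real_,
                      St_Cov_a = NA_real_, se_Re = NA_real_,
                      significant = NA, converged = FALSE))
  Re <- fit$G0[1, 2]
  se <- fit$se_G0[1, 2]
  data.frame(trait = fit$response[2], Re = Re, St_Cov_a = Re / trait_sd,
             se_Re = se,
             significant = is.finite(se) && abs(Re) > 1.96 * se,
             converged = TRUE)
}

#' Exact lognormal back-transformation of log-scale (co)variance components
#'
#' For traits analysed after a natural-log transform, converts the Gaussian
#' log-scale mean and (co)variance components to the data scale using the
#' lognormal closed forms: `E[X] = exp(mu + s2/2)`,
#' `Var[X] = exp(2 mu + s2)(exp(s2) - 1)` and
#' `Cov[X, Y] = exp(mu_x + mu_y + (s2_x + s2_y)/2)(exp(s_xy) - 1)`.
#' These equal the Gaussian-link integrals evaluated by general-purpose
#' GLMM back-transformation packages, here in closed form.
#'
#' @param mu_log Log-scale mean(s) (length 1 or 2).
#' @param var_log Log-scale total variance(s), same length.
#' @param cov_log Log-scale covariance between the two variables (optional).
#' @return List with `mean`, `var` and (when `cov_log` is given) `cov`.
#' @export
lognormal_backtransform <- function(mu_log, var_log, cov_log = NULL) {
  stopifnot(length(mu_log) == length(var_log))
  m <- exp(mu_log + var_log / 2)
  v <- exp(2 * mu_log + var_log) * (exp(var_log) - 1)
  out <- list(mean = m, var = v)
  if (!is.null(cov_log)) {
    stopifnot(length(mu_log) == 2)
    out$cov <- exp(sum(mu_log) + sum(var_log) / 2) * (exp(cov_log) - 1)
  }
  out
}

#' Breeding values across two generations
#'
#' Fits a univariate animal model on the pooled G1 + G2 data with generation
#' as a fixed effect (so environmental/age differences between cohorts are
#' absorbed), predicts breeding values from the mixed-model equations,
#' standardizes them across the two generations, and compares the
#' per-generation means.
#'
#' @param data Pooled `data.frame` with the trait, a `generation` column and
#'   any further fixed effects.
#' @param response Trait column name.
#' @param G_hybrid Two-generation relatedness matrix (e.g.
#'   [hybrid_relatedness()]).
#' @param fixed Additional fixed-effect columns (generation is always
#'   included).
#' @param id Id column name.
#' @param ... Passed to [reml_fit()].
#' @return List with `fit`, `blups` (`tree_id`, `generation`, `bv`,
#'   `bv_std`), `generation_means` (of standardized breeding values) and
#'   `comparison` (Welch test).
#' @export
breeding_values <- function(data, response, G_hybrid, fixed = NULL,
                            id = "tree_id", ...) {
  data <- as.data.frame(data)
  stopifnot("generation" %in% names(data))
  fit <- reml_fit(data, response, fixed = c("generation", fixed),
                  G = G_hybrid, id = id, ...)
  a <- blup(fit)
  gen <- data$generation[match(rownames(a), data[[id]])]
  bv_std <- as.numeric(scale(a[, 1]))
  blups <- data.frame(tree_id = rownames(a), generation = gen,
                      bv = a[, 1], bv_std = bv_std,
                      stringsAsFactors = FALSE)
  gm <- tapply(blups$bv_std, blups$generation, mean)
  cmp <- t.test(bv_std ~ generation, data = blups)
  list(fit = fit, blups = blups, generation_means = gm, comparison = cmp)
}

#' Decomposition of a phenotypic fitness-trait covariance
#'
#' Splits `Cov(w, X)` computed on realized vectors into its additive and
#' environmental components,
#' `Cov(w_a, X_a) + Cov(w_e, X_a) + Cov(w_a, X_e) + Cov(w_e, X_e)`,
#' which holds exactly by bilinearity when `w = w_a + w_e` and
#' `X = X_a + X_e` are built from the same realizations. Available in
#' simulation mode, where the component vectors are known; it underpins the
#' diagnostic for phenotypic gradients and genetic covariances disagreeing
#' in sign (opposite-sign genetic and environmental covariances).
#'
#' @param a_w,e_w Additive and environmental components of relative fitness.
#' @param a_x,e_x Additive and environmental components of the trait.
#' @return `data.frame` with the four terms, their sum and the directly
#'   computed phenotypic covariance.
#' @export
covariance_decomposition <- function(a_w, e_w, a_x, e_x) {
  if (is.null(a_w) || is.null(a_x))
    stop("covariance_decomposition requires simulation truth components")
  stopifnot(length(a_w) == length(e_w), length(a_w) == length(a_x),
            length(a_w) == length(e_x))
  terms <- c(cov_aa = cov(a_w, a_x), cov_ea = cov(e_w, a_x),
             cov_ae = cov(a_w, e_x), cov_ee = cov(e_w, e_x))
  data.frame(t(terms), sum_components = sum(terms),
             cov_phenotypic = cov(a_w + e_w, a_x + e_x))
}
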