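#' Hegyi competition index
#'
#' Distance-weighted sum of neighbour-to-focal diameter ratios,
#' `C_j = sum_i D_i / (D_j * Dist_ij)` over all neighbours `i` within a
#' closed ball of `radius` metres around the focal tree `j`. Trees with no
#' neighbour receive 0.
#'
#' @param stand `data.frame` with `tree_id`, `x`, `y` and `dbh` (> 0).
#' @param radius Neighbourhood radius in metres (default 10, boundary
#'   inclusive).
#' @return Named numeric vector of competition indices.
#' @export
hegyi_index <- function(stand, radius = 10) {
  stopifnot(all(c("tree_id", "x", "y", "dbh") %in% names(stand)))
  if (any(stand$dbh <= 0)) stop("all dbh values must be > 0")
  D <- as.matrix(dist(stand[, c("x", "y")]))
  n <- nrow(stand)
  inside <- D <= radius & row(D) != col(D)
  zero <- which(inside & D == 0, arr.ind = TRUE)
  if (nrow(zero))
    stop("coincident coordinates for trees '",
         stand$tree_id[zero[1, 1]], "' and '", stand$tree_id[zero[1, 2]], "'")
  C <- numeric(n)
  for (j in seq_len(n)) {
    i <- which(inside[j, ])
    if (length(i))
      C[j] <- sum(stand$dbh[i] / (stand$dbh[j] * D[j, i]))
  }
  setNames(C, stand$tree_id)
}

#' Environmental index from ecological variables
#'
#' First principal component (correlation-matrix PCA) of per-tree ecological
#' variables such as altitude, pH, soil moisture, C/N ratio and organic
#' matter. The sign is fixed so that the score correlates positively with
#' the first retained variable; scores are centered by construction.
#'
#' @param env `data.frame` of ecological variables (a `tree_id` column, if
#'   present, supplies names and is excluded from the PCA).
#' @return Named score vector with attributes `explained` (share of variance
#'   on PC1) and `loadings`.
#' @export
environment_index <- function(env) {
  env <- as.data.frame(env)
  ids <- env$tree_id %||% rownames(env)
  vars <- env[, setdiff(names(env), "tree_id"), drop = FALSE]
  if (ncol(vars) < 2) stop("need at least 2 ecological variables")
  if (nrow(vars) < 3) stop("need at least 3 trees")
  constant <- vapply(vars, function(v) sd(v) < 1e-12, logical(1))
  if (any(constant)) {
    warning("dropping constant variable(s): ",
            paste(names(vars)[constant], collapse = ", "))
    vars <- vars[, !constant, drop = FALSE]
    if (ncol(vars) < 2) stop("fewer than 2 variable(s) left after dropping")
  }
  pc <- prcomp(vars, center = TRUE, scale. = TRUE)
  E <- pc$x[, 1]
  s <- cor(E, vars[[1]])
  if (is.finite(s) && s < 0) E <- -E
  structure(setNames(as.numeric(E), ids),
            explained = pc$sdev[1]^2 / sum(pc$sdev^2),
            loadings = pc$rotation[, 1] * sign(s))
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: pairwise distances above the
#' truncation threshold `t` are replaced by `4 t`, the matrix `-d^2 / 2` is
#' Gower double-centered and eigendecomposed, and eigenvectors with positive
#' eigenvalues are returned (unit norm, centered, mutually orthogonal),
#' sorted by descending eigenvalue. With `t` equal to the maximum pairwise
#' distance (the default) the truncation is a no-op and the vectors are the
#' classical principal coordinates of the full distance matrix.
#'
#' @param coords `data.frame` or matrix with `x` and `y` columns (a
#'   `tree_id` column supplies names).
#' @param t Truncation distance in metres; default max pairwise distance.
#' @param tol Relative eigenvalue tolerance for retaining axes.
#' @return List with `vectors` (n x k matrix) and `values` (length k).
#' @export
pcnm_eigenvectors <- function(coords, t = NULL, tol = 1e-10) {
  coords <- as.data.frame(coords)
  ids <- coords$tree_id %||% rownames(coords)
  D <- as.matrix(dist(coords[, c("x", "y")]))
  if (is.null(t)) t <- max(D)
  D[D > t] <- 4 * t
  A <- -0.5 * D^2
  n <- nrow(A)
  ctr <- diag(n) - matrix(1 / n, n, n)
  B <- ctr %*% A %*% ctr
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) stop("no positive PCNM eigenvalue")
  v <- e$vectors[, keep, drop = FALSE]
  rownames(v) <- ids
  colnames(v) <- sprintf("PCNM%d", seq_len(ncol(v)))
  list(vectors = v, values = e$values[keep])
}

## Gaussian profile-likelihood AIC of a simple linear regression,
## k = 3 (intercept, slope, residual variance)
aic_simple_lm <- function(y, v) {
  fit <- lm(y ~ v)
  n <- length(y)
  n * log(sum(fit$residuals^2) / n) + 2 * 3
}

#' Select the spatial covariate by per-eigenvector AIC
#'
#' Regresses relative fitness on each PCNM eigenvector in turn and returns
#' the single eigenvector minimizing the AIC of the simple regression,
#' together with the full AIC trace. AIC ties resolve to the lowest rank.
#'
#' @param w Relative-fitness vector, aligned with the eigenvector rows.
#' @param eigvecs Matrix of PCNM eigenvectors (columns ranked).
#' @return List with `P` (selected eigenvector), `pcnm_rank` and
#'   `aic_trace`.
#' @export
select_spatial_covariate <- function(w, eigvecs) {
  eigvecs <- as.matrix(eigvecs)
  stopifnot(length(w) == nrow(eigvecs))
  aic <- vapply(seq_len(ncol(eigvecs)),
                function(i) aic_simple_lm(w, eigvecs[, i]), numeric(1))
  best <- which.min(aic)        # which.min already takes the lowest index
  list(P = setNames(eigvecs[, best], rownames(eigvecs)),
       pcnm_rank = best, aic_trace = aic)
}

#' Moran's I with inverse-distance weights (diagnostic)
#'
#' Spatial autocorrelation of a variable using `1/d` weights capped at
#' `radius` (weights beyond the radius are zero). Thin wrapper around
#' [ape::Moran.I()], used to verify that regressing out the selected PCNM
#' covariate removes the spatial signal in fitness.
#'
#' @param x Variable of interest.
#' @param coords Matrix/data.frame of `x`, `y` coordinates.
#' @param radius Distance cap in metres.
#' @return The [ape::Moran.I()] result list.
#' @export
moran_i <- function(x, coords, radius = 10) {
  coords <- as.data.frame(coords)
  D <- as.matrix(dist(coords[, c("x", "y")]))
  W <- ifelse(D > 0 & D <= radius, 1 / D, 0)
  diag(W) <- 0
  ape::Moran.I(x, W)
}

#' Assemble the C / E / P covariate table
#'
#' Computes the Hegyi competition index, the environmental PCA index and the
#' AIC-selected PCNM spatial covariate for a set of trees, centered as used
#' in the selection models (E and P have mean zero over the fitted set).
#'
#' @param stand Stand table (`tree_id`, `x`, `y`, `dbh`).
#' @param env Ecological variable table aligned on `tree_id`.
#' @param w Named relative-fitness vector used for the PCNM selection.
#' @param radius Hegyi neighbourhood radius (metres).
#' @return `data.frame` with `tree_id`, `C`, `E`, `P`; attributes
#'   `pcnm_rank` and `aic_trace`.
#' @export
stand_covariates <- function(stand, env, w, radius = 10) {
  ids <- names(w)
  stopifnot(!is.null(ids), all(ids %in% stand$tree_id))
  sub <- stand[match(ids, stand$tree_id), ]
  C <- hegyi_index(sub, radius = radius)
  E <- environment_index(env[match(ids, env$tree_id), ])
  E <- E - mean(E)
  pc <- pcnm_eigenvectors(sub)
  sel <- select_spatial_covariate(as.numeric(w), pc$vectors)
  P <- sel$P - mean(sel$P)
  structure(data.frame(tree_id = ids, C = as.numeric(C),
                       E = as.numeric(E), P = as.numeric(P),
                       stringsAsFactors = FALSE),
            pcnm_rank = sel$pcnm_rank, aic_trace = sel$aic_trace)
}
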