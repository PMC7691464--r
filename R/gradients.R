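#' Univariate phenotypic selection gradients
#'
#' Ordinary least squares of relative fitness on an SD-standardized trait
#' with competition (C), environment (E) and spatial (P) covariates:
#' `w = mu + C + E + P + beta * x_std (+ gamma * x_std^2) + error`.
#' Because the trait enters standardized, `beta` is the selection intensity
#' (the selection differential in SD units). The quadratic coefficient is
#' reported raw and doubled (the Stinchcombe correction), since quadratic-
#' gradient conventions differ between studies.
#'
#' @param data `data.frame` holding fitness, the trait and the covariates.
#' @param trait Name of the trait column.
#' @param fitness Name of the fitness column (default `"w"`).
#' @param covariates Covariate column names (default `c("C", "E", "P")`;
#'   may be empty).
#' @param quadratic Add the squared standardized trait?
#' @param log_fitness Regress `log(w)` instead of `w` (exposed because the
#'   two conventions coexist; default untransformed).
#' @param max_kappa Condition-number ceiling for the design matrix.
#' @return A one-row `data.frame` of class `oakqg_gradient` with `beta`,
#'   `se_beta`, `p_beta`, (`gamma`, `gamma_stinchcombe`, `p_gamma`,) `n`,
#'   `trait_mean`, `trait_sd`; the full coefficient table is attached as
#'   attribute `coefficients`.
#' @export
fit_selection_gradient <- function(data, trait, fitness = "w",
                                   covariates = c("C", "E", "P"),
                                   quadratic = FALSE, log_fitness = FALSE,
                                   max_kappa = 1e8) {
  data <- as.data.frame(data)
  need <- c(fitness, trait, covariates)
  stopifnot(all(need %in% names(data)))
  d <- data[complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  if (nrow(d) < 10) stop("fewer than 10 complete cases for trait '",
                         trait, "'")
  mu_x <- mean(d[[trait]]); sd_x <- sd(d[[trait]])
  if (sd_x <= 0) stop("trait '", trait, "' has zero variance")
  d$x_std <- (d[[trait]] - mu_x) / sd_x
  y <- if (log_fitness) log(d[[fitness]]) else d[[fitness]]
  rhs <- c(covariates, "x_std", if (quadratic) "I(x_std^2)")
  form <- stats::reformulate(rhs, response = "y")
  d$y <- y
  X <- model.matrix(form, d)
  kap <- kappa(X, exact = FALSE)
  if (kap > max_kappa)
    stop("near-collinear design (condition number ", format(kap, digits = 3),
         "); columns: ", paste(colnames(X), collapse = ", "))
  fit <- lm(form, data = d)
  ct <- summary(fit)$coefficients
  out <- data.frame(trait = trait,
                    beta = ct["x_std", 1], se_beta = ct["x_std", 2],
                    p_beta = ct["x_std", 4],
                    n = nrow(d), trait_mean = mu_x, trait_sd = sd_x,
                    stringsAsFactors = FALSE)
  if (quadratic) {
    out$gamma <- ct["I(x_std^2)", 1]
    out$gamma_stinchcombe <- 2 * ct["I(x_std^2)", 1]
    out$se_gamma <- ct["I(x_std^2)", 2]
    out$p_gamma <- ct["I(x_std^2)", 4]
  }
  structure(out, coefficients = ct, class = c("oakqg_gradient", "data.frame"))
}

#' Per-trait selection-gradient screen
#'
#' Fits [fit_selection_gradient()] for every trait column, separately per
#' species, skipping traits with more than half the values missing.
#' Unadjusted p-values are reported (as is conventional for selection
#' screens), with a Benjamini-Hochberg column added per species as a
#' flagged extra.
#'
#' @param traits `data.frame` with `tree_id`, `species` and trait columns.
#' @param fitness `data.frame` with `tree_id` and the fitness column.
#' @param covs Covariate table (`tree_id`, `C`, `E`, `P`); optional.
#' @param trait_cols Trait columns to screen (default: all non-id columns).
#' @param ... Passed to [fit_selection_gradient()].
#' @return `data.frame` with one row per trait x species, plus `p_bh`.
#' @export
gradient_screen <- function(traits, fitness, covs = NULL,
                            trait_cols = NULL, ...) {
  traits <- as.data.frame(traits)
  trait_cols <- trait_cols %||%
    setdiff(names(traits), c("tree_id", "species", "generation"))
  d <- merge(traits, fitness, by = "tree_id")
  covariates <- character(0)
  if (!is.null(covs)) {
    d <- merge(d, covs, by = "tree_id",
               suffixes = c("", ".cov"))
    covariates <- intersect(c("C", "E", "P"), names(covs))
  }
  out <- list()
  for (s in unique(d$species)) {
    ds <- d[d$species == s, , drop = FALSE]
    rows <- list()
    for (tr in trait_cols) {
      if (mean(is.na(ds[[tr]])) > 0.5) {
        message("skipping trait '", tr, "' in ", s, ": >50% missing")
        next
      }
      fitd <- tryCatch(
        fit_selection_gradient(ds, tr, covariates = covariates, ...),
        error = function(e) NULL)
      if (is.null(fitd)) next
      fitd$species <- s
      rows[[tr]] <- as.data.frame(fitd)
    }
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      tab$p_bh <- p.adjust(tab$p_beta, method = "BH")
      out[[s]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
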