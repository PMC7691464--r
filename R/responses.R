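#' Predicted inter-generational response in percent
#'
#' Converts the data-scale predicted genetic change of a trait into a
#' predicted next-generation mean and a percentage response:
#' `G2_pred = G1_mean + Re_data_scale` and
#' `Re_pct = (G2_pred - G1_mean) * 100 / G1_mean`.
#'
#' @param G1_mean Parental-generation phenotypic mean (non-zero).
#' @param Re_data_scale Predicted genetic change on the data scale.
#' @return `data.frame` with `G2_pred` and `Re_pct`.
#' @export
predicted_response_pct <- function(G1_mean, Re_data_scale) {
  if (any(G1_mean == 0)) stop("G1 mean must be non-zero")
  G2_pred <- G1_mean + Re_data_scale
  data.frame(G2_pred = G2_pred, Re_pct = (G2_pred - G1_mean) * 100 / G1_mean)
}

#' Observed phenotypic response from a parental-fitness split
#'
#' Splits the adult generation, per species, at the median of observed
#' fitness (a tree exactly at the median goes to the bottom class), classes
#' each sapling by its parents' classes and compares offspring phenotypic
#' means: `Delta_pct = (mean_top - mean_bottom) * 100 / mean(top, bottom)`
#' with the signed mean in the denominator. A warning flags negative
#' denominators (traits with negative means), where the percentage sign
#' convention becomes ambiguous.
#'
#' @param traits_g2 `data.frame` with `tree_id` and the trait column for
#'   the sapling generation.
#' @param fitness_g1 `data.frame` with `tree_id`, `species`, `w` for
#'   adults.
#' @param pedigree `data.frame` with `id`, `mother`, `father` for saplings.
#' @param trait Trait column name.
#' @param rule Class rule when the two parents disagree: `"mean"` (class by
#'   the mean of the two parental fitness values against the species
#'   median), `"mother"`, or `"exclude"`.
#' @return One-row `data.frame` per species with class means, counts and
#'   `Delta_pct`.
#' @export
parental_split_response <- function(traits_g2, fitness_g1, pedigree, trait,
                                    rule = c("mean", "mother", "exclude")) {
  rule <- match.arg(rule)
  fitness_g1 <- as.data.frame(fitness_g1)
  traits_g2 <- as.data.frame(traits_g2)
  pedigree <- as.data.frame(pedigree)
  out <- list()
  for (s in unique(fitness_g1$species)) {
    fs <- fitness_g1[fitness_g1$species == s, ]
    med <- median(fs$w)
    cls <- setNames(ifelse(fs$w <= med, "bottom", "top"), fs$tree_id)
    wval <- setNames(fs$w, fs$tree_id)
    ped <- pedigree[pedigree$mother %in% fs$tree_id |
                    pedigree$father %in% fs$tree_id, , drop = FALSE]
    ocls <- rep(NA_character_, nrow(ped))
    for (i in seq_len(nrow(ped))) {
      cm <- cls[ped$mother[i]]; cf <- cls[ped$father[i]]
      known <- c(cm, cf)[!is.na(c(cm, cf))]
      if (!length(known)) next
      if (length(unique(known)) == 1) { ocls[i] <- known[1]; next }
      ocls[i] <- switch(rule,
        mean = {
          pw <- mean(wval[c(ped$mother[i], ped$father[i])], na.rm = TRUE)
          if (pw <= med) "bottom" else "top"
        },
        mother = cm,
        exclude = NA_character_)
    }
    x <- traits_g2[[trait]][match(ped$id, traits_g2$tree_id)]
    keep <- !is.na(ocls) & !is.na(x)
    mb <- mean(x[keep & ocls == "bottom"])
    mt <- mean(x[keep & ocls == "top"])
    if (!sum(keep & ocls == "bottom") || !sum(keep & ocls == "top"))
      stop("empty parental-fitness class for species '", s, "'")
    denom <- mean(c(mt, mb))
    if (denom < 0)
      warning("negative class-mean denominator for '", trait, "' (", s,
              "): the sign of Delta_pct follows the signed mean")
    out[[s]] <- data.frame(
      species = s, trait = trait, G2_minus = mb, G2_plus = mt,
      n_minus = sum(keep & ocls == "bottom"),
      n_plus = sum(keep & ocls == "top"),
      Delta_pct = (mt - mb) * 100 / denom, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sign-concordance summary of predicted and observed responses
#'
#' The comparison of prediction methods is deliberately qualitative: only
#' the signs of the shifts are compared. For each trait the signs of the
#' predicted genetic response, the observed phenotypic response and (when
#' available) the generation shift in mean breeding values are tabulated
#' with agreement flags and per-group concordance counts.
#'
#' @param response_table `data.frame` with `trait`, `Re_pct`, `Delta_pct`
#'   and optionally `blup_shift` and `species`.
#' @return List with `table` (per-trait signs and flags) and `summary`
#'   (concordant / discordant counts, per species when present).
#' @export
concordance_report <- function(response_table) {
  tb <- as.data.frame(response_table)
  stopifnot(all(c("trait", "Re_pct", "Delta_pct") %in% names(tb)))
  tb$sign_Re <- sign(tb$Re_pct)
  tb$sign_Delta <- sign(tb$Delta_pct)
  tb$concordant <- tb$sign_Re == tb$sign_Delta
  if ("blup_shift" %in% names(tb)) {
    tb$sign_blup <- sign(tb$blup_shift)
    tb$concordant_blup <- tb$sign_Re == tb$sign_blup
  }
  grp <- if ("species" %in% names(tb)) tb$species else rep("all", nrow(tb))
  smry <- aggregate(list(n_concordant = tb$concordant,
                         n_traits = !is.na(tb$concordant)),
                    by = list(species = grp),
                    FUN = function(v) sum(v, na.rm = TRUE))
  list(table = tb, summary = smry)
}

#' Published predicted/observed response means
#'
#' The printed per-trait response tables for the two oak species: parental
#' (G1) phenotypic means, predicted next-generation means and responses
#' (Re%), and offspring means by parental-fitness class with the observed
#' response (Delta%). Shipped as a plain-text fixture so the worked-example
#' arithmetic can be recomputed without external data.
#'
#' @return `data.frame` with one row per species x trait.
#' @export
published_responses <- function() {
  path <- system.file("extdata", "published_response_means.tsv",
                      package = "oakqg")
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Recompute the worked-example response percentages
#'
#' Recomputes every `Re%` cell from the printed G1 and predicted-G2 means,
#' and every `Delta%` cell from the printed class means, using
#' [predicted_response_pct()] arithmetic and the signed-mean denominator.
#'
#' @param tbl Table in the format of [published_responses()].
#' @return The table with `Re_pct_recomputed` and `Delta_pct_recomputed`
#'   columns appended.
#' @export
recompute_published_responses <- function(tbl = published_responses()) {
  tbl$Re_pct_recomputed <- (tbl$G2_pred - tbl$G1) * 100 / tbl$G1
  denom <- (tbl$G2_plus + tbl$G2_minus) / 2
  tbl$Delta_pct_recomputed <- (tbl$G2_plus - tbl$G2_minus) * 100 / denom
  tbl
}
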