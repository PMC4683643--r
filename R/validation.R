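#' Reference genetic values for cross-validation
#'
#' Fits the full three-kernel model on all available data and returns the
#' BLUP genetic value `a + d + i` per individual, the single target every
#' model variant's predictions are scored against.
#'
#' @param blues BLUE table for one trait.
#' @param kernels named list `Ga`, `Gd`, `Gaa` of [rel_matrix()] objects.
#' @return named numeric vector of BLUP genetic values.
#' @export
cv_reference_gv <- function(blues, kernels) {
  fit <- reml_fit(assemble_design(blues, kernels, "ADE"))
  fit$effects$gv
}

.cv_fold <- function(train_blues, kernels, variant, vp_ids, ref_gv, Ga) {
  fit <- reml_fit(assemble_design(train_blues, kernels, variant))
  gegv <- fit$effects$gv[vp_ids]
  obs <- ref_gv[vp_ids]
  tp_ids <- setdiff(rownames(Ga), vp_ids)
  acc <- if (stats::sd(obs) > 0 && stats::sd(gegv) > 0)
    stats::cor(gegv, obs) else NA_real_
  bias <- if (stats::sd(gegv) > 0)
    unname(stats::coef(stats::lm(obs ~ gegv))[2]) else NA_real_
  list(accuracy = acc, bias = bias,
       relatedness = mean(Ga[vp_ids, tp_ids]),
       converged = fit$converged, gegv = gegv)
}

#' Leave-one-family-out cross-validation, untested strategy
#'
#' Each full-sib family in turn is treated as completely untested: its
#' rows are removed at every site, variance components are re-estimated on
#' the remaining families, and the family's genetic values are predicted
#' through the kernel cross-covariances.  Accuracy is the correlation of
#' the predicted genetic value (`a + d + i`, `a + d` or `a` depending on
#' the variant) with the all-data BLUP genetic value; bias is the slope of
#' the latter regressed on the former.
#'
#' @param blues BLUE table for one trait.
#' @param kernels named list `Ga`, `Gd`, `Gaa` of [rel_matrix()] objects.
#' @param families named vector mapping individual id to family label.
#' @param variant `"A"`, `"AD"` or `"ADE"`.
#' @param ref_gv reference genetic values; computed by [cv_reference_gv()]
#'   when missing.
#' @param min_family folds with fewer members are skipped with a warning.
#' @return data frame, one row per completed fold.
#' @export
cv_untested <- function(blues, kernels, families, variant = "ADE",
                        ref_gv = NULL, min_family = 3) {
  trait <- unique(blues$trait)
  stopifnot(length(trait) == 1)
  if (is.null(ref_gv)) ref_gv <- cv_reference_gv(blues, kernels)
  Ga <- kernels$Ga$values
  out <- list()
  for (f in sort(unique(families))) {
    vp_ids <- intersect(names(families)[families == f],
                        unique(blues$individual_id))
    if (length(vp_ids) < min_family) {
      warning("skipping family ", f, ": fewer than ", min_family, " members")
      next
    }
    train <- blues[!blues$individual_id %in% vp_ids, , drop = FALSE]
    r <- .cv_fold(train, kernels, variant, vp_ids, ref_gv, Ga)
    out[[f]] <- data.frame(
      family = f, strategy = "untested_both_sites", site = NA_character_,
      trait = trait, variant = variant, accuracy = r$accuracy, bias = r$bias,
      n_validation = length(vp_ids),
      mean_tp_vp_relatedness = r$relatedness, converged = r$converged,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Leave-one-family-out cross-validation, single-site strategy
#'
#' The validation family is kept at one site but masked at the target
#' site, mimicking prediction of performance in an untested environment
#' from relatives at the target site plus the family's own records
#' elsewhere.
#'
#' @inheritParams cv_untested
#' @param target_site site whose records are masked and predicted.
#' @return data frame, one row per completed fold.
#' @export
cv_single_site <- function(blues, kernels, families, variant = "ADE",
                           target_site, ref_gv = NULL, min_family = 3) {
  trait <- unique(blues$trait)
  stopifnot(length(trait) == 1)
  if (!target_site %in% blues$site) stop("unknown target site: ", target_site)
  if (is.null(ref_gv)) ref_gv <- cv_reference_gv(blues, kernels)
  Ga <- kernels$Ga$values
  out <- list()
  for (f in sort(unique(families))) {
    vp_ids <- intersect(names(families)[families == f],
                        unique(blues$individual_id))
    masked <- blues$individual_id %in% vp_ids & blues$site == target_site
    if (sum(masked) == 0 || length(vp_ids) < min_family) {
      warning("skipping family ", f, " at site ", target_site)
      next
    }
    train <- blues[!masked, , drop = FALSE]
    r <- .cv_fold(train, kernels, variant, vp_ids, ref_gv, Ga)
    out[[f]] <- data.frame(
      family = f, strategy = "tested_one_site", site = target_site,
      trait = trait, variant = variant, accuracy = r$accuracy, bias = r$bias,
      n_validation = length(vp_ids),
      mean_tp_vp_relatedness = r$relatedness, converged = r$converged,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlates of prediction accuracy
#'
#' Pearson correlation of per-family accuracy (averaged over traits when
#' several are supplied) with the family's mean training-validation
#' additive relatedness, and of per-trait mean accuracy with the trait's
#' narrow-sense heritability.
#'
#' @param results row-bound fold results from [cv_untested()] /
#'   [cv_single_site()], possibly spanning several traits.
#' @param h2 named vector of per-trait narrow-sense heritabilities
#'   (required for the heritability correlate).
#' @return list `r_relatedness`, `r_heritability`, `per_family`,
#'   `per_trait`.
#' @export
accuracy_correlates <- function(results, h2 = NULL) {
  stopifnot(is.data.frame(results))
  ok <- is.finite(results$accuracy)
  results <- results[ok, , drop = FALSE]
  per_family <- stats::aggregate(
    results[c("accuracy", "mean_tp_vp_relatedness")],
    by = list(family = results$family), FUN = mean)
  r_rel <- NA_real_
  if (nrow(per_family) >= 3 &&
      stats::sd(per_family$accuracy) > 0 &&
      stats::sd(per_family$mean_tp_vp_relatedness) > 0) {
    r_rel <- stats::cor(per_family$accuracy,
                        per_family$mean_tp_vp_relatedness)
  }
  per_trait <- stats::aggregate(results["accuracy"],
                                by = list(trait = results$trait), FUN = mean)
  r_h2 <- NA_real_
  if (!is.null(h2)) {
    per_trait$h2 <- h2[per_trait$trait]
    if (nrow(per_trait) >= 3 && stats::sd(per_trait$accuracy) > 0 &&
        stats::sd(per_trait$h2) > 0) {
      r_h2 <- stats::cor(per_trait$accuracy, per_trait$h2)
    }
  }
  list(r_relatedness = r_rel, r_heritability = r_h2,
       per_family = per_family, per_trait = per_trait)
}
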