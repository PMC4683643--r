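#' Stage-one adjusted phenotypes (BLUEs)
#'
#' Collapses clonal-replicate x year records to one adjusted value per
#' individual per site per trait by ordinary least squares on
#' `value ~ genotype + year + replicate` (all fixed), fitted within site.
#' Year and replicate enter as additive factors; factors with a single
#' observed level are dropped from the formula.  The genotype estimates are
#' re-centered so the mean BLUE equals the site's raw trait mean.
#' Genotypes with a single record still receive a BLUE (their record
#' adjusted by the year/replicate estimates).
#'
#' @param pheno phenotype record data frame (see [read_phenotypes()]).
#' @param traits,sites optional subsets; default all present.
#' @return data frame `individual_id, site, trait, blue, n_records`.
#' @export
compute_blues <- function(pheno, traits = NULL, sites = NULL) {
  pheno <- validate_phenotypes(pheno)
  if (is.null(traits)) traits <- unique(pheno$trait)
  if (is.null(sites)) sites <- unique(pheno$site)
  out <- list()
  for (tr in traits) for (st in sites) {
    d <- pheno[pheno$trait == tr & pheno$site == st, , drop = FALSE]
    if (!nrow(d)) next
    out[[paste(tr, st)]] <- .blues_one(d, tr, st)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.blues_one <- function(d, trait, site) {
  d$genotype <- factor(d$individual_id)
  d$yearF <- factor(d$year)
  d$repF <- factor(d$replicate)
  terms <- "genotype"
  if (nlevels(d$yearF) > 1) terms <- c(terms, "yearF")
  if (nlevels(d$repF) > 1) terms <- c(terms, "repF")
  fit <- stats::lm(stats::reformulate(terms, "value"), data = d)
  cf <- stats::coef(fit)
  nuisance <- cf[grep("^(yearF|repF)", names(cf))]
  if (anyNA(nuisance)) {
    bad <- names(nuisance)[is.na(nuisance)]
    stop("confounded stage-one design: cannot separate ",
         paste(bad, collapse = ", "), " from genotype at site ", site)
  }
  # genotype effect = intercept + treatment contrast; constant shifts from
  # the year/replicate reference levels are absorbed by re-centering
  g_lab <- paste0("genotype", levels(d$genotype))
  eff <- c(0, cf[g_lab[-1]])  # reference level first
  blue <- cf[1] + eff
  blue <- blue - mean(blue) + mean(d$value)
  data.frame(individual_id = levels(d$genotype), site = site, trait = trait,
             blue = unname(blue),
             n_records = as.integer(table(d$genotype)),
             stringsAsFactors = FALSE)
}

#' Per-site trait summary
#'
#' Mean and coefficient of variation (sd/mean x 100) per site and trait,
#' plus a two-sample Welch test of the site-mean difference when exactly
#' two sites are present.
#'
#' @param pheno phenotype record data frame.
#' @return data frame with one row per trait x site and, when two sites
#'   are present, the p-value of the site contrast repeated on both rows.
#' @export
site_trait_summary <- function(pheno) {
  pheno <- validate_phenotypes(pheno)
  out <- list()
  for (tr in unique(pheno$trait)) {
    d <- pheno[pheno$trait == tr, ]
    sites <- sort(unique(d$site))
    p_site <- NA_real_
    if (length(sites) == 2) {
      p_site <- tryCatch(stats::t.test(value ~ site, data = d)$p.value,
                         error = function(e) NA_real_)
    }
    for (st in sites) {
      v <- d$value[d$site == st]
      out[[paste(tr, st)]] <- data.frame(
        trait = tr, site = st, n = length(v), mean = mean(v),
        cv_pct = 100 * stats::sd(v) / mean(v),
        p_site_diff = p_site, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
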