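#' Simulation configuration for a synthetic clonal trial
#'
#' Defaults emulate a two-site clonal apple trial: 25 interrelated parents
#' (background relatedness induced through a small grandparental pool so the
#' mean pedigree relationship among parents is about 0.15), 17 full-sib
#' families of 15 offspring, 2828 polymorphic SNPs with MAF at or above
#' 0.05, up to four clonal replicates per individual at each of two sites
#' over two years.  `var_components` gives the target fractions of
#' stage-two phenotypic variance for the seven model components
#' (additive `a`, dominance `d`, additive-by-additive epistasis `aa`, their
#' site interactions `as`, `ds`, `aas`, and residual `e`); the default is
#' the across-trait average architecture of the motivating trial.
#'
#' @param n_parents,n_families,family_size pedigree dimensions.
#' @param n_snps number of unlinked biallelic SNPs.
#' @param maf_floor lower bound of founder allele frequencies (in \[0, 0.5)).
#' @param n_sites,n_reps,n_years trial dimensions.
#' @param var_components named nonnegative fractions for
#'   `a, d, aa, as, ds, aas, e`; must sum to one.
#' @param contamination_rate probability that an offspring's true sire
#'   differs from the recorded one (pollen contamination / mislabeling).
#' @param n_grandparents size of the grandparental pool from which parents
#'   are drawn; smaller pools give more related parents.
#' @param seed integer seed; every stochastic step of the generator is
#'   reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 25, n_families = 17, family_size = 15,
                       n_snps = 2828, maf_floor = 0.05,
                       n_sites = 2, n_reps = 4, n_years = 2,
                       var_components = c(a = 0.30, d = 0.16, aa = 0.19,
                                          as = 0.015, ds = 0.015, aas = 0.025,
                                          e = 0.295),
                       contamination_rate = 0,
                       n_grandparents = 7,
                       seed = 1L) {
  stopifnot(n_parents >= 2, n_families >= 1, family_size >= 1, n_snps >= 1,
            n_sites >= 1, n_reps >= 1, n_years >= 1,
            maf_floor >= 0, maf_floor < 0.5,
            contamination_rate >= 0, contamination_rate <= 1,
            n_grandparents >= 2)
  need <- c("a", "d", "aa", "as", "ds", "aas", "e")
  if (!all(need %in% names(var_components)))
    stop("var_components must name: ", paste(need, collapse = ", "))
  var_components <- var_components[need]
  if (any(var_components < 0)) stop("variance fractions must be nonnegative")
  if (abs(sum(var_components) - 1) > 1e-6)
    stop("variance fractions must sum to 1 (got ", sum(var_components), ")")
  if (choose(n_parents, 2) < n_families)
    stop("not enough distinct parent pairs for ", n_families, " families")
  structure(list(n_parents = n_parents, n_families = n_families,
                 family_size = family_size, n_snps = n_snps,
                 maf_floor = maf_floor, n_sites = n_sites, n_reps = n_reps,
                 n_years = n_years, var_components = var_components,
                 contamination_rate = contamination_rate,
                 n_grandparents = n_grandparents, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate founder (parent) genotypes
#'
#' Grandparents are drawn from Hardy-Weinberg proportions at per-SNP allele
#' frequencies uniform on \[maf_floor, 1 - maf_floor\]; parents are produced
#' by Mendelian gene drop from random grandparent pairs, which induces
#' background relatedness among parents (full/half-sib ties through the
#' small pool).
#'
#' @param config [sim_config()].
#' @return [geno_matrix()] of parent genotypes with attributes
#'   `true_freqs` (founder allele frequencies) and `parent_pedigree`
#'   (grandparents plus parents, topologically sorted).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  p <- stats::runif(m, config$maf_floor, 1 - config$maf_floor)
  gp_ids <- sprintf("GP%02d", seq_len(config$n_grandparents))
  gp <- matrix(stats::rbinom(config$n_grandparents * m, 2, rep(p, each = config$n_grandparents)),
               nrow = config$n_grandparents,
               dimnames = list(gp_ids, sprintf("S%04d", seq_len(m))))
  # each parent from a random distinct grandparent pair
  pairs <- t(vapply(seq_len(config$n_parents),
                    function(i) sample(config$n_grandparents, 2),
                    integer(2)))
  par_ids <- sprintf("P%02d", seq_len(config$n_parents))
  parents <- matrix(0L, config$n_parents, m,
                    dimnames = list(par_ids, colnames(gp)))
  for (i in seq_len(config$n_parents)) {
    parents[i, ] <- .transmit(gp[pairs[i, 1], ]) + .transmit(gp[pairs[i, 2], ])
  }
  ped <- data.frame(
    individual_id = c(gp_ids, par_ids),
    sire_id = c(rep(NA_character_, config$n_grandparents), gp_ids[pairs[, 1]]),
    dam_id = c(rep(NA_character_, config$n_grandparents), gp_ids[pairs[, 2]]),
    stringsAsFactors = FALSE)
  out <- geno_matrix(parents)
  attr(out, "true_freqs") <- p
  attr(out, "parent_pedigree") <- sort_pedigree(ped)
  out
}

# one gamete per locus: fair Mendelian sampling from a dosage vector
.transmit <- function(dos) {
  g <- integer(length(dos))
  het <- dos == 1L
  g[dos == 2L] <- 1L
  g[het] <- stats::rbinom(sum(het), 1, 0.5)
  g
}

#' Assign full-sib families to parent pairs
#'
#' Chooses `n_families` distinct parent pairs, covering every parent at
#' least once when possible, and returns the recorded offspring pedigree.
#'
#' @param config [sim_config()].
#' @param parent_ids character vector of parent ids.
#' @return data frame `individual_id, sire_id, dam_id, family` for all
#'   offspring.
#' @export
make_families <- function(config, parent_ids) {
  stopifnot(length(parent_ids) == config$n_parents)
  perm <- sample(parent_ids)
  pairs <- list()
  # cover all parents first with disjoint consecutive pairs
  i <- 1
  while (i + 1 <= length(perm) && length(pairs) < config$n_families) {
    pairs[[length(pairs) + 1]] <- c(perm[i], perm[i + 1])
    i <- i + 2
  }
  if (i == length(perm) && length(pairs) < config$n_families)
    pairs[[length(pairs) + 1]] <- c(perm[i], sample(setdiff(parent_ids, perm[i]), 1))
  seen <- vapply(pairs, paste, character(1), collapse = "\r")
  while (length(pairs) < config$n_families) {
    cand <- sort(sample(parent_ids, 2))
    key <- paste(cand, collapse = "\r")
    if (!key %in% seen) {
      pairs[[length(pairs) + 1]] <- cand
      seen <- c(seen, key)
    }
  }
  fam_ids <- sprintf("F%02d", seq_along(pairs))
  off <- do.call(rbind, lapply(seq_along(pairs), function(f) {
    data.frame(
      individual_id = sprintf("%s_%02d", fam_ids[f], seq_len(config$family_size)),
      sire_id = pairs[[f]][1], dam_id = pairs[[f]][2],
      family = fam_ids[f], stringsAsFactors = FALSE)
  }))
  off
}

#' Mendelian gene drop from parents to offspring
#'
#' Each offspring receives one allele per locus from each recorded parent
#' by fair Mendelian sampling over unlinked loci.  With probability
#' `contamination_rate` an offspring's transmitting sire is replaced by a
#' different random parent while the recorded pedigree is left unchanged.
#'
#' @param parents [geno_matrix()] of parent genotypes.
#' @param pedigree data frame with `individual_id, sire_id, dam_id` for the
#'   offspring to generate (recorded pedigree).
#' @param config [sim_config()].
#' @return [geno_matrix()] of offspring genotypes with attribute
#'   `true_sires` (the actually transmitting sire per offspring).
#' @export
gene_drop <- function(parents, pedigree, config) {
  stopifnot(inherits(parents, "geno_matrix"))
  ids <- rownames(parents$dosages)
  unknown <- setdiff(c(pedigree$sire_id, pedigree$dam_id), ids)
  if (length(unknown))
    stop("unknown parent id(s): ", paste(unknown, collapse = ", "))
  n_off <- nrow(pedigree)
  true_sire <- pedigree$sire_id
  contam <- stats::runif(n_off) < config$contamination_rate
  for (k in which(contam))
    true_sire[k] <- sample(setdiff(ids, pedigree$sire_id[k]), 1)
  off <- matrix(0L, n_off, ncol(parents$dosages),
                dimnames = list(pedigree$individual_id,
                                colnames(parents$dosages)))
  for (k in seq_len(n_off)) {
    off[k, ] <- .transmit(parents$dosages[true_sire[k], ]) +
      .transmit(parents$dosages[pedigree$dam_id[k], ])
  }
  out <- geno_matrix(off)
  attr(out, "true_sires") <- stats::setNames(true_sire, pedigree$individual_id)
  out
}

#' Simulate phenotype records with known genetic ground truth
#'
#' Additive effects are per-SNP normal draws applied to frequency-centered
#' dosages; dominance effects are normal draws applied to the
#' heterozygosity coding; additive-by-additive epistasis is realized as
#' pairwise products of centered additive codings over `2 * n_snps` random
#' locus pairs.  Each component is rescaled exactly so that the variance it
#' implies on the model scale (its realized variance divided by the
#' corresponding kernel's scale factor `tr(K)/n - sum(K)/n^2`) equals its
#' target fraction of the stage-two phenotypic variance.  Site-interaction
#' deviations are drawn with covariance proportional to the matching kernel
#' per site.  Records (one per clonal replicate x year x site) add fixed
#' site, year and replicate offsets plus a residual whose per-individual-
#' site average hits the residual target, so that targets are recovered at
#' the adjusted-phenotype (stage-two) level.
#'
#' @param geno [geno_matrix()] of the analysis individuals.
#' @param config [sim_config()].
#' @param trait trait label written into the records.
#' @return list with `pheno` (record data frame) and `truth` (per-individual
#'   `a`, `d`, `i` vectors, per-site interaction deviations, target and
#'   realized variance fractions, and the kernels used).
#' @export
simulate_phenotypes <- function(geno, config, trait = "trait1") {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  vc <- config$var_components
  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  ids <- rownames(geno$dosages)
  p <- geno$freqs
  M <- sweep(geno$dosages, 2, 2 * p)
  tpq <- 2 * p * (1 - p)
  H <- sweep((geno$dosages == 1) * 1, 2, tpq)

  Ga <- build_Ga(geno)
  Gd <- build_Gd(geno)
  Gaa <- build_Gaa(Ga)
  kern <- list(a = Ga$values, d = Gd$values, aa = Gaa$values)

  # kernel scale factor linking sigma^2 to realized (population) variance
  cfac <- function(K) mean(diag(K)) - sum(K) / nrow(K)^2
  pvar <- function(x) mean((x - mean(x))^2)
  rescale <- function(x, target, c_k) {
    if (target <= 0) return(numeric(length(x)))
    v <- pvar(x)
    if (v <= 0) stop("degenerate component: zero realized variance")
    x * sqrt(target * c_k / v)
  }

  a_raw <- drop(M %*% stats::rnorm(m))
  d_raw <- drop(H %*% stats::rnorm(m))
  n_pairs <- 2L * m
  pr1 <- sample.int(m, n_pairs, replace = TRUE)
  pr2 <- sample.int(m, n_pairs, replace = TRUE)
  keep <- pr1 != pr2
  i_raw <- drop((M[, pr1[keep], drop = FALSE] * M[, pr2[keep], drop = FALSE]) %*%
                  stats::rnorm(sum(keep)))

  a_eff <- rescale(a_raw, vc["a"], cfac(kern$a))
  d_eff <- rescale(d_raw, vc["d"], cfac(kern$d))
  i_eff <- rescale(i_raw, vc["aa"], cfac(kern$aa))

  s_labels <- paste0("site", seq_len(config$n_sites))
  int_targets <- c(a = unname(vc["as"]), d = unname(vc["ds"]),
                   aa = unname(vc["aas"]))
  t_dev <- list()
  for (comp in names(int_targets)) {
    tg <- int_targets[[comp]]
    mat <- matrix(0, config$n_sites, n, dimnames = list(s_labels, ids))
    if (tg > 0) {
      K <- condition_kernel(rel_matrix(kern[[comp]], "additive_genomic"))$values
      L <- t(chol(K + diag(1e-10, n)))
      for (s in seq_len(config$n_sites)) mat[s, ] <- drop(L %*% stats::rnorm(n))
      # Is (x) K over ns units: scale factor uses stacked vector variance
      c_int <- mean(diag(K)) - sum(K) / (n^2 * config$n_sites)
      vec <- as.numeric(t(mat))
      mat <- mat * sqrt(tg * c_int / pvar(vec))
    }
    t_dev[[comp]] <- mat
  }

  year_eff <- (seq_len(config$n_years) - 1) * 0.3
  rep_eff <- (seq_len(config$n_reps) - 1) * 0.1
  site_mean <- 10 + (seq_len(config$n_sites) - 1) * 0.5

  rec <- expand.grid(replicate = seq_len(config$n_reps),
                     year = seq_len(config$n_years),
                     individual_id = ids, site = s_labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_rec <- nrow(rec)
  e_rec <- stats::rnorm(n_rec)
  # residual target applies to the per-(individual, site) average
  cell <- paste(rec$individual_id, rec$site, sep = "\r")
  e_bar <- tapply(e_rec, cell, mean)
  c_e <- 1 - 1 / (n * config$n_sites)
  e_rec <- e_rec * sqrt(vc["e"] * c_e / pvar(as.numeric(e_bar)))

  ii <- match(rec$individual_id, ids)
  ss <- match(rec$site, s_labels)
  g_main <- a_eff[ii] + d_eff[ii] + i_eff[ii]
  g_int <- t_dev$a[cbind(ss, ii)] + t_dev$d[cbind(ss, ii)] +
    t_dev$aa[cbind(ss, ii)]
  rec$trait <- trait
  rec$value <- site_mean[ss] + year_eff[rec$year] + rep_eff[rec$replicate] +
    g_main + g_int + e_rec
  rec <- rec[c("individual_id", "site", "year", "replicate", "trait", "value")]

  implied <- function(x, c_k) pvar(x) / c_k
  e_bar2 <- tapply(e_rec, cell, mean)
  realized <- c(a = implied(a_eff, cfac(kern$a)),
                d = implied(d_eff, cfac(kern$d)),
                aa = implied(i_eff, cfac(kern$aa)),
                as = if (int_targets[["a"]] > 0)
                  implied(as.numeric(t(t_dev$a)),
                          mean(diag(kern$a)) - sum(kern$a) / (n^2 * config$n_sites)) else 0,
                ds = if (int_targets[["d"]] > 0)
                  implied(as.numeric(t(t_dev$d)),
                          mean(diag(kern$d)) - sum(kern$d) / (n^2 * config$n_sites)) else 0,
                aas = if (int_targets[["aa"]] > 0)
                  implied(as.numeric(t(t_dev$aa)),
                          mean(diag(kern$aa)) - sum(kern$aa) / (n^2 * config$n_sites)) else 0,
                e = implied(as.numeric(e_bar2), c_e))
  truth <- list(a = stats::setNames(a_eff, ids),
                d = stats::setNames(d_eff, ids),
                i = stats::setNames(i_eff, ids),
                site_deviations = t_dev,
                target_fractions = vc,
                realized_fractions = realized / sum(realized),
                kernels = list(Ga = Ga, Gd = Gd, Gaa = Gaa))
  list(pheno = validate_phenotypes(rec, sites = s_labels), truth = truth)
}

#' Simulate a complete clonal trial
#'
#' Runs founder simulation, family assignment, gene drop and phenotype
#' simulation under one seed, returning everything the analysis pipeline
#' consumes plus the ground truth.
#'
#' @param config [sim_config()].
#' @param trait trait label.
#' @return list with `geno` (offspring genotypes), `parents`, `pedigree`
#'   (grandparents, parents and offspring; recorded, i.e. pre-contamination),
#'   `families` (named vector id -> family), `pheno`, `truth`.
#' @export
simulate_trial <- function(config, trait = "trait1") {
  founders <- simulate_founders(config)           # seeds the RNG
  fam <- make_families(config, rownames(founders$dosages))
  off <- gene_drop(founders, fam, config)
  sim <- simulate_phenotypes(off, config, trait = trait)
  ped_top <- attr(founders, "parent_pedigree")
  ped <- rbind(as.data.frame(ped_top),
               fam[c("individual_id", "sire_id", "dam_id")])
  list(geno = off, parents = founders, pedigree = sort_pedigree(ped),
       families = stats::setNames(fam$family, fam$individual_id),
       pheno = sim$pheno, truth = sim$truth,
       true_sires = attr(off, "true_sires"), config = config)
}
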