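#' Variance components of the two-site multi-kernel model
#'
#' The stage-two model decomposes an adjusted phenotype observed on `n`
#' individuals at `s` sites into fixed site effects plus random additive
#' (`a`), dominance (`d`) and additive-by-additive epistatic (`aa`) effects
#' with covariances proportional to the corresponding genomic kernels,
#' their site interactions (`as`, `ds`, `aas`, covariance `I_s (x) G`),
#' and an i.i.d. residual (`e`).  Under site-major record ordering each
#' main-effect covariance contribution is `(1_s 1_s') (x) G` and each
#' interaction contribution is `I_s (x) G`.
#'
#' @name model_overview
NULL

.variant_components <- function(variant, n_sites) {
  main <- switch(variant,
                 A = "a", AD = c("a", "d"), ADE = c("a", "d", "aa"),
                 stop("unknown model variant: ", variant))
  if (n_sites > 1) c(main, paste0(main, "s")) else main
}

.main_of <- function(comp) sub("s$", "", comp)

#' Construct a mixed-model design directly
#'
#' Low-level constructor used by [assemble_design()] and by tests that
#' need arbitrary kernel sets.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param K named list of record-level covariance kernels (N x N), one per
#'   random component excluding the residual.
#' @param kernels_full optional named list of individual-level kernels for
#'   BLUP back-mapping.
#' @param ind_idx,site_idx optional record-to-individual and record-to-site
#'   index vectors.
#' @param ids,sites optional identifier vectors matching the indices.
#' @return list of class `mixed_design`.
#' @export
mixed_design <- function(y, X, K, kernels_full = NULL, ind_idx = NULL,
                         site_idx = NULL, ids = NULL, sites = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(vapply(K, nrow, 1L) == length(y)))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  structure(list(y = y, X = X, K = K, kernels_full = kernels_full,
                 ind_idx = ind_idx, site_idx = site_idx, ids = ids,
                 sites = sites),
            class = "mixed_design")
}

#' Assemble the stage-two design from BLUEs and kernels
#'
#' Stacks per-site adjusted phenotypes in site-major order (all individuals
#' of site 1, then site 2, ...), builds the fixed-effect design
#' (intercept + site), and expands the individual-level kernels to record
#' level: `G[ind_i, ind_j]` for main effects and the same masked to
#' same-site pairs for interactions.  Individuals missing at a site are
#' simply absent from that site's rows (masking by row omission).
#'
#' @param blues BLUE table (one trait) from [compute_blues()].
#' @param kernels named list with elements `Ga`, and for the larger
#'   variants `Gd`/`Gaa`, each a [rel_matrix()] over the same ids.
#' @param variant `"A"`, `"AD"` or `"ADE"`.
#' @param trait optional trait to select when `blues` holds several.
#' @return `mixed_design` with component kernels named
#'   `a, d, aa, as, ds, aas` as present.
#' @export
assemble_design <- function(blues, kernels, variant = c("ADE", "AD", "A"),
                            trait = NULL) {
  variant <- match.arg(variant)
  if (!is.null(trait)) blues <- blues[blues$trait == trait, , drop = FALSE]
  if (length(unique(blues$trait)) > 1)
    stop("blues table holds several traits; pass `trait`")
  ids <- rownames(kernels$Ga$values)
  missing_ids <- setdiff(unique(blues$individual_id), ids)
  if (length(missing_ids))
    stop("individual(s) in blues absent from kernels: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  sites <- sort(unique(blues$site))
  blues$.ind <- match(blues$individual_id, ids)
  blues <- blues[order(match(blues$site, sites), blues$.ind), , drop = FALSE]
  ind_idx <- blues$.ind
  site_idx <- match(blues$site, sites)
  y <- blues$blue
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  if (length(sites) > 1) {
    dummies <- stats::model.matrix(~ factor(site_idx))[, -1, drop = FALSE]
    colnames(dummies) <- paste0("site_", sites[-1])
    X <- cbind(X, dummies)
  }
  comps <- .variant_components(variant, length(sites))
  full <- list(a = kernels$Ga, d = kernels$Gd, aa = kernels$Gaa)
  same_site <- outer(site_idx, site_idx, "==") * 1
  K <- list()
  for (cc in comps) {
    main <- .main_of(cc)
    if (is.null(full[[main]]))
      stop("variant ", variant, " needs kernel for component '", main, "'")
    Krec <- full[[main]]$values[ind_idx, ind_idx, drop = FALSE]
    if (grepl("s$", cc)) Krec <- Krec * same_site
    K[[cc]] <- Krec
  }
  mixed_design(y, X, K,
               kernels_full = lapply(full[!vapply(full, is.null, TRUE)],
                                     function(k) k$values),
               ind_idx = ind_idx, site_idx = site_idx, ids = ids,
               sites = sites)
}

# one REML evaluation: restricted log-likelihood and projection pieces
.reml_core <- function(design, sigma2) {
  y <- design$y; X <- design$X
  N <- length(y)
  V <- diag(sigma2[["e"]], N)
  for (nm in names(design$K)) V <- V + sigma2[[nm]] * design$K[[nm]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  W <- Vinv %*% X
  XtVX <- crossprod(X, W)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  XtVXinv <- chol2inv(chx)
  P <- Vinv - W %*% XtVXinv %*% t(W)
  Py <- drop(P %*% y)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(chx))) + sum(y * Py))
  list(ll = ll, P = P, Py = Py, Vinv = Vinv, XtVXinv = XtVXinv, W = W)
}

#' Restricted log-likelihood at given variance components
#'
#' @param design `mixed_design`.
#' @param sigma2 named vector of component variances including `e`.
#' @return restricted log-likelihood (`-Inf` if the implied covariance is
#'   not positive definite).
#' @export
reml_loglik <- function(design, sigma2) {
  core <- .reml_core(design, as.list(sigma2))
  if (is.null(core)) -Inf else core$ll
}

#' Fit variance components by average-information REML
#'
#' Maximizes the restricted log-likelihood over the component variances by
#' average-information updates, falling back to expectation-maximization
#' steps (with step halving) whenever an AI proposal leaves the parameter
#' space or decreases the objective, so the restricted log-likelihood is
#' non-decreasing across accepted iterations.  Components are constrained
#' nonnegative: estimates hitting the floor (`1e-8` of the phenotypic
#' variance) are pinned there and flagged as boundary estimates.
#'
#' @param design `mixed_design` (see [assemble_design()]).
#' @param init optional named starting values; default splits the sample
#'   variance of `y` equally across components.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   change in restricted log-likelihood (relative component change below
#'   `1e-4` is also required).
#' @return list of class `reml_fit`: `sigma2`, `fractions`, `h2`, `H2`,
#'   `rB` (when the variant's components allow them), `b_hat`, `effects`
#'   (BLUPs from [solve_blups()]), `loglik`, `n_components`, `converged`,
#'   `iterations`, `boundary`, `trace`.
#' @export
reml_fit <- function(design, init = NULL, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(design, "mixed_design"))
  y <- design$y
  N <- length(y)
  comps <- c(names(design$K), "e")
  if (N < ncol(design$X) + 2) stop("too few records to estimate variances")
  vt <- stats::var(y)
  floor_v <- 1e-8 * vt
  sigma <- if (is.null(init)) {
    stats::setNames(rep(vt / length(comps), length(comps)), comps)
  } else {
    stopifnot(all(comps %in% names(init)))
    pmax(init[comps], floor_v)
  }
  core <- .reml_core(design, as.list(sigma))
  if (is.null(core)) stop("initial covariance matrix not positive definite")
  ll <- core$ll
  trace <- list(c(iter = 0, ll = ll, sigma))
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    nk <- length(comps)
    score <- numeric(nk)
    Q <- matrix(0, N, nk)
    trPK <- numeric(nk)
    yPKPy <- numeric(nk)
    for (j in seq_len(nk)) {
      if (comps[j] == "e") {
        trPK[j] <- sum(diag(core$P))
        Q[, j] <- core$Py
      } else {
        Kj <- design$K[[comps[j]]]
        trPK[j] <- sum(core$P * Kj)
        Q[, j] <- Kj %*% core$Py
      }
      yPKPy[j] <- sum(core$Py * Q[, j])
      score[j] <- -0.5 * (trPK[j] - yPKPy[j])
    }
    AI <- 0.5 * crossprod(Q, core$P %*% Q)
    # active set: components pinned at the floor with downhill gradient
    # are held fixed so they do not derail the AI solve
    free <- !(sigma <= floor_v * (1 + 1e-6) & score < 0)
    delta_ai <- NULL
    if (any(free)) {
      d_free <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                         error = function(e) NULL)
      if (!is.null(d_free)) {
        delta_ai <- numeric(nk)
        delta_ai[free] <- d_free
      }
    }
    delta_em <- ifelse(free, sigma^2 / N * (yPKPy - trPK), 0)
    accepted <- FALSE
    for (delta in Filter(Negate(is.null), list(delta_ai, delta_em))) {
      step <- 1
      for (h in 1:20) {
        prop <- pmax(sigma + step * delta, floor_v)
        core_new <- .reml_core(design, as.list(prop))
        if (!is.null(core_new) && is.finite(core_new$ll) &&
            core_new$ll >= ll - 1e-10) {
          rel_change <- max(abs(prop - sigma) / pmax(sigma, floor_v))
          improve <- core_new$ll - ll
          sigma <- prop
          core <- core_new
          ll <- core$ll
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (accepted) break
    }
    trace[[length(trace) + 1]] <- c(iter = it, ll = ll, sigma)
    if (!accepted) { converged <- TRUE; break }
    if (improve < tol && rel_change < 1e-4) { converged <- TRUE; break }
  }
  boundary <- sigma <= floor_v * (1 + 1e-6)
  b_hat <- drop(core$XtVXinv %*% crossprod(design$X, core$Vinv %*% y))
  names(b_hat) <- colnames(design$X)
  fractions <- sigma / sum(sigma)
  fit <- structure(list(
    sigma2 = sigma, fractions = fractions,
    h2 = tryCatch(heritabilities(sigma)[["h2"]], error = function(e) NA_real_),
    H2 = tryCatch(heritabilities(sigma)[["H2"]], error = function(e) NA_real_),
    rB = tryCatch(genotypic_correlation(sigma), error = function(e) NA_real_),
    b_hat = b_hat, loglik = ll, n_components = length(comps),
    converged = converged, iterations = it, boundary = boundary,
    trace = do.call(rbind, trace), design = design), class = "reml_fit")
  fit$effects <- tryCatch(solve_blups(design, sigma, core = core),
                          error = function(e) NULL)
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: logL = %.4f after %d iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  tab <- rbind(variance = x$sigma2, fraction = x$fractions)
  print(round(tab, 4))
  cat(sprintf("h2 = %.3f  H2 = %.3f  rB = %.3f\n", x$h2, x$H2, x$rB))
  invisible(x)
}

#' BLUPs of genetic effects from a fitted design
#'
#' Solves the random effects by covariance projection:
#' `u_hat = sigma2_u Cov(u, y) P y`, giving per-individual additive,
#' dominance and epistatic effects over all kernel individuals (including
#' ones without records, which is how validation individuals are
#' predicted), per-site interaction deviations, and the total genetic
#' value `gv = a + d + i` over whichever of those the design carries.
#'
#' @param design `mixed_design` carrying `kernels_full` and index maps.
#' @param sigma2 named component variances.
#' @param core internal projection pieces; recomputed if missing.
#' @return list with one named vector per main component, `t` (list of
#'   site x individual interaction matrices) and `gv`.
#' @export
solve_blups <- function(design, sigma2, core = NULL) {
  if (is.null(design$kernels_full) || is.null(design$ind_idx))
    stop("design lacks individual-level kernels; BLUP back-mapping undefined")
  if (is.null(core)) core <- .reml_core(design, as.list(sigma2))
  if (is.null(core)) stop("covariance matrix not positive definite")
  ids <- design$ids
  n <- length(ids)
  agg <- function(sel) {
    out <- numeric(n)
    tab <- tapply(core$Py[sel], design$ind_idx[sel], sum)
    out[as.integer(names(tab))] <- tab
    out
  }
  all_rows <- rep(TRUE, length(design$y))
  effects <- list()
  main_map <- c(a = "a", d = "d", aa = "i")
  for (mn in names(main_map)) {
    if (!mn %in% names(design$K)) next
    u <- sigma2[[mn]] * drop(design$kernels_full[[mn]] %*% agg(all_rows))
    effects[[main_map[[mn]]]] <- stats::setNames(u, ids)
  }
  t_list <- list()
  for (mn in c("a", "d", "aa")) {
    cc <- paste0(mn, "s")
    if (!cc %in% names(design$K)) next
    tm <- matrix(0, length(design$sites), n,
                 dimnames = list(design$sites, ids))
    for (s in seq_along(design$sites)) {
      tm[s, ] <- sigma2[[cc]] *
        drop(design$kernels_full[[mn]] %*% agg(design$site_idx == s))
    }
    t_list[[cc]] <- tm
  }
  if (length(t_list)) effects$t <- t_list
  gv <- numeric(n)
  for (mn in c("a", "d", "i")) if (!is.null(effects[[mn]])) gv <- gv + effects[[mn]]
  effects$gv <- stats::setNames(gv, ids)
  effects
}

#' Narrow- and broad-sense heritability from variance components
#'
#' `h2 = sigma2_a / total` and `H2 = (sigma2_a + sigma2_d + sigma2_aa) /
#' total`, the total being the sum of all components in the model.
#' Accepts variances or percentages (ratios are scale free).
#'
#' @param sigma2 named nonnegative vector with at least `a` and `e`;
#'   `d, aa, as, ds, aas` used when present.
#' @return named vector `c(h2, H2)`.
#' @export
heritabilities <- function(sigma2) {
  sigma2 <- .as_components(sigma2)
  total <- sum(sigma2)
  if (total <= 0) stop("total variance is zero")
  gen <- sum(sigma2[intersect(c("a", "d", "aa"), names(sigma2))])
  c(h2 = unname(sigma2["a"] / total), H2 = gen / total)
}

#' Between-site genotypic correlation
#'
#' Ratio of main genetic variance to main-plus-interaction genetic
#' variance: `rB = sG2 / (sG2 + sGxE2)` with
#' `sG2 = sigma2_a + sigma2_d + sigma2_aa` and
#' `sGxE2 = sigma2_as + sigma2_ds + sigma2_aas`.
#'
#' @inheritParams heritabilities
#' @return scalar in \[0, 1\] for nonnegative components.
#' @export
genotypic_correlation <- function(sigma2) {
  sigma2 <- .as_components(sigma2)
  sg <- sum(sigma2[intersect(c("a", "d", "aa"), names(sigma2))])
  sgxe <- sum(sigma2[intersect(c("as", "ds", "aas"), names(sigma2))])
  if (sg + sgxe <= 0) stop("no genetic variance: rB undefined")
  unname(sg / (sg + sgxe))
}

.as_components <- function(sigma2) {
  if (inherits(sigma2, "reml_fit")) sigma2 <- sigma2$sigma2
  stopifnot(is.numeric(sigma2), !is.null(names(sigma2)))
  if (!"a" %in% names(sigma2)) stop("components must include 'a'")
  if (any(sigma2 < 0)) stop("negative variance component")
  sigma2
}

#' Likelihood-ratio test of nested variance models
#'
#' `2 (logL_full - logL_reduced)` referred to a plain chi-square with
#' degrees of freedom equal to the difference in the number of variance
#' components (4 for the full three-kernel model against the additive
#' model).  Because the null pins variances to the boundary, the plain
#' chi-square reference is conservative; an equal-mixture
#' `chi2_df / chi2_{df-1}` p-value is reported alongside as a diagnostic.
#'
#' @param fit_reduced,fit_full `reml_fit` objects on identical data with
#'   nested component sets.
#' @return list `statistic`, `df`, `p_value` (plain chi-square) and
#'   `p_mixture`.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "reml_fit"), inherits(fit_full, "reml_fit"))
  if (!all(names(fit_reduced$sigma2) %in% names(fit_full$sigma2)))
    stop("models are not nested")
  df <- fit_full$n_components - fit_reduced$n_components
  if (df <= 0) stop("full model must have more components than reduced")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  p_mix <- 0.5 * stats::pchisq(stat, df, lower.tail = FALSE) +
    0.5 * stats::pchisq(stat, max(df - 1, 1e-8), lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, p_mixture = p_mix)
}

#' Cross-trait summaries of a variance-component table
#'
#' Given per-trait components (columns = traits, rows named
#' `a, d, aa, as, ds, aas, e`, as variances or percentages), reports the
#' across-trait mean additive, dominance and epistatic fractions (percent
#' of phenotypic variance) and the per-trait nonadditive-to-additive ratio
#' `(sigma2_d + sigma2_aa) / sigma2_a` with its mean.
#'
#' @param varcomp numeric matrix of components by trait.
#' @return list `mean_fraction_pct` (named length 3), `ratio_nonadd_add`
#'   (per trait; `NA` where additive variance is zero) and `mean_ratio`.
#' @export
derived_varcomp_stats <- function(varcomp) {
  stopifnot(is.matrix(varcomp),
            all(c("a", "d", "aa") %in% rownames(varcomp)))
  frac <- sweep(varcomp, 2, colSums(varcomp), "/")
  mean_frac <- 100 * rowMeans(frac[c("a", "d", "aa"), , drop = FALSE])
  ratio <- ifelse(varcomp["a", ] > 0,
                  (varcomp["d", ] + varcomp["aa", ]) / varcomp["a", ],
                  NA_real_)
  list(mean_fraction_pct = mean_frac,
       ratio_nonadd_add = ratio,
       mean_ratio = mean(ratio, na.rm = TRUE))
}

#' Reference variance decomposition for six apple fruit-quality traits
#'
#' Published variance-component estimates (percent of phenotypic variance,
#' three-kernel model with site interactions) from a clonally replicated
#' apple trial of 17 full-sib families at two New Zealand sites: fruit
#' weight (WT), greasiness (GRE), firmness (FF), crispness (CRI),
#' juiciness (JUI) and flavor intensity (FIN).  Used in worked examples
#' and as fixed inputs for the derived-ratio checks.
#'
#' @return 7 x 6 matrix, rows `a, d, aa, as, ds, aas, e`, columns traits.
#' @export
apple_fruit_varcomp <- function() {
  vals <- c(
    51.79, 26.52, 49.63, 23.39, 18.05, 10.67,   # additive
     6.70, 22.86, 19.99, 23.37, 23.78,  0.00,   # dominance
    18.38, 23.64,  9.15, 19.17, 18.58, 23.41,   # additive x additive
     2.31,  1.08,  1.32,  3.38,  0.00,  0.80,   # additive x site
     2.02,  1.72,  4.36,  0.00,  0.00,  0.95,   # dominance x site
     0.00,  8.01,  0.00,  0.00,  4.57,  3.02,   # epistasis x site
    18.80, 16.17, 15.56, 30.70, 35.02, 61.16)   # residual
  matrix(vals, nrow = 7, byrow = TRUE,
         dimnames = list(c("a", "d", "aa", "as", "ds", "aas", "e"),
                         c("WT", "GRE", "FF", "CRI", "JUI", "FIN")))
}
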