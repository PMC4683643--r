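# independent restricted log-likelihood used as an oracle (direct formula,
# no shared code with the package's REML path)
oracle_rll <- function(y, X, Vlist, sigma2) {
  V <- Reduce(`+`, Map(`*`, Vlist, sigma2))
  ld <- determinant(V, logarithm = TRUE)$modulus
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * as.numeric(ld + determinant(XtVX, TRUE)$modulus +
                      t(y) %*% P %*% y)
}

test_that("REML matches the balanced one-way ANOVA closed form", {
  set.seed(14)
  n_g <- 25; r <- 4
  grp <- rep(seq_len(n_g), each = r)
  u <- rnorm(n_g, 0, sqrt(2))
  y <- 10 + u[grp] + rnorm(n_g * r, 0, 1)
  Z <- outer(grp, seq_len(n_g), "==") * 1
  des <- mixed_design(y, matrix(1, n_g * r), K = list(g = tcrossprod(Z)))
  fit <- reml_fit(des, tol = 1e-10)
  ms <- anova(lm(y ~ factor(grp)))$`Mean Sq`
  expect_equal(unname(fit$sigma2["e"]), ms[2], tolerance = 1e-5)
  expect_equal(unname(fit$sigma2["g"]), (ms[1] - ms[2]) / r, tolerance = 1e-4)
})

test_that("REML finds the grid-search optimum on two-kernel problems", {
  set.seed(26)
  for (rep in 1:3) {
    n <- 30
    B <- matrix(rnorm(n * 60), n)
    G <- tcrossprod(scale(B, scale = FALSE)) / 60
    L <- t(chol(G + diag(1e-8, n)))
    y <- 2 + drop(L %*% rnorm(n)) * sqrt(0.7) + rnorm(n, 0, sqrt(0.5))
    X <- matrix(1, n)
    des <- mixed_design(y, X, K = list(g = G))
    fit <- reml_fit(des, tol = 1e-9)
    gridv <- seq(0.01, 3, by = 0.02)
    ll <- outer(gridv, gridv, Vectorize(function(sg, se)
      oracle_rll(y, X, list(G, diag(n)), c(sg, se))))
    best <- arrayInd(which.max(ll), dim(ll))
    expect_equal(unname(fit$sigma2["g"]), gridv[best[1]], tolerance = 0.021)
    expect_equal(unname(fit$sigma2["e"]), gridv[best[2]], tolerance = 0.021)
    expect_gte(fit$loglik, max(ll) - 1e-4)
  }
})

test_that("additive GBLUP equals ridge-regression BLUP with matched penalty", {
  set.seed(33)
  n <- 50; m <- 150
  p <- runif(m, 0.1, 0.9)
  dos <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  g <- geno_matrix(dos)
  Ga <- build_Ga(g)
  d0 <- sum(2 * g$freqs * (1 - g$freqs))
  M <- sweep(g$dosages, 2, 2 * g$freqs)
  s2_marker <- 0.02; s2_e <- 1
  y <- 3 + drop(M %*% rnorm(m, 0, sqrt(s2_marker))) + rnorm(n, 0, sqrt(s2_e))
  X <- matrix(1, n)
  # package route: kernel BLUP at fixed variances
  des <- mixed_design(y, X, K = list(a = Ga$values),
                      kernels_full = list(a = Ga$values),
                      ind_idx = seq_len(n), site_idx = rep(1L, n),
                      ids = rownames(dos), sites = "s1")
  sig <- c(a = s2_marker * d0, e = s2_e)
  gebv <- solve_blups(des, sig)$a
  # oracle route: ridge-regression mixed-model equations on marker effects
  lambda <- s2_e / s2_marker
  lhs <- rbind(cbind(crossprod(X), crossprod(X, M)),
               cbind(crossprod(M, X), crossprod(M) + diag(lambda, m)))
  rhs <- rbind(crossprod(X, y), crossprod(M, y))
  sol <- solve(lhs, rhs)
  pred <- drop(M %*% sol[-1])
  expect_equal(unname(gebv), unname(pred), tolerance = 1e-6)
})

test_that("model nesting and likelihood ascent hold on simulated data", {
  fitA <- small_fit("A")
  fitAD <- small_fit("AD")
  fitADE <- small_fit("ADE")
  expect_gte(fitAD$loglik, fitA$loglik - 1e-5)
  expect_gte(fitADE$loglik, fitAD$loglik - 1e-5)
  for (f in list(fitA, fitAD, fitADE)) {
    expect_true(f$converged)
    expect_true(all(diff(f$trace[, "ll"]) >= -1e-8))
  }
})

test_that("REML is insensitive to starting values", {
  tr <- small_trial()
  des <- assemble_design(small_blues(), small_kern(), "ADE")
  base <- small_fit("ADE")
  vt <- var(des$y)
  starts <- list(
    c(a = 0.8, d = 0.01, aa = 0.01, as = 0.01, ds = 0.01, aas = 0.01, e = 0.2) * vt,
    c(a = 0.05, d = 0.05, aa = 0.6, as = 0.05, ds = 0.05, aas = 0.05, e = 0.2) * vt)
  for (s in starts) {
    alt <- reml_fit(des, init = s)
    expect_equal(alt$loglik, base$loglik, tolerance = 1e-4)
  }
})

test_that("variance components scale as c^2 and ratios are invariant", {
  des <- assemble_design(small_blues(), small_kern(), "ADE")
  f1 <- small_fit("ADE")
  des2 <- des; des2$y <- des$y * 3
  f2 <- reml_fit(des2)
  expect_equal(unname(f2$sigma2), unname(f1$sigma2) * 9, tolerance = 1e-2)
  expect_equal(f2$fractions, f1$fractions, tolerance = 1e-3)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-3)
  expect_equal(f2$rB, f1$rB, tolerance = 1e-3)
  expect_equal(unname(cor(f2$effects$gv, f1$effects$gv)), 1, tolerance = 1e-6)
})

test_that("a component estimated at zero has vanishing BLUPs", {
  fit <- small_fit("ADE")
  zeroed <- names(which(fit$boundary))
  skip_if(length(zeroed) == 0, "no boundary component in this fixture")
  main <- c(a = "a", d = "d", aa = "i")
  for (z in intersect(zeroed, names(main))) {
    expect_lt(max(abs(fit$effects[[main[[z]]]])), 1e-5 * sd(fit$design$y))
  }
})

test_that("design assembly stacks site-major with Kronecker structure", {
  G <- matrix(c(1, .5, .2, .5, 1, .1, .2, .1, 1), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  kern <- list(Ga = rel_matrix(G, "additive_genomic"))
  bl <- data.frame(individual_id = rep(c("x", "y", "z"), 2),
                   site = rep(c("s1", "s2"), each = 3), trait = "t",
                   blue = 1:6)
  des <- assemble_design(bl, kern, "A")
  expect_equal(length(des$y), 6)
  expect_equal(names(des$K), c("a", "as"))
  expect_equal(des$K$a, rbind(cbind(G, G), cbind(G, G)), ignore_attr = TRUE)
  expect_equal(des$K$as, rbind(cbind(G, 0 * G), cbind(0 * G, G)),
               ignore_attr = TRUE)
  # masking one individual-site cell drops exactly that row everywhere
  des2 <- assemble_design(bl[-5, ], kern, "A")
  expect_equal(length(des2$y), 5)
  expect_equal(dim(des2$K$a), c(5L, 5L))
  expect_error(assemble_design(transform(bl, individual_id = "w"), kern, "A"),
               "absent from kernels")
})

test_that("heritability ratios reproduce the published six-trait table", {
  vc <- apple_fruit_varcomp()
  h <- apply(vc, 2, heritabilities)
  expect_equal(unname(round(h["h2", ], 2)),
               c(0.52, 0.27, 0.50, 0.23, 0.18, 0.11))
  expect_equal(unname(round(h["H2", ], 2)),
               c(0.77, 0.73, 0.79, 0.66, 0.60, 0.34))
  expect_equal(round(apply(vc, 2, genotypic_correlation), 2),
               c(WT = 0.95, GRE = 0.87, FF = 0.93, CRI = 0.95, JUI = 0.93,
                 FIN = 0.88))
  # degenerate ratios
  expect_equal(unname(heritabilities(c(a = 0, e = 1))), c(0, 0))
  h_add <- heritabilities(c(a = 2, e = 2))
  expect_equal(h_add[["h2"]], h_add[["H2"]])
  expect_equal(genotypic_correlation(c(a = 1, d = 1, aa = 1)), 1)
  expect_error(heritabilities(c(a = 0, e = 0)), "zero")
})

test_that("likelihood-ratio test degrees of freedom and edge cases", {
  fitA <- small_fit("A")
  fitADE <- small_fit("ADE")
  lrt <- likelihood_ratio_test(fitA, fitADE)
  expect_equal(lrt$df, 4)
  expect_gte(lrt$statistic, 0)
  # identical log-likelihoods give statistic 0 and p = 1
  f2 <- fitADE; f2$loglik <- fitA$loglik; f2$n_components <- fitA$n_components + 1
  ident <- likelihood_ratio_test(fitA, f2)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(likelihood_ratio_test(fitADE, fitA), "not nested")
})

test_that("cross-trait summary statistics match the published derivations", {
  st <- derived_varcomp_stats(apple_fruit_varcomp())
  expect_equal(unname(round(st$mean_fraction_pct)), c(30, 16, 19))
  expect_equal(unname(round(st$ratio_nonadd_add[c("WT", "JUI")], 2)),
               c(0.48, 2.35))
  expect_equal(round(st$mean_ratio, 2), 1.53)
  one <- derived_varcomp_stats(matrix(c(2, 0, 0, 0, 0, 0, 1), 7,
                                      dimnames = list(c("a", "d", "aa", "as",
                                                        "ds", "aas", "e"), "t")))
  expect_equal(unname(one$ratio_nonadd_add), 0)
  zero_a <- derived_varcomp_stats(matrix(c(0, 1, 1, 0, 0, 0, 1), 7,
                                         dimnames = list(c("a", "d", "aa", "as",
                                                           "ds", "aas", "e"), "t")))
  expect_true(is.na(zero_a$ratio_nonadd_add))
})

test_that("prediction of true additive merit improves with heritability", {
  accs <- vapply(c(lo = 0.1, hi = 0.6), function(h2) {
    cfg <- sim_config(n_parents = 10, n_families = 8, family_size = 12,
                      n_snps = 400, n_reps = 2, n_years = 1,
                      var_components = c(a = h2, d = 0.05, aa = 0.05, as = 0,
                                         ds = 0, aas = 0, e = 0.9 - h2),
                      seed = 55)
    tr <- simulate_trial(cfg)
    kern <- make_kernels(tr$geno)
    fit <- reml_fit(assemble_design(compute_blues(tr$pheno), kern, "ADE"))
    cor(fit$effects$a, tr$truth$a[names(fit$effects$a)])
  }, numeric(1))
  expect_gt(accs["hi"], accs["lo"])
})
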