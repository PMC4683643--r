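cv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_parents = 10, n_families = 8, family_size = 12,
                        n_snps = 400, n_reps = 2, n_years = 1,
                        var_components = c(a = 0.45, d = 0.1, aa = 0.1,
                                           as = 0, ds = 0, aas = 0, e = 0.35),
                        seed = 61)
      tr <- simulate_trial(cfg)
      kern <- make_kernels(tr$geno)
      bl <- compute_blues(tr$pheno)
      cache <<- list(tr = tr, kern = kern, bl = bl,
                     ref = cv_reference_gv(bl, kern))
    }
    cache
  }
})

test_that("masked records never influence a fold", {
  fx <- cv_fixture()
  fam <- fx$tr$families
  target <- sort(unique(fam))[1]
  clean <- cv_untested(fx$bl, fx$kern, fam, "A", ref_gv = fx$ref)
  poisoned_bl <- fx$bl
  vp <- names(fam)[fam == target]
  poisoned_bl$blue[poisoned_bl$individual_id %in% vp] <- 1e6
  poisoned <- cv_untested(poisoned_bl, fx$kern, fam, "A", ref_gv = fx$ref)
  row_c <- clean[clean$family == target, ]
  row_p <- poisoned[poisoned$family == target, ]
  expect_equal(row_p$accuracy, row_c$accuracy, tolerance = 1e-10)
  expect_equal(row_p$bias, row_c$bias, tolerance = 1e-10)
  # same for the single-site strategy at the masked site
  clean_s <- cv_single_site(fx$bl, fx$kern, fam, "A", "site2",
                            ref_gv = fx$ref)
  poison_s_bl <- fx$bl
  poison_s_bl$blue[poison_s_bl$individual_id %in% vp &
                     poison_s_bl$site == "site2"] <- -1e6
  poisoned_s <- cv_single_site(poison_s_bl, fx$kern, fam, "A", "site2",
                               ref_gv = fx$ref)
  expect_equal(poisoned_s[poisoned_s$family == target, ]$accuracy,
               clean_s[clean_s$family == target, ]$accuracy,
               tolerance = 1e-10)
})

test_that("fold results do not depend on family processing order", {
  fx <- cv_fixture()
  fam <- fx$tr$families
  res1 <- cv_untested(fx$bl, fx$kern, fam, "ADE", ref_gv = fx$ref)
  fam_rev <- rev(fam)
  res2 <- cv_untested(fx$bl, fx$kern, fam_rev, "ADE", ref_gv = fx$ref)
  res2 <- res2[match(res1$family, res2$family), ]
  expect_equal(res2$accuracy, res1$accuracy, tolerance = 1e-8)
})

test_that("folds partition the families and small families are skipped", {
  fx <- cv_fixture()
  fam <- fx$tr$families
  res <- cv_untested(fx$bl, fx$kern, fam, "A", ref_gv = fx$ref)
  expect_setequal(res$family, unique(fam))
  expect_equal(anyDuplicated(res$family), 0)
  fam_small <- fam
  fam_small[names(fam)[fam == "F01"][-(1:2)]] <- "F02"  # F01 left with 2
  expect_warning(res2 <- cv_untested(fx$bl, fx$kern, fam_small, "A",
                                     ref_gv = fx$ref, min_family = 3),
                 "fewer than")
  expect_false("F01" %in% res2$family)
  # single-site: a family absent at the target site is skipped
  bl_gone <- fx$bl[!(fx$bl$individual_id %in% names(fam)[fam == "F03"] &
                       fx$bl$site == "site1"), ]
  expect_warning(res3 <- cv_single_site(bl_gone, fx$kern, fam, "A", "site1",
                                        ref_gv = fx$ref),
                 "F03")
  expect_false("F03" %in% res3$family)
})

test_that("accuracy of a pure-noise trait centers on zero", {
  cfg <- sim_config(n_parents = 10, n_families = 8, family_size = 12,
                    n_snps = 300, n_reps = 2, n_years = 1,
                    var_components = c(a = 0, d = 0, aa = 0, as = 0, ds = 0,
                                       aas = 0, e = 1),
                    seed = 71)
  tr <- simulate_trial(cfg)
  kern <- make_kernels(tr$geno)
  bl <- compute_blues(tr$pheno)
  res <- cv_untested(bl, kern, tr$families, "A")
  expect_lt(abs(mean(res$accuracy, na.rm = TRUE)), 0.35)
})

test_that("prediction accuracy rises with heritability", {
  mean_acc <- vapply(c(lo = 0.1, hi = 0.5), function(h2) {
    cfg <- sim_config(n_parents = 10, n_families = 8, family_size = 12,
                      n_snps = 400, n_reps = 2, n_years = 1,
                      var_components = c(a = h2, d = 0.05, aa = 0.05, as = 0,
                                         ds = 0, aas = 0, e = 0.9 - h2),
                      seed = 81)
    tr <- simulate_trial(cfg)
    kern <- make_kernels(tr$geno)
    bl <- compute_blues(tr$pheno)
    # score against the simulation's true genetic values so the target is
    # not itself shrunken toward the kernels at low heritability
    truth_gv <- tr$truth$a + tr$truth$d + tr$truth$i
    mean(cv_untested(bl, kern, tr$families, "ADE",
                     ref_gv = truth_gv)$accuracy, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean_acc["hi"], mean_acc["lo"])
})

test_that("testing at one site sharply improves over untested validation", {
  fx <- cv_fixture()
  fam <- fx$tr$families
  res_u <- cv_untested(fx$bl, fx$kern, fam, "ADE", ref_gv = fx$ref)
  res_s <- rbind(
    cv_single_site(fx$bl, fx$kern, fam, "ADE", "site1", ref_gv = fx$ref),
    cv_single_site(fx$bl, fx$kern, fam, "ADE", "site2", ref_gv = fx$ref))
  expect_gt(mean(res_s$accuracy), mean(res_u$accuracy))
})

test_that("accuracy correlates behave and degenerate inputs are flagged", {
  fx <- cv_fixture()
  res <- cv_untested(fx$bl, fx$kern, fx$tr$families, "ADE", ref_gv = fx$ref)
  h2 <- c(t = 0.4)
  names(h2) <- unique(res$trait)
  cc <- accuracy_correlates(res, h2 = h2)
  expect_true(is.finite(cc$r_relatedness))
  expect_true(is.na(cc$r_heritability))   # single trait: undefined
  expect_equal(nrow(cc$per_family), length(unique(res$family)))
  # constant accuracies leave the correlation undefined
  const <- res; const$accuracy <- 0.5
  expect_true(is.na(accuracy_correlates(const)$r_relatedness))
})
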