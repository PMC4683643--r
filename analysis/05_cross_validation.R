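#!/usr/bin/env Rscript
# Step 5: leave-one-family-out cross-validation of genomic prediction over
# all six simulated traits.  Strategy 1 treats the validation family as
# untested at both sites (models A and ADE); strategy 2 keeps it at one
# site and predicts the other (model ADE, first trait at both sites).
# Accuracy is the correlation with the all-data BLUP genetic value; bias is
# the regression slope of the latter on the prediction.
suppressMessages(library(clonalGBLUP))

dat <- "results/data"
blues <- read.csv(file.path(dat, "blues.csv"))
kern <- readRDS(file.path(dat, "kernels.rds"))
fits_ade <- readRDS(file.path(dat, "fits_ade.rds"))
fam_tab <- read.csv(file.path(dat, "families.csv"))
families <- setNames(fam_tab$family, fam_tab$individual_id)
traits <- unique(blues$trait)

res <- list()
for (tr in traits) {
  bl <- blues[blues$trait == tr, ]
  ref <- fits_ade[[tr]]$effects$gv
  res[[paste(tr, "A")]] <- cv_untested(bl, kern, families, "A", ref_gv = ref)
  res[[paste(tr, "ADE")]] <- cv_untested(bl, kern, families, "ADE",
                                         ref_gv = ref)
}
bl1 <- blues[blues$trait == traits[1], ]
ref1 <- fits_ade[[traits[1]]]$effects$gv
res$site1 <- cv_single_site(bl1, kern, families, "ADE", "site1", ref_gv = ref1)
res$site2 <- cv_single_site(bl1, kern, families, "ADE", "site2", ref_gv = ref1)
res <- do.call(rbind, res)
rownames(res) <- NULL
write.csv(res, "results/cv_folds.csv", row.names = FALSE)

cat("== mean accuracy and bias by trait, strategy and model ==\n")
agg <- aggregate(res[c("accuracy", "bias")],
                 by = res[c("trait", "strategy", "variant")], mean,
                 na.rm = TRUE)
print(agg[order(agg$strategy, agg$variant, agg$trait), ], digits = 2)

h2 <- vapply(fits_ade, function(f) f$h2, numeric(1))
cc <- accuracy_correlates(res[res$strategy == "untested_both_sites" &
                                res$variant == "ADE", ], h2 = h2)
cat(sprintf("\ncorrelation of family accuracy with TP-VP relatedness: %.2f\n",
            cc$r_relatedness))
cat(sprintf("correlation of trait accuracy with estimated h2: %.2f\n",
            cc$r_heritability))
write.csv(cc$per_family, "results/cv_family_summary.csv", row.names = FALSE)
write.csv(cc$per_trait, "results/cv_trait_summary.csv", row.names = FALSE)
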