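#!/usr/bin/env Rscript
# Step 3: stage-one adjusted phenotypes -- one BLUE per individual per site,
# removing year and clonal-replicate effects, plus per-site trait summaries.
suppressMessages(library(clonalGBLUP))

dat <- "results/data"
pheno <- read_phenotypes(file.path(dat, "phenotypes.csv"))

summ <- site_trait_summary(pheno)
print(summ, digits = 3)
write.csv(summ, "results/site_trait_summary.csv", row.names = FALSE)

blues <- compute_blues(pheno)
write.csv(blues, file.path(dat, "blues.csv"), row.names = FALSE)
cat(sprintf("%d BLUEs written (%d individuals x %d sites)\n", nrow(blues),
            length(unique(blues$individual_id)),
            length(unique(blues$site))))
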