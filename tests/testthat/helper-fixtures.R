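# shared fixtures, built once per test run
.fixtures <- new.env()

# a modest two-site clonal trial with the default (mixed) architecture
small_trial <- function() {
  if (is.null(.fixtures$tr)) {
    cfg <- sim_config(n_parents = 10, n_families = 8, family_size = 12,
                      n_snps = 400, n_reps = 2, n_years = 2, seed = 11)
    .fixtures$tr <- simulate_trial(cfg)
  }
  .fixtures$tr
}

make_kernels <- function(geno, freqs = NULL) {
  Ga <- build_Ga(geno, freqs = freqs)
  list(Ga = condition_kernel(Ga),
       Gd = condition_kernel(build_Gd(geno, freqs = freqs)),
       Gaa = condition_kernel(build_Gaa(Ga)))
}

small_fit <- function(variant = "ADE") {
  key <- paste0("fit_", variant)
  if (is.null(.fixtures[[key]])) {
    tr <- small_trial()
    if (is.null(.fixtures$kern)) .fixtures$kern <- make_kernels(tr$geno)
    if (is.null(.fixtures$blues)) .fixtures$blues <- compute_blues(tr$pheno)
    .fixtures[[key]] <- reml_fit(
      assemble_design(.fixtures$blues, .fixtures$kern, variant))
  }
  .fixtures[[key]]
}

small_blues <- function() { small_fit("ADE"); .fixtures$blues }
small_kern <- function() { small_fit("ADE"); .fixtures$kern }

# simple genotype matrix from explicit dosages
gm <- function(dosages, ids = NULL, snps = NULL) {
  d <- as.matrix(dosages)
  rownames(d) <- if (is.null(ids)) paste0("i", seq_len(nrow(d))) else ids
  colnames(d) <- if (is.null(snps)) paste0("s", seq_len(ncol(d))) else snps
  geno_matrix(d)
}
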