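#' Genotype matrix container
#'
#' Wraps an n x m allele-dosage matrix (individuals x SNPs, values 0/1/2 or
#' NA for missing calls) together with per-SNP allele frequencies of the
#' counted allele, estimated from the non-missing dosages.
#'
#' @param dosages numeric matrix with individual ids as rownames and SNP ids
#'   as colnames; entries must be 0, 1, 2 or NA.
#' @return an object of class `geno_matrix` with elements `dosages` and
#'   `freqs` (frequency of the counted allele per SNP).
#' @export
geno_matrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate individual ids in genotype matrix")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate SNP ids in genotype matrix")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(dosages)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage at row '%s', column '%s' (must be 0/1/2 or NA)",
                 rownames(dosages)[idx[1]], colnames(dosages)[idx[2]]))
  }
  structure(list(dosages = dosages, freqs = .col_freqs(dosages)),
            class = "geno_matrix")
}

.col_freqs <- function(dosages) colMeans(dosages, na.rm = TRUE) / 2

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Read / write a genotype matrix
#'
#' Wide CSV dialect: one row per individual, first column `id`, remaining
#' columns one per SNP holding dosages 0/1/2; empty cells or `NA` denote
#' missing calls.  Any other token is a parse error naming the offending
#' row and column.
#'
#' @param path file path.
#' @return `read_genotypes` returns a [geno_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(tab)[1] != "id") stop("first column of genotype file must be 'id'")
  ids <- tab$id
  raw <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = list(ids, colnames(raw))))
  missing_tok <- is.na(raw) | raw %in% c("", "NA", "na", ".")
  bad <- which((is.na(num) & !missing_tok) |
                 (!is.na(num) & !num %in% c(0, 1, 2)), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("unparseable dosage '%s' at row '%s', column '%s'",
                 raw[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(raw)[bad[1, 2]]))
  }
  geno_matrix(num)
}

#' @rdname read_genotypes
#' @param geno a [geno_matrix()].
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  out <- data.frame(id = rownames(geno$dosages), geno$dosages,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Marker quality control
#'
#' Drops SNPs with missing-call rate above `max_missing`, then SNPs with
#' minor allele frequency below `maf_min` (computed from the calls that
#' survive the missingness filter).  The removal counts per criterion are
#' attached as attribute `qc_report`.
#'
#' @param geno a [geno_matrix()].
#' @param maf_min minimum minor allele frequency retained (default 0.05).
#' @param max_missing maximum fraction of missing calls retained (default 0.05).
#' @return filtered [geno_matrix()] with a `qc_report` attribute.
#' @export
qc_markers <- function(geno, maf_min = 0.05, max_missing = 0.05) {
  stopifnot(inherits(geno, "geno_matrix"),
            maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  d <- geno$dosages
  miss_rate <- colMeans(is.na(d))
  drop_miss <- miss_rate > max_missing
  d <- d[, !drop_miss, drop = FALSE]
  p <- .col_freqs(d)
  maf <- pmin(p, 1 - p)
  drop_maf <- maf < maf_min
  d <- d[, !drop_maf, drop = FALSE]
  if (ncol(d) == 0) warning("no SNPs left after QC")
  out <- geno_matrix(d)
  attr(out, "qc_report") <- c(n_input = ncol(geno$dosages),
                              removed_missing = sum(drop_miss),
                              removed_maf = sum(drop_maf),
                              n_retained = ncol(d))
  out
}

#' Mean imputation of missing genotypes
#'
#' Replaces each missing dosage by twice the observed allele frequency of
#' its SNP (the mean dosage), the standard deterministic fill-in for
#' genomic-relationship-matrix construction.
#'
#' @param geno a [geno_matrix()].
#' @return a complete [geno_matrix()]; per-SNP mean dosage is preserved.
#' @export
impute_mean <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing))
    stop("cannot impute all-missing SNP(s): ",
         paste(colnames(d)[all_missing], collapse = ", "))
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx)) d[na_idx] <- 2 * geno$freqs[na_idx[, 2]]
  geno$dosages <- d
  geno$freqs <- .col_freqs(d)
  geno
}

#' Read / write phenotype records
#'
#' Long CSV dialect: columns `individual_id`, `site`, `year`, `replicate`,
#' `trait`, `value`, one row per clonal replicate per year per trait.
#'
#' @param path file path.
#' @param sites optional character vector of admissible site labels; records
#'   at other sites are an error.
#' @return data frame of typed phenotype records.
#' @export
read_phenotypes <- function(path, sites = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  validate_phenotypes(tab, sites = sites)
}

#' @rdname read_phenotypes
#' @param pheno phenotype record data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
validate_phenotypes <- function(pheno, sites = NULL) {
  need <- c("individual_id", "site", "year", "replicate", "trait", "value")
  missing_cols <- setdiff(need, names(pheno))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  pheno$individual_id <- as.character(pheno$individual_id)
  pheno$site <- as.character(pheno$site)
  pheno$value <- as.numeric(pheno$value)
  if (!is.null(sites)) {
    bad <- setdiff(unique(pheno$site), sites)
    if (length(bad)) stop("unknown site label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(pheno$value)))
    stop("non-finite phenotype value(s)")
  key <- do.call(paste, c(pheno[c("individual_id", "site", "year",
                                  "replicate", "trait")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (individual, site, year, replicate, trait) record(s)")
  pheno
}

#' Read, validate and topologically sort a pedigree
#'
#' Three-column CSV: `individual_id`, `sire_id`, `dam_id`; empty or `NA`
#' parent fields mean unknown.  The result is sorted so every parent
#' precedes its offspring; cycles are an error.
#'
#' @param path file path.
#' @return data frame of class `pedigree_table`, topologically sorted.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("individual_id", "sire_id", "dam_id")
  if (!all(need %in% names(tab)))
    stop("pedigree file needs columns: ", paste(need, collapse = ", "))
  sort_pedigree(tab[need])
}

#' @rdname read_pedigree
#' @param ped pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_pedigree
#' @export
sort_pedigree <- function(ped) {
  ped$individual_id <- as.character(ped$individual_id)
  ped$sire_id <- .na_parent(ped$sire_id)
  ped$dam_id <- .na_parent(ped$dam_id)
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual in pedigree")
  # Kahn-style topological sort; leftover rows imply a cycle
  placed <- character(0)
  remaining <- ped
  order_rows <- integer(0)
  repeat {
    ready <- with(remaining,
                  (is.na(sire_id) | sire_id %in% placed |
                     !sire_id %in% ped$individual_id) &
                    (is.na(dam_id) | dam_id %in% placed |
                       !dam_id %in% ped$individual_id))
    if (!any(ready)) break
    idx <- match(remaining$individual_id[ready], ped$individual_id)
    order_rows <- c(order_rows, idx)
    placed <- c(placed, remaining$individual_id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
    if (nrow(remaining) == 0) break
  }
  if (nrow(remaining) > 0)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(remaining$individual_id, 5), collapse = ", "))
  out <- ped[order_rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}

.na_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "NA", "0", ".")] <- NA_character_
  x
}
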