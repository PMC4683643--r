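#' Relationship-matrix container
#'
#' @param values symmetric n x n numeric matrix with individual ids as
#'   dimnames.
#' @param kind one of `"additive_genomic"`, `"dominance_genomic"`,
#'   `"epistatic_genomic"`, `"additive_pedigree"`, `"dominance_pedigree"`.
#' @param bending_applied whether diagonal inflation was applied to restore
#'   positive semi-definiteness.
#' @return object of class `rel_matrix`.
#' @export
rel_matrix <- function(values,
                       kind = c("additive_genomic", "dominance_genomic",
                                "epistatic_genomic", "additive_pedigree",
                                "dominance_pedigree"),
                       bending_applied = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("relationship matrix must be symmetric")
  values <- (values + t(values)) / 2
  structure(list(values = values, kind = kind,
                 bending_applied = bending_applied),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix [%s]: %d x %d, mean diag %.3f, mean off-diag %.3f%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(diag(x$values)), .offdiag_mean(x$values),
              if (x$bending_applied) " (bent)" else ""))
  invisible(x)
}

.offdiag_mean <- function(v) {
  n <- nrow(v)
  if (n < 2) return(NA_real_)
  (sum(v) - sum(diag(v))) / (n * (n - 1))
}

.check_complete <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (anyNA(geno$dosages))
    stop("genotype matrix has missing dosages; run impute_mean() first")
}

#' Additive genomic relationship matrix (VanRaden scaling)
#'
#' Centers each SNP's dosage at twice its allele frequency and scales the
#' cross-product by the sum of 2 p q over SNPs:
#' `G_a = M M' / sum(2 p q)`.
#'
#' @param geno complete [geno_matrix()].
#' @param freqs optional per-SNP frequencies of the counted allele used for
#'   centering and scaling; defaults to the frequencies observed in `geno`
#'   (base-population frequencies can be supplied when known, e.g. in
#'   simulation).
#' @return [rel_matrix()] of kind `additive_genomic`.
#' @export
build_Ga <- function(geno, freqs = NULL) {
  .check_complete(geno)
  p <- if (is.null(freqs)) geno$freqs else freqs
  stopifnot(length(p) == ncol(geno$dosages))
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic: sum(2pq) is zero, G_a undefined")
  M <- sweep(geno$dosages, 2, 2 * p)
  rel_matrix(tcrossprod(M) / denom, "additive_genomic")
}

#' Dominance genomic relationship matrix
#'
#' Heterozygosity coding per SNP: `1 - 2pq` for heterozygotes and `-2pq`
#' for homozygotes; `G_d = H H' / sum(2pq (1 - 2pq))`.
#'
#' @inheritParams build_Ga
#' @return [rel_matrix()] of kind `dominance_genomic`.
#' @export
build_Gd <- function(geno, freqs = NULL) {
  .check_complete(geno)
  p <- if (is.null(freqs)) geno$freqs else freqs
  stopifnot(length(p) == ncol(geno$dosages))
  tpq <- 2 * p * (1 - p)
  denom <- sum(tpq * (1 - tpq))
  if (denom <= 0)
    stop("dominance scaling sum(2pq(1-2pq)) is zero, G_d undefined")
  het <- abs(geno$dosages - 1) < 1e-9
  H <- sweep(ifelse(het, 1, 0), 2, tpq)
  rel_matrix(tcrossprod(H) / denom, "dominance_genomic")
}

#' Additive-by-additive epistatic relationship matrix
#'
#' Hadamard (element-wise) square of the additive genomic matrix.
#'
#' @param Ga [rel_matrix()] of kind `additive_genomic`.
#' @return [rel_matrix()] of kind `epistatic_genomic`.
#' @export
build_Gaa <- function(Ga) {
  stopifnot(inherits(Ga, "rel_matrix"))
  if (Ga$kind != "additive_genomic")
    stop("build_Gaa expects an additive_genomic kernel, got ", Ga$kind)
  rel_matrix(Ga$values * Ga$values, "epistatic_genomic")
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' `A_ii = 1 + A(sire,dam)/2`; `A_ij = (A(j,sire_i) + A(j,dam_i))/2` with
#' unknown parents contributing zero.  Requires a topologically sorted
#' pedigree (see [sort_pedigree()]).
#'
#' @param ped `pedigree_table`.
#' @return [rel_matrix()] of kind `additive_pedigree`.
#' @export
build_A_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree_table")) ped <- sort_pedigree(ped)
  ids <- ped$individual_id
  n <- length(ids)
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (!is.na(s)) row <- row + A[j, s] / 2
      if (!is.na(d)) row <- row + A[j, d] / 2
      A[j, i] <- A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  rel_matrix(A, "additive_pedigree")
}

#' Pedigree dominance relationship matrix
#'
#' `D_ij = (A(s_i,s_j) A(d_i,d_j) + A(s_i,d_j) A(d_i,s_j)) / 4` for i != j,
#' with unknown-parent relationships taken as zero, and `D_ii = 1`
#' (non-inbred simplification).
#'
#' @param ped `pedigree_table`.
#' @param A optional precomputed [build_A_pedigree()] result.
#' @return [rel_matrix()] of kind `dominance_pedigree`.
#' @export
build_D_pedigree <- function(ped, A = NULL) {
  if (!inherits(ped, "pedigree_table")) ped <- sort_pedigree(ped)
  if (is.null(A)) A <- build_A_pedigree(ped)
  Av <- A$values
  ids <- ped$individual_id
  n <- length(ids)
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  rel <- function(i, j) {
    if (is.na(i) || is.na(j)) 0 else Av[i, j]
  }
  D <- diag(1, n)
  dimnames(D) <- list(ids, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      D[i, j] <- D[j, i] <-
        (rel(si[i], si[j]) * rel(di[i], di[j]) +
           rel(si[i], di[j]) * rel(di[i], si[j])) / 4
    }
  }
  rel_matrix(D, "dominance_pedigree")
}

#' Condition a kernel to positive semi-definiteness
#'
#' If the smallest eigenvalue is below zero, inflates the diagonal by
#' `|lambda_min| + epsilon` ("bending") and flags the result; positive
#' semi-definite input is returned unchanged.
#'
#' @param K [rel_matrix()].
#' @param epsilon margin added beyond the most negative eigenvalue.
#' @return conditioned [rel_matrix()].
#' @export
condition_kernel <- function(K, epsilon = 1e-8) {
  stopifnot(inherits(K, "rel_matrix"))
  lam_min <- min(eigen(K$values, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min >= 0) return(K)
  K$values <- K$values + diag(abs(lam_min) + epsilon, nrow(K$values))
  K$bending_applied <- TRUE
  K
}

#' Relatedness summary of a kernel
#'
#' Off-diagonal mean and quantiles overall and, when family labels are
#' given, within and between recorded families.
#'
#' @param K [rel_matrix()].
#' @param families optional named character vector mapping individual ids to
#'   family labels.
#' @return list with `overall` statistics and optional `within_family` /
#'   `between_family` tables.
#' @export
relatedness_summary <- function(K, families = NULL) {
  stopifnot(inherits(K, "rel_matrix"))
  v <- K$values
  n <- nrow(v)
  if (n < 2) stop("relatedness summary needs at least two individuals")
  off <- v[lower.tri(v)]
  out <- list(overall = c(
    mean_offdiag = mean(off),
    mean_incl_diag = mean(v),
    mean_diag = mean(diag(v)),
    q05 = unname(stats::quantile(off, 0.05)),
    q50 = unname(stats::quantile(off, 0.50)),
    q95 = unname(stats::quantile(off, 0.95))))
  if (!is.null(families)) {
    fam <- families[rownames(v)]
    fi <- matrix(fam, n, n)
    same <- fi == t(fi)
    lt <- lower.tri(v)
    out$within_family_mean <- mean(v[lt & same])
    out$between_family_mean <- mean(v[lt & !same])
    labs <- sort(unique(fam))
    out$within_family <- vapply(labs, function(f) {
      sel <- fam == f
      if (sum(sel) < 2) return(NA_real_)
      .offdiag_mean(v[sel, sel, drop = FALSE])
    }, numeric(1))
  }
  out
}

#' Principal components of the genotype matrix
#'
#' Eigendecomposition of the covariance of frequency-centered dosages
#' (equivalently of the additive genomic kernel), returning the leading
#' coordinate vectors and their variance-explained fractions.
#'
#' @param geno complete [geno_matrix()].
#' @param k number of components (default 2).
#' @return list with `coords` (n x k) and `var_explained` (length k).
#' @export
pca_genotypes <- function(geno, k = 2) {
  .check_complete(geno)
  n <- nrow(geno$dosages)
  if (n < 2) stop("PCA needs at least two individuals")
  M <- sweep(geno$dosages, 2, 2 * geno$freqs)
  G <- tcrossprod(M)
  ev <- eigen(G, symmetric = TRUE)
  k <- min(k, n - 1)
  lam <- pmax(ev$values, 0)
  coords <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  rownames(coords) <- rownames(geno$dosages)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, var_explained = lam[seq_len(k)] / sum(lam))
}
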