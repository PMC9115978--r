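#' Build a genomic relationship matrix
#'
#' GCTA-style variance-standardised estimator with per-SNP standardisation:
#' `A_jk = (1/N_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over SNPs non-missing in both samples, where `p_i` is the cohort allele_b
#' frequency and `N_jk` the per-pair SNP count. Monomorphic or undefined
#' variants are excluded with a warning.
#'
#' @param dataset A QC'd [genotype_dataset()].
#' @return A `grm` object: list with `A` (n_i x n_i symmetric matrix),
#'   `n_snps` (per-pair counts) and `sample_id`.
#' @export
build_grm <- function(dataset) {
  g <- dataset$calls
  n_obs <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / pmax(2 * n_obs, 1)
  usable <- n_obs > 0 & p > 0 & p < 1
  if (any(!usable)) {
    warning(sum(!usable), " monomorphic or all-missing variant(s) excluded from GRM")
    g <- g[, usable, drop = FALSE]
    p <- p[usable]
  }
  z <- sweep(g, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)
  n_jk <- tcrossprod(obs * 1)
  if (any(n_jk == 0))
    stop("sample pair with zero jointly genotyped SNPs")
  A <- num / n_jk
  if (!all(is.finite(A))) stop("non-finite GRM entries")
  structure(list(A = A, n_snps = n_jk,
                 sample_id = dataset$samples$sample_id),
            class = "grm")
}

#' Principal component analysis of a GRM
#'
#' Top-k eigenpairs with eigenvalues in non-increasing order; sample scores
#' are eigenvectors scaled by the square root of their (non-negative part
#' of the) eigenvalue. Sign convention: within each component the loading of
#' largest magnitude is positive, so output is reproducible across runs and
#' platforms.
#'
#' @param grm A `grm` from [build_grm()], or a symmetric numeric matrix.
#' @param k Number of components (< number of samples).
#' @return List with `eigenvalues` (length k) and `scores`
#'   (n_i x k matrix, rownames = sample ids when available).
#' @export
grm_pca <- function(grm, k = 3) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  ids <- if (inherits(grm, "grm")) grm$sample_id else rownames(A)
  if (!all(is.finite(A))) stop("non-finite GRM entries")
  if (k >= nrow(A)) stop("k must be smaller than the number of samples")
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- eig$values[seq_len(k)]
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2, sqrt(pmax(vals, 0)), "*")
  rownames(scores) <- ids
  colnames(scores) <- paste0("PC", seq_len(k))
  list(eigenvalues = vals, scores = scores)
}

#' Write a GRM in GCTA-compatible text triplet form
#'
#' Lower-triangle rows `(id1_index, id2_index, N_jk, A_jk)` plus an id list
#' at `<prefix>.grm.id`.
#'
#' @param grm A `grm`.
#' @param prefix Output prefix; writes `<prefix>.grm.txt` and
#'   `<prefix>.grm.id`.
#' @return Invisibly, the file paths.
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$A)
  idx <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(id1 = idx[, 1], id2 = idx[, 2],
                   n_snps = grm$n_snps[idx], a = grm$A[idx])
  data.table::fwrite(df, paste0(prefix, ".grm.txt"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(data.frame(fid = grm$sample_id, iid = grm$sample_id),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     col.names = FALSE)
  invisible(paste0(prefix, c(".grm.txt", ".grm.id")))
}
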