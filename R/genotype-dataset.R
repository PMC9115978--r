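#' Construct a genotype dataset
#'
#' The central container of the pipeline: an `n_i x n_s` matrix of diploid
#' genotype codes for autosomal biallelic markers, together with a variant map
#' and per-sample metadata. Codes count copies of `allele_b` (0, 1, 2) with
#' `NA` for missing calls.
#'
#' @param calls Integer matrix, samples in rows, variants in columns. Entries
#'   must be 0, 1, 2 or `NA`.
#' @param variants `data.frame` with columns `id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`. Positions are 1-based base pairs. Variants are
#'   reordered by `(chrom, pos_bp)`; within a chromosome positions must be
#'   unique.
#' @param samples `data.frame` with columns `sample_id`, `breed` and
#'   optionally `group`. `sample_id` must be unique.
#'
#' @return An object of class `genotype_dataset` with elements `calls`,
#'   `variants`, `samples`, `n_i` (individuals) and `n_s` (variants).
#' @export
genotype_dataset <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  need_v <- c("id", "chrom", "pos_bp", "allele_a", "allele_b")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("sample_id", "breed") %in% names(samples)))
    stop("samples must have columns sample_id, breed")
  if (is.null(samples$group)) samples$group <- "other"
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples")
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants))
    stop(sprintf("calls is %d x %d but there are %d samples and %d variants",
                 nrow(calls), ncol(calls), nrow(samples), nrow(variants)))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(variants$pos_bp < 1))
    stop("pos_bp must be >= 1")

  variants$chrom <- as.character(variants$chrom)
  variants$pos_bp <- as.numeric(variants$pos_bp)
  ord <- order(suppressWarnings(as.numeric(variants$chrom)), variants$chrom,
               variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dup <- stats::ave(variants$pos_bp, variants$chrom,
                    FUN = function(p) duplicated(p))
  if (any(dup > 0))
    stop("duplicate pos_bp within a chromosome")
  dimnames(calls) <- list(samples$sample_id, variants$id)

  structure(
    list(calls = calls, variants = variants, samples = samples,
         n_i = nrow(calls), n_s = ncol(calls)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d variants on %d chromosome(s)\n",
              x$n_i, x$n_s, length(unique(x$variants$chrom))))
  cat("breeds:", paste(sort(unique(x$samples$breed)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param samples Logical/integer index over samples (rows).
#' @param variants Logical/integer index over variants (columns).
#' @return A new `genotype_dataset`.
#' @export
subset_dataset <- function(x, samples = seq_len(x$n_i),
                           variants = seq_len(x$n_s)) {
  genotype_dataset(x$calls[samples, variants, drop = FALSE],
                   x$variants[variants, , drop = FALSE],
                   x$samples[samples, , drop = FALSE])
}

# positions and SNP index helpers for one chromosome
.chrom_split <- function(dataset) {
  split(seq_len(dataset$n_s), dataset$variants$chrom)
}
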