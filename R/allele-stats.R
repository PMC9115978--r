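#' Per-variant allele frequencies and heterozygosity
#'
#' Frequencies are computed from non-missing calls only. A variant with no
#' non-missing call is flagged undefined (`p = NA`). The dataset-level
#' heterozygosity `het` — the quantity entering the Lencz minimum-SNP rule —
#' is the mean over defined variants of the observed heterozygote fraction.
#'
#' @param dataset A [genotype_dataset()].
#' @return A list with `variants` (a `data.frame` with `id`, `p` = allele_b
#'   frequency, `n_obs` = non-missing calls, `het_obs` = observed heterozygote
#'   fraction, `undefined` flag) and scalar `het`.
#' @export
allele_stats <- function(dataset) {
  g <- dataset$calls
  n_obs <- colSums(!is.na(g))
  s <- colSums(g, na.rm = TRUE)
  p <- ifelse(n_obs > 0, s / (2 * n_obs), NA_real_)
  het_obs <- ifelse(n_obs > 0, colSums(g == 1L, na.rm = TRUE) / n_obs,
                    NA_real_)
  vtab <- data.frame(id = dataset$variants$id, p = p, n_obs = n_obs,
                     het_obs = het_obs, undefined = n_obs == 0L,
                     stringsAsFactors = FALSE)
  list(variants = vtab, het = mean(het_obs, na.rm = TRUE))
}

#' Hardy-Weinberg exact test
#'
#' Two-sided conditional exact test: given the allele counts, the p-value is
#' the summed probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. No mid-p
#' correction is applied. Probabilities are accumulated with the standard
#' stable recurrence over heterozygote counts.
#'
#' @param n_hom_a,n_het,n_hom_b Non-negative integer genotype counts.
#' @return The exact p-value, in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  if (any(c(n_hom_a, n_het, n_hom_b) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom_a + n_het + n_hom_b
  if (n < 1) stop("total genotype count must be >= 1")
  n_minor <- min(2 * n_hom_a + n_het, 2 * n_hom_b + n_het)
  pv <- .hwe_het_pvals(n_minor, n)
  # feasible het counts share the parity of the minor allele count and are
  # indexed parity, parity + 2, ..., n_minor
  pv[[(n_het - n_minor %% 2L) / 2 + 1L]]
}

# p-values for every feasible heterozygote count, given the minor allele
# count and the number of genotypes. Returns a vector indexed over
# n_het = parity, parity+2, ..., n_minor.
.hwe_het_pvals <- function(n_minor, n) {
  if (n_minor == 0L) return(1)
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  k <- length(hets)
  logp <- numeric(k)
  # unnormalized log-probabilities by recurrence:
  # P(h+2)/P(h) = 4 * hom_minor(h) * hom_major(h) / ((h+1)(h+2))
  for (i in seq_len(k - 1L)) {
    h <- hets[i]
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - hom_min - h
    logp[i + 1L] <- logp[i] +
      log(4 * hom_min * hom_maj) - log((h + 1) * (h + 2))
  }
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  # sum of probabilities no larger than each one's (with relative tolerance)
  vapply(prob, function(p0) min(1, sum(prob[prob <= p0 * (1 + 1e-10)])),
         numeric(1))
}

#' Default quality-control thresholds
#'
#' @param max_variant_missing Drop variants with missing-call fraction above
#'   this (default 0.05, PLINK `--geno 0.05`).
#' @param min_maf Drop variants with minor allele frequency below this
#'   (default 0.05, `--maf 0.05`).
#' @param max_sample_missing Drop samples with missing-call fraction above
#'   this (default 0.10, `--mind 0.1`).
#' @param hwe_p_floor Drop variants with HWE exact p below this (default
#'   1e-6, `--hwe 0.000001`).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_variant_missing = 0.05, min_maf = 0.05,
                          max_sample_missing = 0.10, hwe_p_floor = 1e-6) {
  th <- list(max_variant_missing = max_variant_missing, min_maf = min_maf,
             max_sample_missing = max_sample_missing,
             hwe_p_floor = hwe_p_floor)
  bad <- vapply(th, function(x) !is.numeric(x) || x < 0 || x > 1, logical(1))
  if (any(bad)) stop("thresholds must be fractions in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Apply quality control
#'
#' Single ordered pass: (1) samples with missing fraction > `max_sample_missing`
#' (mind); (2) variants with missing fraction > `max_variant_missing` (geno);
#' (3) variants with HWE exact p < `hwe_p_floor`; (4) variants with
#' MAF < `min_maf`. MAF and HWE are computed on the post-mind samples from
#' non-missing calls only; a monomorphic variant has HWE p = 1 and falls at
#' the MAF stage.
#'
#' @param dataset A [genotype_dataset()].
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with the filtered `dataset` and a `report` of class
#'   `qc_report` (per-stage counts and removed ids, stage order).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  g <- dataset$calls

  miss_i <- rowMeans(is.na(g))
  drop_mind <- miss_i > thresholds$max_sample_missing
  removed_mind <- dataset$samples$sample_id[drop_mind]
  if (all(drop_mind)) stop("QC removed every sample (mind stage)")
  g <- g[!drop_mind, , drop = FALSE]

  miss_s <- colMeans(is.na(g))
  drop_geno <- miss_s > thresholds$max_variant_missing
  removed_geno <- dataset$variants$id[drop_geno]

  n_aa <- colSums(g == 0L, na.rm = TRUE)
  n_ab <- colSums(g == 1L, na.rm = TRUE)
  n_bb <- colSums(g == 2L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    if (n_aa[j] + n_ab[j] + n_bb[j] == 0L) return(1)
    hwe_exact_test(n_aa[j], n_ab[j], n_bb[j])
  }, numeric(1))
  drop_hwe <- !drop_geno & hwe_p < thresholds$hwe_p_floor
  removed_hwe <- dataset$variants$id[drop_hwe]

  n_obs <- n_aa + n_ab + n_bb
  p <- ifelse(n_obs > 0, (2 * n_bb + n_ab) / (2 * n_obs), 0)
  maf <- pmin(p, 1 - p)
  drop_maf <- !drop_geno & !drop_hwe &
    (maf < thresholds$min_maf | n_obs == 0L)
  removed_maf <- dataset$variants$id[drop_maf]

  keep_v <- !(drop_geno | drop_hwe | drop_maf)
  if (!any(keep_v)) stop("QC removed every variant")

  out <- subset_dataset(dataset, samples = !drop_mind, variants = keep_v)
  report <- structure(list(
    n_removed_mind = sum(drop_mind), n_removed_geno = sum(drop_geno),
    n_removed_hwe = sum(drop_hwe), n_removed_maf = sum(drop_maf),
    n_samples_kept = out$n_i, n_variants_kept = out$n_s,
    removed_samples = removed_mind,
    removed_geno = removed_geno, removed_hwe = removed_hwe,
    removed_maf = removed_maf,
    stage_order = c("mind", "geno", "hwe", "maf"),
    thresholds = thresholds), class = "qc_report")
  stopifnot(report$n_samples_kept + report$n_removed_mind == dataset$n_i,
            report$n_variants_kept + report$n_removed_geno +
              report$n_removed_hwe + report$n_removed_maf == dataset$n_s)
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC pass (order: ", paste(x$stage_order, collapse = " -> "), ")\n",
      sep = "")
  cat(sprintf("  samples removed (mind): %d\n", x$n_removed_mind))
  cat(sprintf("  variants removed: geno %d, hwe %d, maf %d\n",
              x$n_removed_geno, x$n_removed_hwe, x$n_removed_maf))
  cat(sprintf("  kept: %d samples x %d variants\n",
              x$n_samples_kept, x$n_variants_kept))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    stage = c("mind", "geno", "hwe", "maf", "kept_samples", "kept_variants"),
    count = c(report$n_removed_mind, report$n_removed_geno,
              report$n_removed_hwe, report$n_removed_maf,
              report$n_samples_kept, report$n_variants_kept))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
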