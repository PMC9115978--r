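#' Expected homozygote count for each sample
#'
#' Under random mating, a variant with cohort allele frequency `p` observed
#' on `n` haploid alleles contributes `1 - 2 p (1 - p) * n / (n - 1)` to the
#' expected homozygote count (the `n/(n-1)` small-sample correction matches
#' PLINK's `--het`; disable it with `correction = FALSE`). A sample's E sums
#' the contributions of its non-missing variants; variants observed on fewer
#' than two alleles are skipped with a warning.
#'
#' @param dataset A QC'd [genotype_dataset()].
#' @param sample_id One sample id, or `NULL` for every sample.
#' @param correction Apply the `n/(n-1)` correction (default `TRUE`).
#' @return Named numeric vector of E values.
#' @export
expected_homozygotes <- function(dataset, sample_id = NULL,
                                 correction = TRUE) {
  g <- dataset$calls
  n_obs <- colSums(!is.na(g))
  n_hap <- 2 * n_obs
  usable <- n_hap >= 2
  if (any(!usable))
    warning(sum(!usable), " variant(s) with < 2 observed alleles skipped")
  p <- colSums(g, na.rm = TRUE) / pmax(n_hap, 1)
  contrib <- 1 - 2 * p * (1 - p) *
    (if (correction) n_hap / pmax(n_hap - 1, 1) else 1)
  contrib[!usable] <- 0
  obs <- !is.na(g)
  obs[, !usable] <- FALSE
  e <- as.numeric(obs %*% contrib)
  names(e) <- dataset$samples$sample_id
  if (!is.null(sample_id)) {
    if (!sample_id %in% names(e)) stop("unknown sample_id: ", sample_id)
    e <- e[sample_id]
  }
  e
}

#' Observed homozygote and genotyped-SNP counts per sample
#'
#' @param dataset A [genotype_dataset()].
#' @return `data.frame` with `sample_id`, `O` (observed homozygotes) and `L`
#'   (non-missing autosomal genotypes).
#' @export
observed_homozygotes <- function(dataset) {
  g <- dataset$calls
  data.frame(sample_id = dataset$samples$sample_id,
             O = rowSums(g != 1L, na.rm = TRUE),
             L = rowSums(!is.na(g)),
             stringsAsFactors = FALSE)
}

#' Excess-homozygosity inbreeding coefficient
#'
#' `F_HOM = (O - E) / (L - E)`; negative when fewer homozygotes are observed
#' than expected.
#'
#' @param O Observed homozygote count.
#' @param E Expected homozygote count.
#' @param L Genotyped autosomal SNP count.
#' @return The coefficient (vectorised).
#' @export
f_hom <- function(O, E, L) {
  if (any(L <= E)) stop("degenerate input: L must exceed E")
  (O - E) / (L - E)
}

#' Autosomal map length
#'
#' `L_auto` is the summed span (last SNP - first SNP + 1) of every autosome
#' in the post-QC map — the F_ROH denominator. Chromosomes with fewer than
#' two SNPs are excluded with a warning.
#'
#' @param dataset A [genotype_dataset()].
#' @return Total length in bp.
#' @export
autosome_length <- function(dataset) {
  spans <- vapply(split(dataset$variants$pos_bp, dataset$variants$chrom),
                  function(p) if (length(p) < 2) NA_real_ else
                    max(p) - min(p) + 1, numeric(1))
  if (anyNA(spans))
    warning(sum(is.na(spans)), " chromosome(s) with < 2 SNPs excluded from L_auto")
  sum(spans, na.rm = TRUE)
}

#' ROH-based inbreeding coefficient for one sample
#'
#' `F_ROH = sum_i L_ROHi / L_auto`, optionally restricted to one length
#' class (`[lo, hi)` Mb bin of each segment's whole length).
#'
#' @param sample_segments Segments of a single sample (`chrom`, `start_bp`,
#'   `end_bp`, `length_bp`).
#' @param L_auto Autosomal map length in bp (> 0).
#' @param class_filter Optional `c(lo, hi)` in Mb; segments with
#'   `lo <= length_mb < hi` are kept.
#' @return The coefficient.
#' @export
f_roh <- function(sample_segments, L_auto, class_filter = NULL) {
  if (L_auto <= 0) stop("L_auto must be positive")
  s <- as.data.frame(sample_segments)
  if (nrow(s) > 1) {
    o <- order(s$chrom, s$start_bp)
    s <- s[o, ]
    same <- s$chrom[-1] == s$chrom[-nrow(s)]
    if (any(same & s$start_bp[-1] <= s$end_bp[-nrow(s)]))
      stop("overlapping segments for one sample")
  }
  if (!is.null(class_filter)) {
    mb <- s$length_bp / 1e6
    s <- s[mb >= class_filter[1] & mb < class_filter[2], , drop = FALSE]
  }
  sum(s$length_bp) / L_auto
}

#' Pearson correlation
#'
#' Product-moment correlation with the contracts used throughout the
#' pipeline: equal lengths of at least 3 and strictly positive variances.
#'
#' @param x,y Numeric vectors.
#' @return The coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Per-individual inbreeding records
#'
#' Combines observed/expected homozygosity with called ROH into one table:
#' O, E, L, F_HOM, per-class and total F_ROH, and L_auto.
#'
#' @param dataset A QC'd [genotype_dataset()].
#' @param rohset A `roh_set` from [detect_roh()] on the same dataset.
#' @param class_edges_mb Length-class edges in Mb.
#' @param correction Small-sample correction for E (see
#'   [expected_homozygotes()]).
#' @return `data.frame`, one row per individual.
#' @export
inbreeding_records <- function(dataset, rohset,
                               class_edges_mb = c(1, 5, 10, 20, 40),
                               correction = TRUE) {
  ol <- observed_homozygotes(dataset)
  e <- expected_homozygotes(dataset, correction = correction)
  l_auto <- autosome_length(dataset)
  segs <- as.data.frame(rohset)
  labels <- .class_labels(class_edges_mb)
  bounds <- cbind(class_edges_mb, c(class_edges_mb[-1], Inf))

  rec <- data.frame(sample_id = ol$sample_id,
                    breed = dataset$samples$breed,
                    O = ol$O, E = as.numeric(e[ol$sample_id]), L = ol$L,
                    stringsAsFactors = FALSE)
  rec$F_HOM <- f_hom(rec$O, rec$E, rec$L)
  per_sample <- split(segs, factor(segs$sample_id, levels = rec$sample_id))
  rec$F_ROH_total <- vapply(per_sample, f_roh, numeric(1), L_auto = l_auto)
  for (k in seq_along(labels))
    rec[[paste0("F_ROH_", labels[k])]] <-
      vapply(per_sample, f_roh, numeric(1), L_auto = l_auto,
             class_filter = bounds[k, ])
  rec$L_auto <- l_auto
  rownames(rec) <- NULL
  rec
}

#' Per-breed inbreeding summaries
#'
#' Mean +/- SE of per-class and total F_ROH, mean +/- SD of F_HOM, and the
#' Pearson correlation between total F_ROH and F_HOM. Breeds with fewer than
#' 3 individuals, or with zero variance in either coefficient, get `NA` for
#' the correlation.
#'
#' @param records Output of [inbreeding_records()].
#' @return `data.frame`, one row per breed.
#' @export
breed_summaries <- function(records) {
  froh_cols <- grep("^F_ROH_", names(records), value = TRUE)
  rows <- lapply(split(records, records$breed), function(r) {
    out <- data.frame(breed = r$breed[1], n_ind = nrow(r),
                      stringsAsFactors = FALSE)
    for (cl in froh_cols) {
      out[[paste0("mean_", cl)]] <- mean(r[[cl]])
      out[[paste0("se_", cl)]] <- .se(r[[cl]])
    }
    out$mean_F_HOM <- mean(r$F_HOM)
    out$sd_F_HOM <- stats::sd(r$F_HOM)
    out$r_froh_fhom <- if (nrow(r) >= 3 && stats::sd(r$F_ROH_total) > 0 &&
                           stats::sd(r$F_HOM) > 0)
      pearson_r(r$F_ROH_total, r$F_HOM) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
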