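#' Simulation configuration
#'
#' Describes a breed-structured SNP-array cohort with exact ground truth:
#' HWE background genotypes at breed-shifted allele frequencies, planted
#' autozygous tracts per individual reaching a per-breed target autozygous
#' fraction, island loci shared by a fixed fraction of a breed, rare
#' heterozygous calls inside tracts, and uniform missingness. The default is
#' a scaled-down cohort (10 breeds x 30 individuals, 18 autosomes x 300 SNPs
#' at ~40 kb spacing, roughly 5,400 SNPs) that runs in seconds; the default
#' per-breed autozygosity gradient spans 0.05-0.30, matching the range of
#' F_ROH reported for indigenous vs commercial pig breeds.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_breeds,individuals_per_breed Cohort shape. The first half of the
#'   breeds form group `"AHIP"`, the rest `"WECP"`.
#' @param n_chromosomes,snps_per_chromosome Map shape.
#' @param mean_spacing_kb,spacing_jitter Inter-SNP spacing: uniform on
#'   `mean * (1 +/- jitter)` kb.
#' @param maf_low,maf_high Base allele_b frequency drawn uniformly.
#' @param group_divergence Allele-frequency divergence between the two
#'   groups: per SNP, a random sign splits the base frequency by +/- half
#'   the divergence, so both groups drift away from the cohort mean and the
#'   cohort shows Wahlund-style excess homozygosity.
#' @param breed_drift_sd Per-breed, per-SNP frequency drift (normal SD).
#' @param f_star Per-breed mean target autozygous fraction
#'   (recycled/truncated to `n_breeds`).
#' @param f_star_sd Between-individual SD of the autozygosity target within
#'   a breed (truncated at 0). The default 0.05 matches the within-breed
#'   dispersion of SNP-based inbreeding coefficients reported for pig
#'   breeds; without it, within-breed correlations between inbreeding
#'   estimators would be undefined noise.
#' @param class_weights Sampling weights of planted tract lengths over the
#'   classes 1-5, 5-10, 10-20, 20-40, >40 Mb. Classes infeasible on the
#'   configured chromosomes must have zero weight.
#' @param islands `data.frame(chrom, start_bp, end_bp, breed, carrier_frac)`
#'   of island loci, or `NULL`. Carriers are the first
#'   `floor(carrier_frac * n)` individuals of the breed by sample index.
#' @param het_error_rate Probability a planted-tract call is flipped to a
#'   heterozygote (genotyping error inside autozygous tracts).
#' @param missing_rate Uniform missing-call probability.
#' @param min_tract_snps Minimum SNPs per planted tract (default 55, a small
#'   margin over the scanner's 50-SNP floor so planted truth is detectable).
#' @param tract_buffer_snps Minimum SNP separation between planted tracts of
#'   one individual (default 50 = one scanner window, so calls stay distinct).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_breeds = 10L, individuals_per_breed = 30L,
                       n_chromosomes = 18L, snps_per_chromosome = 300L,
                       mean_spacing_kb = 40, spacing_jitter = 0.25,
                       maf_low = 0.05, maf_high = 0.5,
                       group_divergence = 0.10, breed_drift_sd = 0.02,
                       f_star = seq(0.05, 0.30, length.out = n_breeds),
                       f_star_sd = 0.05,
                       class_weights = c(0.60, 0.32, 0.08, 0, 0),
                       islands = NULL,
                       het_error_rate = 0.002, missing_rate = 0.01,
                       min_tract_snps = 55L, tract_buffer_snps = 50L) {
  cfg <- as.list(environment())
  cfg$f_star <- rep_len(f_star, n_breeds)
  if (length(class_weights) != 5 || any(class_weights < 0) ||
      abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must be 5 non-negative values summing to 1")
  probs <- c(maf_low, maf_high, spacing_jitter, group_divergence,
             het_error_rate, missing_rate, cfg$f_star)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (mean_spacing_kb <= 0) stop("spacing must be positive")
  if (!is.null(islands)) {
    need <- c("chrom", "start_bp", "end_bp", "breed", "carrier_frac")
    if (!all(need %in% names(islands)))
      stop("islands needs columns: ", paste(need, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

.class_bounds_mb <- cbind(lo = c(1, 5, 10, 20, 40),
                          hi = c(5, 10, 20, 40, Inf))

#' Simulate a cohort with known ground truth
#'
#' See [sim_config()] for the generating model. Fully reproducible from the
#' config seed (R's default Mersenne-Twister generator). When `dir` is given,
#' the cohort is also written as PLINK binary files plus breed-map and truth
#' TSVs.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `dataset` (a [genotype_dataset()]) and `truth`
#'   (`tracts`, per-individual `f_star` targets and realised fractions,
#'   `island_carriers`, generating `freqs`).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nb <- config$n_breeds; ni <- config$individuals_per_breed
  nc <- config$n_chromosomes; ns_chr <- config$snps_per_chromosome
  n_i <- nb * ni; n_s <- nc * ns_chr

  groups <- rep(c("AHIP", "WECP"), c(ceiling(nb / 2), floor(nb / 2)))
  breeds <- sprintf("%s%02d", ifelse(groups == "AHIP", "AH", "WC"),
                    seq_len(nb))
  samples <- data.frame(
    sample_id = sprintf("%s_i%02d", rep(breeds, each = ni),
                        rep(seq_len(ni), nb)),
    breed = rep(breeds, each = ni), group = rep(groups, each = ni),
    stringsAsFactors = FALSE)

  # map: jittered spacing, 1-based positions
  spacing <- matrix(round(stats::runif(
    n_s, config$mean_spacing_kb * (1 - config$spacing_jitter) * 1000,
    config$mean_spacing_kb * (1 + config$spacing_jitter) * 1000)),
    ns_chr, nc)
  pos <- apply(spacing, 2, cumsum)
  chrom <- rep(as.character(seq_len(nc)), each = ns_chr)
  variants <- data.frame(
    id = sprintf("snp_%s_%04d", chrom, rep(seq_len(ns_chr), nc)),
    chrom = chrom, pos_bp = as.numeric(pos),
    allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  spans <- pos[ns_chr, ] - pos[1, ] + 1
  l_auto <- sum(spans)

  # feasibility of requested tract classes
  max_span_mb <- max(spans) / 1e6
  needed <- which(config$class_weights > 0)
  infeasible <- needed[.class_bounds_mb[needed, "lo"] >= max_span_mb]
  if (length(infeasible))
    stop("tract classes infeasible for the simulated chromosomes: ",
         paste(.class_labels(c(1, 5, 10, 20, 40))[infeasible],
               collapse = ", "))

  # breed-shifted allele frequencies: per-SNP random-sign split between the
  # groups, so both diverge away from the cohort mean (Wahlund effect)
  p0 <- stats::runif(n_s, config$maf_low, config$maf_high)
  snp_sign <- sample(c(-1, 1), n_s, replace = TRUE)
  shift <- ifelse(groups == "AHIP", 1, -1)
  p_breed <- vapply(seq_len(nb), function(b)
    pmin(0.99, pmax(0.01, p0 + shift[b] * snp_sign *
                      config$group_divergence / 2 +
                      stats::rnorm(n_s, 0, config$breed_drift_sd))),
    numeric(n_s))

  # HWE background genotypes
  calls <- matrix(NA_integer_, n_i, n_s)
  for (b in seq_len(nb)) {
    rows <- which(samples$breed == breeds[b])
    calls[rows, ] <- matrix(
      stats::rbinom(ni * n_s, 2L, rep(p_breed[, b], each = ni)), ni, n_s)
  }

  chrom_idx <- split(seq_len(n_s), variants$chrom)
  tract_list <- list()
  occupied <- vector("list", n_i)  # per individual: list of chrom index ranges
  for (i in seq_len(n_i)) occupied[[i]] <- list()

  add_tract <- function(i, ch, s, e, cls, src) {
    idx <- chrom_idx[[ch]][s:e]
    hap <- stats::rbinom(length(idx), 1L,
                         p_breed[idx, match(samples$breed[i], breeds)])
    calls[i, idx] <<- 2L * hap
    occupied[[i]][[length(occupied[[i]]) + 1L]] <<- list(ch = ch, s = s, e = e)
    tract_list[[length(tract_list) + 1L]] <<- data.frame(
      sample_id = samples$sample_id[i], breed = samples$breed[i],
      chrom = ch, start_bp = variants$pos_bp[idx[1]],
      end_bp = variants$pos_bp[idx[length(idx)]],
      start_idx = s, end_idx = e, n_snps = e - s + 1L,
      length_bp = variants$pos_bp[idx[length(idx)]] -
        variants$pos_bp[idx[1]] + 1,
      class = cls, source = src, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  overlaps_existing <- function(i, ch, s, e, buffer) {
    for (oc in occupied[[i]])
      if (oc$ch == ch && s <= oc$e + buffer && e >= oc$s - buffer)
        return(TRUE)
    FALSE
  }

  # island loci first: deterministic carrier assignment by sample index,
  # one shared haplotype per (island, breed). Random background tracts are
  # kept off island intervals of the same breed so the configured carrier
  # fraction is exactly the ROH incidence the locus presents.
  island_carriers <- list()
  forbidden <- list()
  if (!is.null(config$islands)) {
    for (r in seq_len(nrow(config$islands))) {
      isl <- config$islands[r, ]
      ch <- as.character(isl$chrom)
      idx <- chrom_idx[[ch]]
      inside <- which(variants$pos_bp[idx] >= isl$start_bp &
                        variants$pos_bp[idx] <= isl$end_bp)
      if (length(inside) < 1) stop("island interval contains no SNPs")
      s <- inside[1]; e <- inside[length(inside)]
      rows <- which(samples$breed == isl$breed)
      if (!length(rows)) stop("island breed not in cohort: ", isl$breed)
      n_carriers <- floor(isl$carrier_frac * length(rows))
      carriers <- rows[seq_len(n_carriers)]
      hap <- stats::rbinom(e - s + 1L, 1L,
                           p_breed[idx[s:e], match(isl$breed, breeds)])
      for (i in carriers) {
        calls[i, idx[s:e]] <- 2L * hap
        occupied[[i]][[length(occupied[[i]]) + 1L]] <-
          list(ch = ch, s = s, e = e)
        tract_list[[length(tract_list) + 1L]] <- data.frame(
          sample_id = samples$sample_id[i], breed = samples$breed[i],
          chrom = ch, start_bp = variants$pos_bp[idx[s]],
          end_bp = variants$pos_bp[idx[e]], start_idx = s, end_idx = e,
          n_snps = e - s + 1L,
          length_bp = variants$pos_bp[idx[e]] - variants$pos_bp[idx[s]] + 1,
          class = as.character(.classify_mb(
            (variants$pos_bp[idx[e]] - variants$pos_bp[idx[s]] + 1) / 1e6,
            c(1, 5, 10, 20, 40))),
          source = "island", stringsAsFactors = FALSE)
      }
      island_carriers[[r]] <- samples$sample_id[carriers]
      forbidden[[length(forbidden) + 1L]] <-
        list(breed = isl$breed, ch = ch, s = s, e = e)
    }
  }
  overlaps_forbidden <- function(breed, ch, s, e, buffer) {
    for (fb in forbidden)
      if (fb$breed == breed && fb$ch == ch &&
          s <= fb$e + buffer && e >= fb$s - buffer)
        return(TRUE)
    FALSE
  }

  # random autozygous tracts up to each individual's target fraction;
  # individuals vary around their breed mean
  feasible_w <- config$class_weights
  ind_target <- pmax(0, stats::rnorm(
    n_i, config$f_star[match(samples$breed, breeds)], config$f_star_sd))
  for (i in seq_len(n_i)) {
    target <- ind_target[i] * l_auto
    planted <- sum(vapply(occupied[[i]],
                          function(oc) {
                            idx <- chrom_idx[[oc$ch]]
                            variants$pos_bp[idx[oc$e]] -
                              variants$pos_bp[idx[oc$s]] + 1
                          }, numeric(1)))
    attempts <- 0L
    while (planted < target && attempts < 500L) {
      attempts <- attempts + 1L
      cls <- sample.int(5L, 1L, prob = feasible_w)
      lo <- .class_bounds_mb[cls, "lo"] * 1e6
      hi <- min(.class_bounds_mb[cls, "hi"] * 1e6, max(spans))
      len <- stats::runif(1, lo, hi)
      ok_chr <- which(spans >= len)
      if (!length(ok_chr)) next
      ch <- as.character(ok_chr[sample.int(length(ok_chr), 1L)])
      idx <- chrom_idx[[ch]]
      posc <- variants$pos_bp[idx]
      s <- sample.int(length(idx), 1L)
      e <- findInterval(posc[s] + len - 1, posc)
      if (e <= s) next
      span <- posc[e] - posc[s] + 1
      if (e - s + 1L < config$min_tract_snps) next
      if (span < lo || span >= .class_bounds_mb[cls, "hi"] * 1e6) next
      if (overlaps_existing(i, ch, s, e, config$tract_buffer_snps)) next
      if (overlaps_forbidden(samples$breed[i], ch, s, e,
                             config$tract_buffer_snps)) next
      add_tract(i, ch, s, e,
                .class_labels(c(1, 5, 10, 20, 40))[cls], "planted")
      planted <- planted + span
    }
  }

  tracts <- if (length(tract_list)) do.call(rbind, tract_list) else
    data.frame(sample_id = character(), breed = character(),
               chrom = character(), start_bp = numeric(), end_bp = numeric(),
               start_idx = integer(), end_idx = integer(),
               n_snps = integer(), length_bp = numeric(),
               class = character(), source = character(),
               stringsAsFactors = FALSE)

  # rare heterozygous calls inside tracts, then uniform missingness
  if (nrow(tracts) && config$het_error_rate > 0) {
    for (r in seq_len(nrow(tracts))) {
      i <- match(tracts$sample_id[r], samples$sample_id)
      idx <- chrom_idx[[tracts$chrom[r]]][tracts$start_idx[r]:tracts$end_idx[r]]
      flip <- stats::runif(length(idx)) < config$het_error_rate
      if (any(flip)) calls[i, idx[flip]] <- 1L
    }
  }
  if (config$missing_rate > 0)
    calls[matrix(stats::runif(n_i * n_s) < config$missing_rate, n_i, n_s)] <-
      NA_integer_

  planted_bp <- vapply(samples$sample_id, function(id)
    sum(tracts$length_bp[tracts$sample_id == id]), numeric(1))
  f_star_tab <- data.frame(
    sample_id = samples$sample_id, breed = samples$breed,
    f_target = ind_target,
    f_true = as.numeric(planted_bp) / l_auto, stringsAsFactors = FALSE)

  dataset <- genotype_dataset(calls, variants, samples)
  truth <- list(tracts = tracts, f_star = f_star_tab,
                island_carriers = island_carriers,
                freqs = list(base = p0, by_breed = p_breed),
                l_auto = l_auto, seed = config$seed)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_plink_binary(dataset, file.path(dir, "cohort"))
    data.table::fwrite(samples[, c("breed", "group")][!duplicated(samples$breed), ],
                       file.path(dir, "breed_groups.tsv"), sep = "\t")
    data.table::fwrite(tracts, file.path(dir, "truth_tracts.tsv"), sep = "\t")
    data.table::fwrite(f_star_tab, file.path(dir, "truth_fstar.tsv"),
                       sep = "\t")
    cfg <- unclass(config)
    scalar <- vapply(cfg, function(x) is.atomic(x) || is.null(x), logical(1))
    writeLines(paste0(names(cfg)[scalar], "=",
                      vapply(cfg[scalar], function(x)
                        paste(format(x, scientific = FALSE), collapse = ","),
                        character(1))),
               file.path(dir, "sim_config.txt"))
  }
  list(dataset = dataset, truth = truth)
}

#' Compare called ROH against simulated truth
#'
#' A planted tract counts as recovered when a called segment of the same
#' sample and chromosome overlaps it reciprocally by at least 80%. Boundary
#' error is the mean absolute offset of matched segment bounds from the
#' planted bounds, in SNP-index units. `f_roh_bias` is
#' `mean(F_ROH - f_true)` over individuals and `f_roh_r` their Pearson
#' correlation.
#'
#' @param rohset A `roh_set` called on the simulated cohort.
#' @param truth Truth object from [simulate_cohort()].
#' @param dataset The simulated [genotype_dataset()].
#' @param tolerance_snps Boundary tolerance used for the `boundary_ok`
#'   fraction (default 1).
#' @param min_length_bp,min_snps Eligibility floor for the sensitivity
#'   denominator (default 1 Mb, 50 SNPs).
#' @return List with `sensitivity`, `precision`, `boundary_error`,
#'   `boundary_ok`, `f_roh_bias`, `f_roh_r`, `n_tracts`, `n_segments`.
#' @export
truth_compare <- function(rohset, truth, dataset, tolerance_snps = 1,
                          min_length_bp = 1e6, min_snps = 50) {
  samples <- attr(rohset, "samples")
  if (is.null(samples) ||
      !identical(sort(samples$sample_id),
                 sort(truth$f_star$sample_id)))
    stop("cohort mismatch between ROH set and truth")
  segs <- as.data.frame(rohset)
  v <- dataset$variants
  idx_of <- function(ch, bp) {
    p <- v$pos_bp[v$chrom == ch]
    match(bp, p)
  }
  tr <- truth$tracts
  eligible <- tr$length_bp >= min_length_bp & tr$n_snps >= min_snps
  tr_el <- tr[eligible, , drop = FALSE]

  matched_seg <- rep(FALSE, nrow(segs))
  recovered <- rep(FALSE, nrow(tr_el))
  bnd <- numeric(0)
  for (r in seq_len(nrow(tr_el))) {
    cand <- which(segs$sample_id == tr_el$sample_id[r] &
                    segs$chrom == tr_el$chrom[r])
    if (!length(cand)) next
    ov <- pmin(segs$end_bp[cand], tr_el$end_bp[r]) -
      pmax(segs$start_bp[cand], tr_el$start_bp[r]) + 1
    rec <- ov >= 0.8 * tr_el$length_bp[r] &
      ov >= 0.8 * segs$length_bp[cand]
    if (any(rec)) {
      recovered[r] <- TRUE
      matched_seg[cand[rec]] <- TRUE
      best <- cand[rec][which.max(ov[rec])]
      bnd <- c(bnd,
               mean(abs(c(
                 idx_of(tr_el$chrom[r], segs$start_bp[best]) -
                   tr_el$start_idx[r],
                 idx_of(tr_el$chrom[r], segs$end_bp[best]) -
                   tr_el$end_idx[r]))))
    }
  }
  ids <- samples$sample_id
  f_roh_vec <- vapply(split(segs, factor(segs$sample_id, levels = ids)),
                      f_roh, numeric(1), L_auto = truth$l_auto)
  f_true <- truth$f_star$f_true[match(ids, truth$f_star$sample_id)]
  list(sensitivity = if (nrow(tr_el)) mean(recovered) else NA_real_,
       precision = if (nrow(segs)) mean(matched_seg) else NA_real_,
       boundary_error = if (length(bnd)) mean(bnd) else NA_real_,
       boundary_ok = if (length(bnd)) mean(bnd <= tolerance_snps) else NA_real_,
       f_roh_bias = mean(f_roh_vec - f_true),
       f_roh_r = if (stats::sd(f_true) > 0 && stats::sd(f_roh_vec) > 0)
         stats::cor(f_roh_vec, f_true) else NA_real_,
       n_tracts = nrow(tr_el), n_segments = nrow(segs))
}
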