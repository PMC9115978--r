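#' ROH calling parameters
#'
#' The seven sliding-window criteria of a PLINK-style `--homozyg` scan, plus
#' the false-positive rate `alpha` of the Lencz minimum-SNP rule. Defaults
#' follow standard SNP-array practice for livestock: minimum run length 1 Mb,
#' 50 SNPs per run and per window, at most 1 heterozygous and 5 missing calls
#' per window, a 1 Mb gap ceiling, at least 1 SNP per 100 kb, and a per-SNP
#' window-hit threshold of 0.01.
#'
#' @param min_length_kb Minimum run length (kb).
#' @param min_snps Minimum SNPs per run.
#' @param max_gap_kb Maximum gap between consecutive run SNPs (kb).
#' @param min_density_kb_per_snp Maximum kb per SNP inside a run.
#' @param window_snps Sliding-window size (SNPs).
#' @param window_max_het Maximum heterozygous calls per passing window.
#' @param window_max_missing Maximum missing calls per passing window.
#' @param window_threshold Minimum fraction of a SNP's containing windows
#'   that must pass for the SNP to qualify.
#' @param alpha False-positive rate used by [min_roh_snps()].
#' @return A `roh_params` list.
#' @export
roh_params <- function(min_length_kb = 1000, min_snps = 50,
                       max_gap_kb = 1000, min_density_kb_per_snp = 100,
                       window_snps = 50, window_max_het = 1,
                       window_max_missing = 5, window_threshold = 0.01,
                       alpha = 0.05) {
  p <- list(min_length_kb = min_length_kb, min_snps = min_snps,
            max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp,
            window_snps = window_snps, window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            window_threshold = window_threshold, alpha = alpha)
  counts <- c("min_length_kb", "min_snps", "max_gap_kb",
              "min_density_kb_per_snp", "window_snps")
  if (any(vapply(p[counts], function(x) x < 1, logical(1))))
    stop("length, SNP, gap, density and window parameters must be >= 1")
  if (window_threshold <= 0 || window_threshold > 1)
    stop("window_threshold must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (window_snps > min_snps)
    warning("window_snps exceeds min_snps; windows are longer than the shortest admissible run")
  structure(p, class = "roh_params")
}

#' Minimum SNPs per ROH (Lencz rule)
#'
#' `l = ln(alpha / (n_s * n_i)) / ln(1 - het)`, rounded up: the smallest run
#' length such that the expected number of chance homozygous runs across
#' `n_s` SNPs and `n_i` individuals stays below `alpha`.
#'
#' @param alpha False-positive rate in (0, 1).
#' @param n_s Number of SNPs per individual.
#' @param n_i Number of individuals.
#' @param het Mean heterozygosity across SNPs, in (0, 1).
#' @return Integer minimum SNP count (>= 1).
#' @export
min_roh_snps <- function(alpha, n_s, n_i, het) {
  if (het <= 0 || het >= 1) stop("het must be strictly inside (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_s < 1 || n_i < 1) stop("n_s and n_i must be >= 1")
  max(1L, as.integer(ceiling(log(alpha / (n_s * n_i)) / log(1 - het))))
}

#' Sliding-window pass flags for one chromosome of one sample
#'
#' Every contiguous window of `window_snps` SNPs (step 1) passes iff it
#' holds at most `window_max_het` heterozygous and `window_max_missing`
#' missing calls. A chromosome shorter than one window yields zero windows.
#'
#' @param sample_calls Integer vector of genotype codes (0/1/2/NA) ordered
#'   by map position along one chromosome.
#' @param params A [roh_params()] object.
#' @return Logical vector of length `max(0, n - window_snps + 1)`.
#' @export
window_pass_flags <- function(sample_calls, params = roh_params()) {
  k <- params$window_snps
  n <- length(sample_calls)
  if (n < k) return(logical(0))
  het <- cumsum(c(0L, !is.na(sample_calls) & sample_calls == 1L))
  mis <- cumsum(c(0L, is.na(sample_calls)))
  i <- seq_len(n - k + 1L)
  (het[i + k] - het[i]) <= params$window_max_het &
    (mis[i + k] - mis[i]) <= params$window_max_missing
}

#' Per-SNP run-qualification flags
#'
#' A SNP qualifies iff the fraction of passing windows among the windows that
#' actually contain it reaches `window_threshold`. SNPs near chromosome ends
#' sit in fewer than `window_snps` windows and the denominator shrinks
#' accordingly; SNPs on a chromosome shorter than one window sit in zero
#' windows and never qualify.
#'
#' @param window_flags Logical vector from [window_pass_flags()].
#' @param n_snps Number of SNPs on the chromosome.
#' @param params A [roh_params()] object.
#' @return Logical vector of length `n_snps`.
#' @export
snp_in_run_flags <- function(window_flags, n_snps, params = roh_params()) {
  k <- params$window_snps
  if (length(window_flags) == 0L) return(rep(FALSE, n_snps))
  stopifnot(length(window_flags) == n_snps - k + 1L)
  n_win <- length(window_flags)
  cs <- cumsum(c(0L, window_flags))
  i <- seq_len(n_snps)
  lo <- pmax(1L, i - k + 1L)
  hi <- pmin(i, n_win)
  n_pass <- cs[hi + 1L] - cs[lo]
  n_contain <- hi - lo + 1L
  n_contain > 0L & n_pass / n_contain >= params$window_threshold
}

#' Call ROH segments for one sample
#'
#' Maximal runs of consecutive qualifying SNPs are split at inter-SNP gaps
#' larger than `max_gap_kb`, trimmed so that both terminal SNPs are
#' homozygous non-missing calls (a heterozygous or missing call cannot bound
#' a homozygous run, though tolerated calls may remain inside), and kept iff
#' they hold at least `min_snps` SNPs, span at least `min_length_kb`, and
#' average at most `min_density_kb_per_snp` kb per SNP. Segment bounds are
#' the positions of the first and last SNP; `length_bp = end - start + 1`.
#'
#' @param dataset A QC'd [genotype_dataset()].
#' @param sample_id Sample identifier.
#' @param params A [roh_params()] object.
#' @return `data.frame` with columns `sample_id`, `breed`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`.
#' @export
call_roh_for_sample <- function(dataset, sample_id, params = roh_params()) {
  i <- match(sample_id, dataset$samples$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id)
  breed <- dataset$samples$breed[i]
  out <- list()
  for (idx in .chrom_split(dataset)) {
    calls <- dataset$calls[i, idx]
    pos <- dataset$variants$pos_bp[idx]
    segs <- .call_roh_chrom(calls, pos, params)
    if (nrow(segs))
      out[[length(out) + 1L]] <-
        cbind(data.frame(sample_id = sample_id, breed = breed,
                         chrom = dataset$variants$chrom[idx[1L]],
                         stringsAsFactors = FALSE),
              segs)
  }
  if (!length(out)) return(.empty_roh())
  do.call(rbind, out)
}

.empty_roh <- function() {
  data.frame(sample_id = character(), breed = character(),
             chrom = character(), start_bp = numeric(), end_bp = numeric(),
             n_snps = integer(), length_bp = numeric(),
             stringsAsFactors = FALSE)
}

# scanner core for one (sample, chromosome): positions must be sorted
.call_roh_chrom <- function(calls, pos, params) {
  n <- length(calls)
  qual <- snp_in_run_flags(window_pass_flags(calls, params), n, params)
  if (!any(qual))
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric()))
  # split qualifying runs at map gaps beyond the ceiling
  gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
  run_id <- cumsum(!qual | gap_break)
  segs <- list()
  hom <- !is.na(calls) & calls != 1L
  for (r in split(which(qual), run_id[qual])) {
    # trim terminal het/missing calls tolerated by the window filter
    in_hom <- r[hom[r]]
    if (length(in_hom) == 0L) next
    s <- in_hom[1L]; e <- in_hom[length(in_hom)]
    r <- r[r >= s & r <= e]
    n_snps <- length(r)
    length_bp <- pos[e] - pos[s] + 1
    if (n_snps < params$min_snps) next
    if (length_bp < params$min_length_kb * 1000) next
    if ((length_bp / 1000) / n_snps > params$min_density_kb_per_snp) next
    segs[[length(segs) + 1L]] <-
      data.frame(start_bp = pos[s], end_bp = pos[e],
                 n_snps = n_snps, length_bp = length_bp)
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric()))
  do.call(rbind, segs)
}

#' Detect ROH across a cohort
#'
#' Runs [call_roh_for_sample()] for every individual. The result carries the
#' cohort's sample table as attribute `samples` so that summaries can count
#' individuals without any ROH.
#'
#' @param dataset A QC'd [genotype_dataset()].
#' @param params A [roh_params()] object.
#' @return A `roh_set`: `data.frame` of segments (one row per run).
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  segs <- lapply(dataset$samples$sample_id, call_roh_for_sample,
                 dataset = dataset, params = params)
  out <- do.call(rbind, c(list(.empty_roh()), segs))
  rownames(out) <- NULL
  attr(out, "samples") <- dataset$samples
  attr(out, "params") <- params
  class(out) <- c("roh_set", "data.frame")
  out
}

#' Write ROH segments as TSV
#'
#' Column layout mirrors PLINK's `.hom` fields: sample, breed, chromosome,
#' bp bounds, SNP count and length in Mb.
#'
#' @param rohset A `roh_set` from [detect_roh()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_roh_segments <- function(rohset, path) {
  df <- as.data.frame(rohset)
  df$length_mb <- df$length_bp / 1e6
  data.table::fwrite(
    df[, c("sample_id", "breed", "chrom", "start_bp", "end_bp", "n_snps",
           "length_mb")],
    path, sep = "\t")
  invisible(path)
}
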