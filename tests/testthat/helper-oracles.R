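# Independent oracles used across the suite. These deliberately share no
# code with the package: the HWE oracle evaluates the conditional
# distribution by direct log-factorial formula, the ROH oracle materialises
# every window and per-SNP ratio with plain loops, and the overlap oracle is
# a quadratic all-pairs scan.

# exact conditional probabilities of every heterozygote count, direct formula
hwe_oracle_pvals <- function(n_minor, n) {
  if (n_minor == 0) return(1)
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - hom_min - h
    lfactorial(n) - lfactorial(hom_min) - lfactorial(h) -
      lfactorial(hom_maj) + h * log(2) +
      lfactorial(n_minor) + lfactorial(n_major) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p <- p / sum(p)
  vapply(p, function(p0) min(1, sum(p[p <= p0 * (1 + 1e-10)])), numeric(1))
}

hwe_oracle <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  n_minor <- min(2 * n_hom_a + n_het, 2 * n_hom_b + n_het)
  pv <- hwe_oracle_pvals(n_minor, n)
  pv[(n_het - n_minor %% 2) / 2 + 1]
}

# naive reference ROH scanner for one (sample, chromosome)
brute_force_roh <- function(calls, pos, params = roh_params()) {
  n <- length(calls)
  k <- params$window_snps
  n_win <- max(0L, n - k + 1L)
  wpass <- logical(n_win)
  for (w in seq_len(n_win)) {
    win <- calls[w:(w + k - 1)]
    wpass[w] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }
  qual <- logical(n)
  for (i in seq_len(n)) {
    ws <- max(1L, i - k + 1L):min(i, n_win)
    ws <- ws[ws >= 1 & ws <= n_win]
    if (length(ws))
      qual[i] <- sum(wpass[ws]) / length(ws) >= params$window_threshold
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!qual[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n && qual[j + 1L] &&
           pos[j + 1L] - pos[j] <= params$max_gap_kb * 1000) j <- j + 1L
    r <- i:j
    hom <- r[!is.na(calls[r]) & calls[r] != 1]
    if (length(hom)) {
      r <- hom[1]:hom[length(hom)]
      n_snps <- length(r)
      len <- pos[r[n_snps]] - pos[r[1]] + 1
      if (n_snps >= params$min_snps &&
          len >= params$min_length_kb * 1000 &&
          (len / 1000) / n_snps <= params$min_density_kb_per_snp)
        segs[[length(segs) + 1L]] <- c(start_bp = pos[r[1]],
                                       end_bp = pos[r[n_snps]],
                                       n_snps = n_snps, length_bp = len)
    }
    i <- j + 1L
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = numeric(), length_bp = numeric()))
  as.data.frame(do.call(rbind, segs))
}

# random single-sample chromosome with optional planted homozygous stretches
# and occasional large gaps (to exercise gap splitting)
random_chromosome <- function(n, seed, plant_prob = 0.6) {
  set.seed(seed)
  spacing <- ifelse(runif(n) < 0.03, runif(n, 9e5, 1.5e6),
                    runif(n, 1e4, 1e5))
  pos <- cumsum(round(spacing))
  p <- runif(n, 0.05, 0.5)
  calls <- rbinom(n, 2, p)
  if (runif(1) < plant_prob && n > 120) {
    len <- sample(60:min(300, n - 10), 1)
    s <- sample(1:(n - len), 1)
    calls[s:(s + len - 1)] <- 2 * rbinom(len, 1, p[s:(s + len - 1)])
  }
  calls[runif(n) < 0.01] <- NA
  list(calls = as.integer(calls), pos = pos)
}

one_sample_dataset <- function(calls, pos, chrom = "1") {
  genotype_dataset(
    matrix(calls, nrow = 1, dimnames = list("s1", NULL)),
    data.frame(id = paste0("v", seq_along(pos)), chrom = chrom,
               pos_bp = pos, allele_a = "A", allele_b = "C"),
    data.frame(sample_id = "s1", breed = "b1"))
}

# random multi-chromosome dataset for round-trip properties; allele_b is
# arranged to be the minor allele so the text dialect round-trips exactly
random_dataset <- function(n_i, n_s, n_chrom = 2, miss = 0.05, seed = 1) {
  set.seed(seed)
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), n_s))
  pos <- unlist(lapply(split(seq_len(n_s), chrom), function(ix)
    cumsum(sample(1e4:1e5, length(ix), replace = TRUE))))
  p <- runif(n_s, 0.05, 0.45)
  calls <- matrix(rbinom(n_i * n_s, 2, rep(p, each = n_i)), n_i, n_s)
  calls[matrix(runif(n_i * n_s) < miss, n_i, n_s)] <- NA
  # ensure allele_b is strictly minor among observed calls (flip polarity,
  # and break exact ties, since the text reader assigns minor-by-default
  # with a lexicographic tie-break)
  for (j in seq_len(n_s)) {
    ok <- which(!is.na(calls[, j]))
    if (!length(ok)) next
    if (mean(calls[ok, j]) / 2 > 0.5) calls[, j] <- 2L - calls[, j]
    if (mean(calls[ok, j]) / 2 == 0.5) {
      nz <- ok[calls[ok, j] > 0]
      calls[nz[1], j] <- 0L
    }
  }
  genotype_dataset(
    calls,
    data.frame(id = sprintf("v%04d", seq_len(n_s)), chrom = chrom,
               pos_bp = pos, allele_a = "A", allele_b = "C"),
    data.frame(sample_id = sprintf("s%03d", seq_len(n_i)),
               breed = rep_len(c("x", "y"), n_i)))
}

# quadratic all-pairs interval overlap (1-based inclusive coordinates)
brute_overlap <- function(islands, features) {
  hits <- list()
  for (i in seq_len(nrow(islands)))
    for (f in seq_len(nrow(features))) {
      if (islands$chrom[i] != features$chrom[f]) next
      ov <- min(islands$end_bp[i], features$end[f]) -
        max(islands$start_bp[i], features$start[f]) + 1
      if (ov >= 1)
        hits[[length(hits) + 1L]] <- data.frame(
          island = i, feature_id = features$id[f], overlap_bp = ov)
    }
  if (!length(hits))
    return(data.frame(island = integer(), feature_id = character(),
                      overlap_bp = numeric()))
  do.call(rbind, hits)
}

# wrap a plain data.frame of segments as a roh_set
.as_rohset <- function(df, samples) {
  if (!nrow(df))
    df <- data.frame(sample_id = character(), breed = character(),
                     chrom = character(), start_bp = numeric(),
                     end_bp = numeric(), n_snps = integer(),
                     length_bp = numeric())
  attr(df, "samples") <- samples
  class(df) <- c("roh_set", "data.frame")
  df
}

# two-pass textbook Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
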