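test_that("min_roh_snps follows the closed form", {
  # ln(0.25)/ln(0.5) = 2 exactly
  expect_equal(min_roh_snps(0.25, 1, 1, 0.5), 2L)
  # chip-scale inputs: 0.05/(54075*320), het 0.33 -> 49.097 -> 50
  expect_equal(min_roh_snps(0.05, 54075, 320, 0.33), 50L)
  # non-increasing in het
  l <- vapply(seq(0.05, 0.9, by = 0.05), function(h)
    min_roh_snps(0.05, 5000, 100, h), integer(1))
  expect_true(all(diff(l) <= 0))
  expect_error(min_roh_snps(0.05, 10, 10, 0), "het")
  expect_error(min_roh_snps(0.05, 10, 10, 1), "het")
})

test_that("window pass flags respect the het and missing tolerances", {
  p <- roh_params()
  w <- rep(0L, 50)
  w[25] <- 1L
  expect_true(window_pass_flags(w, p))              # 1 het allowed
  w[26] <- 1L
  expect_false(window_pass_flags(w, p))             # 2 hets fail
  m <- rep(2L, 50); m[1:6] <- NA
  expect_false(window_pass_flags(m, p))             # 6 missing fail
  m[6] <- 2L
  expect_true(window_pass_flags(m, p))              # 5 missing pass
  expect_length(window_pass_flags(rep(0L, 49), p), 0)  # short chromosome
})

test_that("per-SNP flags match brute-force window enumeration", {
  p <- roh_params()
  ch <- random_chromosome(600, seed = 61)
  flags <- snp_in_run_flags(window_pass_flags(ch$calls, p), 600, p)
  wpass <- vapply(1:551, function(w) {
    win <- ch$calls[w:(w + 49)]
    sum(win == 1, na.rm = TRUE) <= 1 && sum(is.na(win)) <= 5
  }, logical(1))
  brute <- vapply(1:600, function(i) {
    ws <- max(1, i - 49):min(i, 551)
    length(ws) > 0 && sum(wpass[ws]) / length(ws) >= 0.01
  }, logical(1))
  expect_identical(flags, brute)
  # degenerate directions
  expect_true(all(snp_in_run_flags(rep(TRUE, 51), 100, p)))
  expect_false(any(snp_in_run_flags(rep(FALSE, 51), 100, p)))
})

test_that("call_roh_for_sample honours the segment-level criteria", {
  p <- roh_params()
  # all-heterozygous sample: nothing
  ds <- one_sample_dataset(rep(1L, 200), cumsum(rep(4e4, 200)))
  expect_equal(nrow(call_roh_for_sample(ds, "s1", p)), 0)
  expect_error(call_roh_for_sample(ds, "nope", p), "unknown sample")

  # planted homozygous tract of 60 SNPs spanning ~2.4 Mb with heterozygous
  # flanking SNPs: exactly one segment bounded by the planted first/last SNP
  set.seed(71)
  n <- 400
  pos <- cumsum(round(runif(n, 3.5e4, 4.5e4)))
  calls <- rbinom(n, 2, runif(n, 0.2, 0.5))
  tract <- 150:209
  calls[tract] <- 2L
  calls[c(148, 149, 210, 211)] <- 1L  # clean break at both ends
  ds <- one_sample_dataset(as.integer(calls), pos)
  segs <- call_roh_for_sample(ds, "s1", p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, pos[150])
  expect_equal(segs$end_bp, pos[209])
  expect_equal(segs$n_snps, 60)

  # 49-SNP tract (below the 50-SNP floor): no segment
  calls2 <- rep(1L, n)
  calls2[150:198] <- 2L
  ds2 <- one_sample_dataset(calls2, pos)
  expect_equal(nrow(call_roh_for_sample(ds2, "s1", p)), 0)
})

test_that("scanner equals the brute-force reference on random chromosomes", {
  p <- roh_params()
  for (seed in 1:25) {
    n <- sample(60:600, 1)
    ch <- random_chromosome(n, seed = 1000 + seed)
    ds <- one_sample_dataset(ch$calls, ch$pos)
    got <- call_roh_for_sample(ds, "s1", p)
    want <- brute_force_roh(ch$calls, ch$pos, p)
    expect_equal(nrow(got), nrow(want), label = paste("seed", seed))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, as.integer(want$n_snps))
    }
  }
})

test_that("every emitted segment satisfies the six constraints", {
  p <- roh_params()
  sim <- simulate_cohort(sim_config(seed = 81, n_breeds = 3,
                                    individuals_per_breed = 10,
                                    n_chromosomes = 5))
  rs <- detect_roh(sim$dataset, p)
  expect_gt(nrow(rs), 0)
  expect_true(all(rs$start_bp <= rs$end_bp))
  expect_true(all(rs$n_snps >= p$min_snps))
  expect_true(all(rs$length_bp >= p$min_length_kb * 1000))
  expect_true(all((rs$length_bp / 1000) / rs$n_snps <=
                    p$min_density_kb_per_snp))
  expect_equal(rs$length_bp, rs$end_bp - rs$start_bp + 1)
  # per sample per chromosome: sorted, non-overlapping, gaps respected
  for (key in split(rs, paste(rs$sample_id, rs$chrom))) {
    key <- key[order(key$start_bp), ]
    if (nrow(key) > 1)
      expect_true(all(key$start_bp[-1] > key$end_bp[-nrow(key)]))
  }
})

test_that("scanner is deterministic and polarity-invariant", {
  sim <- simulate_cohort(sim_config(seed = 91, n_breeds = 2,
                                    individuals_per_breed = 8,
                                    n_chromosomes = 4))
  r1 <- detect_roh(sim$dataset)
  r2 <- detect_roh(sim$dataset)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  flipped <- sim$dataset
  flipped$calls <- 2L - flipped$calls
  flipped <- genotype_dataset(flipped$calls, flipped$variants,
                              flipped$samples)
  r3 <- detect_roh(flipped)
  expect_identical(as.data.frame(r1), as.data.frame(r3))
})

test_that("doubling min_length_kb never increases the segment count", {
  sim <- simulate_cohort(sim_config(seed = 95, n_breeds = 2,
                                    individuals_per_breed = 10,
                                    n_chromosomes = 4))
  n1 <- nrow(detect_roh(sim$dataset, roh_params(min_length_kb = 1000)))
  n2 <- nrow(detect_roh(sim$dataset, roh_params(min_length_kb = 2000)))
  n3 <- nrow(detect_roh(sim$dataset, roh_params(min_length_kb = 4000)))
  expect_true(n2 <= n1 && n3 <= n2)
})

test_that("empty cohorts yield an empty ROH set", {
  sim <- simulate_cohort(sim_config(seed = 97, n_breeds = 2,
                                    individuals_per_breed = 3,
                                    n_chromosomes = 2))
  empty <- subset_dataset(sim$dataset, samples = integer(0))
  expect_equal(nrow(detect_roh(empty)), 0)
})

test_that("length_class_table bins and dispersions are correct", {
  samples <- data.frame(sample_id = c("a", "b"), breed = "x", group = "G1")
  seg <- data.frame(sample_id = "a", breed = "x", chrom = "1",
                    start_bp = 1e6, end_bp = 4e6 - 1, n_snps = 80,
                    length_bp = 3e6)
  lct <- length_class_table(seg, samples = samples)
  expect_equal(unname(lct$class_totals), c(1, 0, 0, 0, 0))
  expect_equal(lct$grand_total, 1)
  expect_equal(lct$by_breed$mean_number, 0.5)  # one ROH over two animals
  # SE of the per-individual count: sd(c(1, 0)) / sqrt(2)
  expect_equal(lct$by_breed$se_number, sd(c(1, 0)) / sqrt(2))
  seg$length_bp <- 5e5
  expect_error(length_class_table(seg, samples = samples), "first class")
})

test_that("chromosome coverage matches planted spans", {
  samples <- data.frame(sample_id = "a", breed = "x")
  v <- data.frame(id = paste0("v", 1:10), chrom = "1",
                  pos_bp = seq(1e6, 10e6, by = 1e6),
                  allele_a = "A", allele_b = "C")
  ds <- genotype_dataset(matrix(0L, 1, 10), v, samples)
  cov0 <- chromosome_coverage(.as_rohset(data.frame(), samples), ds)
  expect_equal(cov0$coverage, 0)
  seg <- data.frame(sample_id = "a", breed = "x", chrom = "1",
                    start_bp = 1e6, end_bp = 10e6, n_snps = 10,
                    length_bp = 9e6 + 1)
  cov1 <- chromosome_coverage(.as_rohset(seg, samples), ds)
  expect_equal(cov1$coverage, 1)
  # a chromosome with one SNP is flagged undefined
  v2 <- rbind(v, data.frame(id = "w", chrom = "2", pos_bp = 5e6,
                            allele_a = "A", allele_b = "C"))
  ds2 <- genotype_dataset(matrix(0L, 1, 11), v2, samples)
  cov2 <- chromosome_coverage(.as_rohset(seg, samples), ds2)
  expect_true(is.na(cov2$coverage[cov2$chrom == "2"]))
})
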