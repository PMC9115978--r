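make_track <- function(incidence, chrom = "1", breed = "x") {
  data.frame(chrom = chrom, pos_bp = seq_along(incidence) * 4e4,
             snp_id = paste0(chrom, "_", seq_along(incidence)),
             breed = breed, incidence = incidence,
             stringsAsFactors = FALSE)
}

test_that("snp_incidence counts covering individuals per SNP", {
  samples <- data.frame(sample_id = paste0("s", 1:10), breed = "x")
  v <- data.frame(id = paste0("v", 1:20), chrom = "1",
                  pos_bp = (1:20) * 1e5, allele_a = "A", allele_b = "C")
  ds <- genotype_dataset(matrix(0L, 10, 20), v, samples)
  # no ROH: all-zero track
  t0 <- snp_incidence(.as_rohset(data.frame(), samples), ds, "x")
  expect_true(all(t0$incidence == 0))
  expect_error(snp_incidence(.as_rohset(data.frame(), samples), ds, "nope"),
               "unknown breed")
  # 5 of 10 individuals covered at SNPs 5..10
  segs <- data.frame(sample_id = paste0("s", 1:5), breed = "x", chrom = "1",
                     start_bp = 5e5, end_bp = 1e6, n_snps = 6,
                     length_bp = 5e5 + 1)
  tr <- snp_incidence(.as_rohset(segs, samples), ds, "x")
  expect_equal(tr$incidence[5:10], rep(0.5, 6))
  expect_equal(tr$incidence[c(1:4, 11:20)], rep(0, 14))
})

test_that("call_islands respects threshold, maximality and chromosomes", {
  expect_equal(nrow(call_islands(make_track(rep(0.39, 50)), 0.40)), 0)
  one <- call_islands(make_track(c(0, 0, 0.5, 0, 0)), 0.40)
  expect_equal(one$n_snps, 1)
  expect_equal(one$start_bp, one$end_bp)
  expect_error(call_islands(make_track(0.5), 0), "threshold")
  expect_error(call_islands(make_track(0.5), 1.2), "threshold")

  inc <- rep(0.1, 200); inc[60:139] <- 0.6
  isl <- call_islands(make_track(inc), 0.40)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$snp_ids[[1]], paste0("1_", 60:139))  # planted block
  expect_equal(isl$peak_incidence, 0.6)
  # a single dip splits an island; runs never span chromosomes
  inc[100] <- 0.2
  isl2 <- call_islands(make_track(inc), 0.40)
  expect_equal(nrow(isl2), 2)
  two_chr <- rbind(make_track(rep(0.6, 5), chrom = "1"),
                   make_track(rep(0.6, 5), chrom = "2"))
  expect_equal(nrow(call_islands(two_chr, 0.40)), 2)
})

test_that("raising the threshold monotonically shrinks total island bp", {
  set.seed(151)
  inc <- pmin(1, abs(stats::filter(runif(400), rep(1 / 15, 15),
                                   sides = 2)) * 2)
  inc[is.na(inc)] <- 0
  tr <- make_track(as.numeric(inc))
  total_bp <- vapply(c(0.2, 0.3, 0.4, 0.5, 0.6), function(th) {
    isl <- call_islands(tr, th)
    if (!nrow(isl)) 0 else sum(isl$end_bp - isl$start_bp + 1)
  }, numeric(1))
  expect_true(all(diff(total_bp) <= 0))
  # maximality audit: neighbours of island bounds are below threshold
  isl <- call_islands(tr, 0.4)
  for (r in seq_len(nrow(isl))) {
    i0 <- match(isl$start_bp[r], tr$pos_bp)
    i1 <- match(isl$end_bp[r], tr$pos_bp)
    if (i0 > 1) expect_lt(tr$incidence[i0 - 1], 0.4)
    if (i1 < nrow(tr)) expect_lt(tr$incidence[i1 + 1], 0.4)
    expect_true(all(tr$incidence[i0:i1] >= 0.4))
  }
})

test_that("group island comparison is a set identity", {
  gm <- data.frame(breed = c("a", "b"), group = c("G1", "G2"))
  t_a <- make_track(c(rep(0.6, 10), rep(0, 30)), breed = "a")
  t_b <- make_track(c(rep(0, 20), rep(0.7, 10), rep(0, 10)), breed = "b")
  cmp <- compare_group_islands(list(a = t_a, b = t_b), gm, 0.40)
  expect_equal(cmp$n_unique_1, 10)
  expect_equal(cmp$n_unique_2, 10)
  expect_equal(cmp$n_shared, 0)
  # identical tracks: nothing unique
  cmp2 <- compare_group_islands(list(a = t_a, b = t_a), gm, 0.40)
  expect_equal(cmp2$n_unique_1 + cmp2$n_unique_2, 0)
  expect_equal(cmp2$n_shared, 10)
  # shared + unique1 + unique2 = |union|
  t_c <- make_track(c(rep(0, 5), rep(0.8, 10), rep(0, 25)), breed = "b")
  cmp3 <- compare_group_islands(list(a = t_a, b = t_c), gm, 0.40)
  union_size <- length(unique(c(paste0("1_", 1:10), paste0("1_", 6:15))))
  expect_equal(cmp3$n_shared + cmp3$n_unique_1 + cmp3$n_unique_2,
               union_size)
  expect_error(compare_group_islands(list(a = t_a), gm, 0.4), "two groups")
})

test_that("annotation respects BED and GFF3 coordinate conventions", {
  isl <- data.frame(breed = "x", chrom = "1", start_bp = 100, end_bp = 200,
                    n_snps = 5, peak_incidence = 0.5)
  bed <- tempfile(fileext = ".bed")
  # 0-based half-open "99 200" is 1-based 100..200 -> full 101 bp overlap
  writeLines(c("1\t99\t200\tgeneA", "1\t90\t99\tgeneB"), bed)
  hits <- annotate_islands(isl, bed)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$feature_id, "geneA")
  expect_equal(hits$overlap_bp, 101)
  # geneB ends at bp 99 (1-based), island starts at 100: no hit

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t100\t200\t.\t+\t.\tID=geneA",
               "1\tsrc\tgene\t91\t99\t.\t+\t.\tID=geneB"), gff)
  hits_gff <- annotate_islands(isl, gff)
  expect_equal(hits_gff$feature_id, "geneA")
  expect_equal(hits_gff$overlap_bp, 101)
})

test_that("annotation equals the quadratic all-pairs oracle", {
  set.seed(161)
  n_isl <- 15; n_feat <- 40
  isl <- data.frame(breed = "x", chrom = sample(c("1", "2"), n_isl, TRUE),
                    start_bp = sample(1:5000, n_isl))
  isl$end_bp <- isl$start_bp + sample(50:800, n_isl)
  isl$n_snps <- 5; isl$peak_incidence <- 0.5
  feats <- data.frame(chrom = sample(c("1", "2", "3"), n_feat, TRUE),
                      start = sample(1:5000, n_feat),
                      id = sprintf("g%02d", 1:n_feat))
  feats$end <- feats$start + sample(20:600, n_feat)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       feats$chrom, feats$start, feats$end, feats$id)), gff)
  got <- suppressWarnings(annotate_islands(isl, gff))
  want <- brute_overlap(isl, feats)
  got_keys <- sort(paste(got$start_bp, got$feature_id, got$overlap_bp))
  want_keys <- sort(paste(isl$start_bp[want$island], want$feature_id,
                          want$overlap_bp))
  expect_identical(got_keys, want_keys)

  # the same features through the BED encoding give identical hits
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", feats$chrom, feats$start - 1,
                     feats$end, feats$id), bed)
  got_bed <- suppressWarnings(annotate_islands(isl, bed))
  expect_identical(got_keys,
                   sort(paste(got_bed$start_bp, got_bed$feature_id,
                              got_bed$overlap_bp)))
})
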