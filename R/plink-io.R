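#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses the classic 4-column MAP / allele-pair PED dialect. Non-autosomal
#' rows and rows with unknown (non-positive) positions are dropped with a
#' message; the dropped count is attached as attribute `n_dropped_variants`.
#' The counted allele (`allele_b`, genotype code 2) is the minor allele by
#' default; ties break to the lexicographically smaller allele, and a
#' monomorphic variant gets the placeholder allele `"0"` as `allele_b`.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param autosomes Character or integer vector of accepted chromosome
#'   labels (default `1:18`, the pig autosome set).
#' @return A [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path, autosomes = 1:18) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  autosomes <- as.character(autosomes)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map <- lapply(seq_along(map_lines), function(i) {
    f <- strsplit(trimws(map_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 4L)
      stop(sprintf("malformed MAP line %d: expected 4 columns, got %d",
                   i, length(f)))
    f
  })
  map <- as.data.frame(do.call(rbind, map), stringsAsFactors = FALSE)
  names(map) <- c("chrom", "id", "cm", "pos_bp")
  map$pos_bp <- suppressWarnings(as.numeric(map$pos_bp))
  if (anyNA(map$pos_bp)) stop("non-numeric position in MAP file")
  n_map <- nrow(map)

  keep <- map$chrom %in% autosomes & map$pos_bp >= 1
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " non-autosomal or unknown-position variant(s) dropped on load")

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ok_allele <- c("A", "C", "G", "T", "1", "2", "0")
  n_i <- length(ped_lines)
  geno_a <- matrix("0", n_i, n_map)
  geno_b <- matrix("0", n_i, n_map)
  fam <- vector("list", n_i)
  for (i in seq_len(n_i)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_map)
      stop(sprintf(
        "PED line %d has %d genotype columns but MAP has %d rows",
        i, max(0L, length(f) - 6L), n_map))
    al <- f[-(1:6)]
    if (!all(al %in% ok_allele))
      stop(sprintf("malformed PED line %d: invalid allele code", i))
    fam[[i]] <- f[1:6]
    geno_a[i, ] <- al[c(TRUE, FALSE)]
    geno_b[i, ] <- al[c(FALSE, TRUE)]
  }
  fam <- as.data.frame(do.call(rbind, fam), stringsAsFactors = FALSE)
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  if (anyDuplicated(fam$iid))
    fam$iid <- make.unique(fam$iid)

  geno_a <- geno_a[, keep, drop = FALSE]
  geno_b <- geno_b[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  n_s <- nrow(map)
  calls <- matrix(NA_integer_, n_i, n_s)
  allele_a <- allele_b <- character(n_s)
  for (j in seq_len(n_s)) {
    a1 <- geno_a[, j]; a2 <- geno_b[, j]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop(sprintf("variant %s has >2 alleles", map$id[j]))
    if (length(alleles) == 0L) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      allele_a[j] <- alleles[1L]; allele_b[j] <- "0"
      calls[!miss, j] <- 0L
      next
    }
    cnt <- table(factor(obs, levels = alleles))
    # minor allele (tie -> lexicographically smaller) is the counted allele_b
    minor <- if (cnt[[1L]] <= cnt[[2L]]) alleles[1L] else alleles[2L]
    major <- setdiff(alleles, minor)
    allele_a[j] <- major; allele_b[j] <- minor
    calls[!miss, j] <- (a1[!miss] == minor) + (a2[!miss] == minor)
  }

  variants <- data.frame(id = map$id, chrom = map$chrom, pos_bp = map$pos_bp,
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam$iid, breed = fam$fid,
                        stringsAsFactors = FALSE)
  out <- genotype_dataset(calls, variants, samples)
  attr(out, "n_dropped_variants") <- n_dropped
  out
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_plink_text()]. The breed label is written as the family
#' id. Missing calls become the `"0 0"` allele pair.
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(dataset, prefix) {
  if (dataset$n_i == 0L || dataset$n_s == 0L) stop("empty dataset")
  v <- dataset$variants
  map <- paste(v$chrom, v$id, 0, format(v$pos_bp, scientific = FALSE,
                                        trim = TRUE))
  writeLines(map, paste0(prefix, ".map"))

  aa <- ifelse(v$allele_a == "0" & v$allele_b != "0", v$allele_b, v$allele_a)
  bb <- ifelse(v$allele_b == "0", aa, v$allele_b)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(dataset$n_i)) {
    g <- dataset$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, bb, aa))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, bb, aa))
    line <- paste(dataset$samples$breed[i], dataset$samples$sample_id[i],
                  0, 0, 0, -9,
                  paste(paste(a1, a2), collapse = " "))
    writeLines(line, con)
  }
  invisible(paste0(prefix, c(".ped", ".map")))
}

# PLINK 1 binary: magic 0x6C 0x1B, mode 0x01 (SNP-major). Each variant is
# ceil(n_i/4) bytes; sample i occupies bits (2i, 2i+1) little-endian within
# its byte. Bit pairs: 00 hom allele_a, 01 missing, 10 het, 11 hom allele_b.
.bed_magic <- as.raw(c(0x6C, 0x1B, 0x01))
.code_to_bits <- c(`0` = 0L, `1` = 2L, `2` = 3L)  # NA -> 1L

#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Supports the SNP-major layout only (mode byte `0x01`). `allele_a` is the
#' fifth BIM column and `allele_b` (the counted allele, code 2) the sixth,
#' matching the on-disk bit semantics `00` = homozygous first-column allele,
#' `11` = homozygous second-column allele. Non-autosomal variants are dropped
#' with a message.
#'
#' @param bed_path,bim_path,fam_path File paths.
#' @param autosomes Accepted chromosome labels (default `1:18`).
#' @return A [genotype_dataset()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path, autosomes = 1:18) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  autosomes <- as.character(autosomes)

  bim <- data.table::fread(bim_path, header = FALSE,
                           colClasses = list(character = c(1, 2, 5, 6)),
                           data.table = FALSE)
  if (ncol(bim) != 6L) stop("BIM must have 6 columns, got ", ncol(bim))
  names(bim) <- c("chrom", "id", "cm", "pos_bp", "a1", "a2")
  fam <- data.table::fread(fam_path, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2L) stop("FAM must have >= 2 columns")
  n_i <- nrow(fam); n_s <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != .bed_magic[1] || raw[2] != .bed_magic[2])
    stop("unsupported format: BED magic bytes are not 0x6C 0x1B")
  if (raw[3] != .bed_magic[3])
    stop("unsupported format: only SNP-major BED (mode byte 0x01) is supported")
  bpv <- ceiling(n_i / 4)
  expected <- 3L + bpv * n_s
  if (length(raw) != expected)
    stop(sprintf("truncated or oversized BED: expected %d bytes, found %d",
                 expected, length(raw)))

  payload <- raw[-(1:3)]
  # expand every byte into 4 two-bit codes, little-endian pairs
  m <- matrix(as.integer(payload), nrow = bpv, ncol = n_s)
  codes <- matrix(NA_integer_, n_i, n_s)
  lut <- .bed_decode_lut()
  for (shift in 0:3) {
    rows <- shift + 1L + 4L * (seq_len(bpv) - 1L)
    sel <- rows <= n_i
    if (!any(sel)) break
    two <- lut[[shift + 1L]][m + 1L]
    dim(two) <- dim(m)
    codes[rows[sel], ] <- two[sel, , drop = FALSE]
  }

  keep <- bim$chrom %in% autosomes & bim$pos_bp >= 1
  if (any(!keep))
    message(sum(!keep), " non-autosomal or unknown-position variant(s) dropped on load")
  variants <- data.frame(id = bim$id, chrom = bim$chrom, pos_bp = bim$pos_bp,
                         allele_a = bim$a1, allele_b = bim$a2,
                         stringsAsFactors = FALSE)[keep, , drop = FALSE]
  samples <- data.frame(sample_id = fam[[2]], breed = fam[[1]],
                        stringsAsFactors = FALSE)
  genotype_dataset(codes[, keep, drop = FALSE], variants, samples)
}

# lookup tables: for byte value 0..255 and lane 0..3, the genotype code
.bed_decode_lut <- function() {
  bytes <- 0:255
  lapply(0:3, function(shift) {
    two <- bitwAnd(bitwShiftR(bytes, 2L * shift), 3L)
    c(0L, NA_integer_, 1L, 2L)[two + 1L]
  })
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' SNP-major layout; re-reading with [read_plink_binary()] reproduces the
#' calls matrix exactly and a write-read-write cycle is byte-identical.
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.bed`, `.bim`, `.fam`.
#' @return Invisibly, the three file paths.
#' @export
write_plink_binary <- function(dataset, prefix) {
  if (dataset$n_i == 0L || dataset$n_s == 0L) stop("empty dataset")
  n_i <- dataset$n_i; n_s <- dataset$n_s
  v <- dataset$variants
  data.table::fwrite(
    data.frame(v$chrom, v$id, 0L, format(v$pos_bp, scientific = FALSE,
                                         trim = TRUE),
               v$allele_a, v$allele_b),
    paste0(prefix, ".bim"), sep = "\t", col.names = FALSE, quote = FALSE)
  data.table::fwrite(
    data.frame(dataset$samples$breed, dataset$samples$sample_id,
               0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = " ", col.names = FALSE, quote = FALSE)

  bpv <- ceiling(n_i / 4)
  pad <- 4L * bpv - n_i
  g <- dataset$calls
  two <- matrix(1L, 4L * bpv, n_s)  # padding lanes encode 01 = missing
  two[seq_len(n_i), ] <- ifelse(is.na(g), 1L,
                                .code_to_bits[as.character(g)])
  if (pad > 0) two[(n_i + 1L):(4L * bpv), ] <- 0L  # PLINK zero-pads
  lane <- matrix(two, nrow = 4L)
  bytes <- lane[1, ] + bitwShiftL(lane[2, ], 2L) +
    bitwShiftL(lane[3, ], 4L) + bitwShiftL(lane[4, ], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
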