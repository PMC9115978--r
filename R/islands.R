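#' Per-SNP ROH incidence for one breed
#'
#' For every post-QC SNP, the fraction of the breed's individuals whose
#' called ROH cover the SNP position.
#'
#' @param rohset A `roh_set`.
#' @param dataset The matching [genotype_dataset()].
#' @param breed Breed label.
#' @return `data.frame` with `chrom`, `pos_bp`, `snp_id`, `breed`,
#'   `incidence` in `[0, 1]`, ordered like the map.
#' @export
snp_incidence <- function(rohset, dataset, breed) {
  ids <- dataset$samples$sample_id[dataset$samples$breed == breed]
  if (!length(ids)) stop("unknown breed: ", breed)
  v <- dataset$variants
  segs <- as.data.frame(rohset)
  segs <- segs[segs$sample_id %in% ids, , drop = FALSE]
  hits <- integer(nrow(v))
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    pos <- v$pos_bp[vi]
    sc <- segs[segs$chrom == ch, , drop = FALSE]
    if (!nrow(sc)) next
    for (id in unique(sc$sample_id)) {
      s <- sc[sc$sample_id == id, , drop = FALSE]
      covered <- rep(FALSE, length(pos))
      for (r in seq_len(nrow(s)))
        covered <- covered | (pos >= s$start_bp[r] & pos <= s$end_bp[r])
      hits[vi] <- hits[vi] + covered
    }
  }
  data.frame(chrom = v$chrom, pos_bp = v$pos_bp, snp_id = v$id,
             breed = breed, incidence = hits / length(ids),
             stringsAsFactors = FALSE)
}

#' Call ROH islands from an incidence track
#'
#' Maximal runs of map-adjacent, same-chromosome SNPs with incidence at or
#' above the hotspot threshold (inclusive; a single below-threshold SNP
#' splits an island, and runs never span chromosomes).
#'
#' @param track Output of [snp_incidence()].
#' @param threshold Hotspot threshold in `(0, 1]` (default 0.40).
#' @return `data.frame` with `breed`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `peak_incidence`, plus a `snp_ids` list-column of member SNPs.
#' @export
call_islands <- function(track, threshold = 0.40) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    above <- t$incidence >= threshold
    if (!any(above)) next
    run_id <- cumsum(!above)
    for (r in split(which(above), run_id[above])) {
      out[[length(out) + 1L]] <- data.frame(
        breed = t$breed[1], chrom = ch,
        start_bp = t$pos_bp[r[1]], end_bp = t$pos_bp[r[length(r)]],
        n_snps = length(r), peak_incidence = max(t$incidence[r]),
        snp_ids = I(list(t$snp_id[r])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(breed = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), peak_incidence = numeric(),
                      snp_ids = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare island SNP sets between two sample groups
#'
#' A SNP belongs to a group's island set if it lies in any island of any
#' breed of the group. Returns the set sizes of the two unique sides and the
#' intersection.
#'
#' @param tracks_by_breed Named list of incidence tracks (one per breed).
#' @param group_map `data.frame` with columns `breed`, `group` (exactly two
#'   groups across the supplied breeds).
#' @param threshold Hotspot threshold passed to [call_islands()].
#' @return List with `groups`, `n_unique_1`, `n_unique_2`, `n_shared`, and
#'   the SNP id sets `unique_1`, `unique_2`, `shared`.
#' @export
compare_group_islands <- function(tracks_by_breed, group_map,
                                  threshold = 0.40) {
  groups <- unique(group_map$group[group_map$breed %in%
                                     names(tracks_by_breed)])
  if (length(groups) != 2) stop("need exactly two groups with >= 1 breed each")
  snp_set <- function(g) {
    breeds <- intersect(group_map$breed[group_map$group == g],
                        names(tracks_by_breed))
    if (!length(breeds)) stop("empty group: ", g)
    unique(unlist(lapply(breeds, function(b)
      unlist(call_islands(tracks_by_breed[[b]], threshold)$snp_ids))))
  }
  s1 <- snp_set(groups[1]); s2 <- snp_set(groups[2])
  list(groups = groups,
       n_unique_1 = length(setdiff(s1, s2)),
       n_unique_2 = length(setdiff(s2, s1)),
       n_shared = length(intersect(s1, s2)),
       unique_1 = setdiff(s1, s2), unique_2 = setdiff(s2, s1),
       shared = intersect(s1, s2))
}

#' Annotate islands against a feature interval file
#'
#' Reads features from BED (0-based half-open) or GFF3 (1-based inclusive)
#' via `rtracklayer`, normalises to 1-based inclusive coordinates, and
#' reports every (island, feature) pair overlapping by at least 1 bp, in
#' deterministic `(chrom, start, feature id)` order. Features on chromosomes
#' absent from the islands are skipped; island chromosomes absent from the
#' feature file are warned about.
#'
#' @param islands Output of [call_islands()].
#' @param feature_file Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return `data.frame` with island coordinates, `feature_id`,
#'   `feature_start`, `feature_end`, `overlap_bp`.
#' @export
annotate_islands <- function(islands, feature_file) {
  empty <- data.frame(breed = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      feature_id = character(), feature_start = numeric(),
                      feature_end = numeric(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(islands)) return(empty)
  feats <- rtracklayer::import(feature_file)
  fid <- .feature_ids(feats)
  isl_gr <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start_bp, islands$end_bp))
  missing_chrom <- setdiff(unique(islands$chrom),
                           as.character(GenomicRanges::seqnames(feats)))
  if (length(missing_chrom))
    warning("no features on chromosome(s): ",
            paste(missing_chrom, collapse = ", "))
  ov <- GenomicRanges::findOverlaps(isl_gr, feats, minoverlap = 1L)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::pintersect(isl_gr[qi], feats[si])
  out <- data.frame(breed = islands$breed[qi], chrom = islands$chrom[qi],
                    start_bp = islands$start_bp[qi],
                    end_bp = islands$end_bp[qi],
                    feature_id = fid[si],
                    feature_start = GenomicRanges::start(feats[si]),
                    feature_end = GenomicRanges::end(feats[si]),
                    overlap_bp = GenomicRanges::width(inter),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start_bp, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.feature_ids <- function(feats) {
  md <- S4Vectors::mcols(feats)
  for (col in c("name", "Name", "ID", "gene_id", "gene_name"))
    if (!is.null(md[[col]]) && !all(is.na(md[[col]])))
      return(as.character(md[[col]]))
  paste0("feature_", seq_along(feats))
}

#' Write incidence tracks or islands as TSV
#'
#' @param x A track, island table or annotation table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_island_table <- function(x, path) {
  x <- as.data.frame(x)
  if (!is.null(x$snp_ids))
    x$snp_ids <- vapply(x$snp_ids, paste, character(1), collapse = ",")
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
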