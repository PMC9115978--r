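.class_labels <- function(edges_mb) {
  k <- length(edges_mb)
  c(paste0(edges_mb[-k], "-", edges_mb[-1]), paste0(">", edges_mb[k]))
}

.classify_mb <- function(length_mb, edges_mb) {
  if (any(length_mb < edges_mb[1]))
    stop("segment shorter than the first class edge (", edges_mb[1], " Mb)")
  cut(length_mb, c(edges_mb, Inf), right = FALSE,
      labels = .class_labels(edges_mb))
}

.se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_

#' Per-breed ROH length-class table
#'
#' Bins each segment wholly into half-open physical length classes
#' `[lo, hi)` Mb (final class open-ended) and summarises, per breed: class
#' counts, the mean +/- SE and range of the per-individual ROH count
#' (individuals without any ROH count as zero), and the mean +/- SE and range
#' of segment length in Mb. Grand totals and, when sample groups are present,
#' per-class group shares are attached.
#'
#' @param rohset A `roh_set` from [detect_roh()].
#' @param samples Sample table (`sample_id`, `breed`, optional `group`);
#'   defaults to the table carried by `rohset`.
#' @param class_edges_mb Ascending class edges in Mb.
#' @return A list of class `length_class_table`: `by_breed` (data.frame),
#'   `class_totals`, `grand_total`, `group_class_counts`, `group_class_shares`
#'   (fractions summing to 1 within each class), `class_labels`.
#' @export
length_class_table <- function(rohset, samples = attr(rohset, "samples"),
                               class_edges_mb = c(1, 5, 10, 20, 40)) {
  if (is.null(samples)) stop("sample table required")
  labels <- .class_labels(class_edges_mb)
  df <- as.data.frame(rohset)
  df$class <- if (nrow(df)) .classify_mb(df$length_bp / 1e6, class_edges_mb)
              else factor(character(), levels = labels)
  breeds <- unique(samples$breed)

  rows <- lapply(breeds, function(b) {
    ids <- samples$sample_id[samples$breed == b]
    sb <- df[df$breed == b, , drop = FALSE]
    per_ind <- table(factor(sb$sample_id, levels = ids))
    len_mb <- sb$length_bp / 1e6
    cls <- table(factor(sb$class, levels = labels))
    out <- data.frame(breed = b, n_ind = length(ids), n_roh = nrow(sb),
                      mean_length_mb = if (nrow(sb)) mean(len_mb) else NA_real_,
                      se_length_mb = .se(len_mb),
                      min_length_mb = if (nrow(sb)) min(len_mb) else NA_real_,
                      max_length_mb = if (nrow(sb)) max(len_mb) else NA_real_,
                      mean_number = mean(per_ind), se_number = .se(c(per_ind)),
                      min_number = min(per_ind), max_number = max(per_ind),
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(rbind(c(cls))))
  })
  by_breed <- do.call(rbind, rows)
  names(by_breed)[(ncol(by_breed) - length(labels) + 1):ncol(by_breed)] <- labels

  class_totals <- colSums(by_breed[, labels, drop = FALSE])
  grand_total <- sum(class_totals)

  group_counts <- group_shares <- NULL
  if (!is.null(samples$group)) {
    gmap <- samples$group[match(by_breed$breed, samples$breed)]
    group_counts <- rowsum(as.matrix(by_breed[, labels, drop = FALSE]), gmap)
    denom <- rep(1, length(labels))
    denom[class_totals > 0] <- class_totals[class_totals > 0]
    group_shares <- sweep(group_counts, 2, denom, "/")
  }
  structure(list(by_breed = by_breed, class_totals = class_totals,
                 grand_total = grand_total,
                 group_class_counts = group_counts,
                 group_class_shares = group_shares,
                 class_labels = labels),
            class = "length_class_table")
}

#' @export
print.length_class_table <- function(x, ...) {
  cat("ROH length-class table (", x$grand_total, " segments)\n", sep = "")
  print(x$by_breed, digits = 4)
  invisible(x)
}

#' Aggregate per-breed ROH class counts
#'
#' Reporting helper over an already-tabulated counts matrix (breed x length
#' class, plus a `group` column): returns the grand total, per-class totals
#' and percentage shares of the total, per-group totals, and each group's
#' percentage share within every class.
#'
#' @param counts `data.frame` with columns `breed`, `group`, and one numeric
#'   column per length class.
#' @return A list: `grand_total`, `class_totals`, `class_shares_pct`,
#'   `group_totals`, `group_class_shares_pct` (rows groups, columns classes).
#' @export
aggregate_class_counts <- function(counts) {
  stopifnot(all(c("breed", "group") %in% names(counts)))
  cls <- setdiff(names(counts), c("breed", "group", "n_ind"))
  m <- as.matrix(counts[, cls, drop = FALSE])
  class_totals <- colSums(m)
  grand <- sum(class_totals)
  group_counts <- rowsum(m, counts$group)
  shares <- sweep(group_counts, 2, pmax(class_totals, 1), "/") * 100
  list(grand_total = grand,
       class_totals = class_totals,
       class_shares_pct = 100 * class_totals / grand,
       group_totals = rowSums(group_counts),
       group_class_counts = group_counts,
       group_class_shares_pct = shares)
}

#' Bundled per-breed ROH length-class counts
#'
#' Example counts for ten pig breeds (five Anhui indigenous, five Western
#' commercial; PorcineSNP80k post-QC data) across the five standard length
#' classes. Breeds where a class held no segment are recorded as zero.
#'
#' @return `data.frame` with `breed`, `group`, `n_ind` and five class-count
#'   columns.
#' @export
example_breed_class_counts <- function() {
  path <- system.file("extdata", "pig_breed_roh_class_counts.tsv",
                      package = "rohscan", mustWork = TRUE)
  data.table::fread(path, data.table = FALSE)
}

#' Per-breed chromosome coverage by ROH
#'
#' Coverage of a chromosome for a breed is the mean over the breed's
#' individuals of (bp covered by the individual's ROH on that chromosome) /
#' (chromosome span from first to last mapped SNP). Chromosomes carrying
#' fewer than two SNPs are flagged undefined (`NA`).
#'
#' @param rohset A `roh_set`.
#' @param dataset The matching [genotype_dataset()].
#' @return `data.frame` with `breed`, `chrom`, `coverage` in `[0, 1]`.
#' @export
chromosome_coverage <- function(rohset, dataset) {
  samples <- dataset$samples
  df <- as.data.frame(rohset)
  chroms <- unique(dataset$variants$chrom)
  spans <- vapply(chroms, function(ch) {
    p <- dataset$variants$pos_bp[dataset$variants$chrom == ch]
    if (length(p) < 2) NA_real_ else max(p) - min(p) + 1
  }, numeric(1))
  out <- expand.grid(breed = unique(samples$breed), chrom = chroms,
                     stringsAsFactors = FALSE)
  out$coverage <- mapply(function(b, ch) {
    span <- spans[[match(ch, chroms)]]
    if (is.na(span)) return(NA_real_)
    ids <- samples$sample_id[samples$breed == b]
    segs <- df[df$breed == b & df$chrom == ch, , drop = FALSE]
    per <- vapply(ids, function(id) {
      s <- segs[segs$sample_id == id, , drop = FALSE]
      sum(s$end_bp - s$start_bp + 1)
    }, numeric(1))
    mean(per) / span
  }, out$breed, out$chrom)
  out
}
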