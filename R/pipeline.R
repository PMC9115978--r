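#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Stages communicate through
#' TSV/PLINK artifacts in `out_dir`, so each stage is independently testable
#' and resumable.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param input_prefix PLINK file prefix of an existing cohort, or `NULL`
#'   to simulate one.
#' @param input_dialect `"binary"` (BED/BIM/FAM) or `"text"` (PED/MAP).
#' @param group_map_path Optional two-column TSV (`breed`, `group`).
#' @param sim A [sim_config()] used when `input_prefix` is `NULL`.
#' @param qc A [qc_thresholds()].
#' @param roh A [roh_params()].
#' @param island_threshold Hotspot threshold.
#' @param feature_file Optional BED/GFF3 features for island annotation.
#' @param pca_k Number of principal components.
#' @param autosomes Accepted chromosome labels.
#' @param seed Seed forwarded to the simulator.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input_prefix = NULL,
                            input_dialect = c("binary", "text"),
                            group_map_path = NULL,
                            sim = sim_config(seed = seed),
                            qc = qc_thresholds(), roh = roh_params(),
                            island_threshold = 0.40, feature_file = NULL,
                            pca_k = 3, autosomes = 1:18, seed = 1L) {
  input_dialect <- match.arg(input_dialect)
  if (island_threshold <= 0 || island_threshold > 1)
    stop("island_threshold must be in (0, 1]")
  if (!is.null(input_prefix)) {
    ext <- if (input_dialect == "binary") c(".bed", ".bim", ".fam")
           else c(".ped", ".map")
    missing <- !file.exists(paste0(input_prefix, ext))
    if (any(missing))
      stop("missing input file(s): ",
           paste(paste0(input_prefix, ext)[missing], collapse = ", "))
  }
  structure(list(out_dir = out_dir, input_prefix = input_prefix,
                 input_dialect = input_dialect,
                 group_map_path = group_map_path, sim = sim, qc = qc,
                 roh = roh, island_threshold = island_threshold,
                 feature_file = feature_file, pca_k = pca_k,
                 autosomes = autosomes, seed = seed),
            class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Recognised keys: `out_dir`, `input_prefix`, `input_dialect`,
#' `group_map_path`, `feature_file`, `island_threshold`, `pca_k`, `seed`,
#' any [qc_thresholds()] field prefixed `qc.`, any [roh_params()] field
#' prefixed `roh.`, and any scalar [sim_config()] field prefixed `sim.`.
#'
#' @param path Configuration file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  get <- function(k, default = NULL, num = FALSE) {
    if (!k %in% keys) return(default)
    v <- vals[match(k, keys)]
    if (num) as.numeric(v) else v
  }
  sub_args <- function(prefix, numeric = TRUE) {
    sel <- startsWith(keys, prefix)
    out <- lapply(vals[sel], function(v) {
      x <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (anyNA(x)) v else x
    })
    names(out) <- substring(keys[sel], nchar(prefix) + 1)
    out
  }
  seed <- as.integer(get("seed", 1, num = TRUE))
  pipeline_config(
    out_dir = get("out_dir", stop("config must set out_dir")),
    input_prefix = get("input_prefix"),
    input_dialect = get("input_dialect", "binary"),
    group_map_path = get("group_map_path"),
    feature_file = get("feature_file"),
    island_threshold = get("island_threshold", 0.40, num = TRUE),
    pca_k = get("pca_k", 3, num = TRUE),
    seed = seed,
    sim = do.call(sim_config, c(list(seed = seed), sub_args("sim."))),
    qc = do.call(qc_thresholds, sub_args("qc.")),
    roh = do.call(roh_params, sub_args("roh.")))
}

.artifact <- function(config, name) file.path(config$out_dir, name)

.require_artifact <- function(config, name, stage) {
  p <- .artifact(config, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact %s: run stage '%s' first", p, stage))
  p
}

.load_qcd <- function(config) {
  read_plink_binary(.require_artifact(config, "qcd.bed", "qc"),
                    .artifact(config, "qcd.bim"),
                    .artifact(config, "qcd.fam"),
                    autosomes = config$autosomes)
}

.read_groups <- function(config) {
  p <- config$group_map_path
  if (is.null(p)) p <- .artifact(config, "breed_groups.tsv")
  if (!file.exists(p)) return(NULL)
  data.table::fread(p, data.table = FALSE, colClasses = "character")
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (or load external input), `qc`, `roh`, `inbreed`,
#' `islands`, `pca`, `report`. Each stage reads the previous stage's
#' artifacts from `out_dir` and fails with an actionable error naming the
#' required prior stage when they are absent. A run manifest
#' (`manifest.tsv`) accumulates parameter values, artifact checksums and the
#' package version.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- switch(
    stage,
    simulate = {
      if (is.null(config$input_prefix)) {
        config$sim$seed <- config$seed
        simulate_cohort(config$sim, dir = config$out_dir)
        .artifact(config, c("cohort.bed", "cohort.bim", "cohort.fam",
                            "breed_groups.tsv", "truth_tracts.tsv",
                            "truth_fstar.tsv"))
      } else {
        ds <- if (config$input_dialect == "binary")
          read_plink_binary(paste0(config$input_prefix, ".bed"),
                            paste0(config$input_prefix, ".bim"),
                            paste0(config$input_prefix, ".fam"),
                            autosomes = config$autosomes)
        else
          read_plink_text(paste0(config$input_prefix, ".ped"),
                          paste0(config$input_prefix, ".map"),
                          autosomes = config$autosomes)
        write_plink_binary(ds, .artifact(config, "cohort"))
      }
    },
    qc = {
      ds <- read_plink_binary(
        .require_artifact(config, "cohort.bed", "simulate"),
        .artifact(config, "cohort.bim"), .artifact(config, "cohort.fam"),
        autosomes = config$autosomes)
      gm <- .read_groups(config)
      if (!is.null(gm))
        ds$samples$group <- gm$group[match(ds$samples$breed, gm$breed)]
      res <- apply_qc(ds, config$qc)
      write_plink_binary(res$dataset, .artifact(config, "qcd"))
      write_qc_report(res$report, .artifact(config, "qc_report.tsv"))
      .artifact(config, c("qcd.bed", "qcd.bim", "qcd.fam", "qc_report.tsv"))
    },
    roh = {
      ds <- .load_qcd(config)
      st <- allele_stats(ds)
      l_advisory <- min_roh_snps(config$roh$alpha, ds$n_s, ds$n_i,
                                 min(max(st$het, 1e-6), 1 - 1e-6))
      message("Lencz advisory minimum SNPs per ROH: ", l_advisory,
              " (using params.min_snps = ", config$roh$min_snps, ")")
      rs <- detect_roh(ds, config$roh)
      write_roh_segments(rs, .artifact(config, "roh_segments.tsv"))
      .artifact(config, "roh_segments.tsv")
    },
    inbreed = {
      ds <- .load_qcd(config)
      rs <- .read_rohset(config)
      rec <- inbreeding_records(ds, rs)
      data.table::fwrite(rec, .artifact(config, "inbreeding.tsv"),
                         sep = "\t")
      data.table::fwrite(breed_summaries(rec),
                         .artifact(config, "breed_inbreeding.tsv"),
                         sep = "\t")
      .artifact(config, c("inbreeding.tsv", "breed_inbreeding.tsv"))
    },
    islands = {
      ds <- .load_qcd(config)
      rs <- .read_rohset(config)
      tracks <- lapply(unique(ds$samples$breed), snp_incidence,
                       rohset = rs, dataset = ds)
      names(tracks) <- unique(ds$samples$breed)
      data.table::fwrite(do.call(rbind, tracks),
                         .artifact(config, "roh_incidence.tsv"), sep = "\t")
      isl <- do.call(rbind, lapply(tracks, call_islands,
                                   threshold = config$island_threshold))
      write_island_table(isl, .artifact(config, "roh_islands.tsv"))
      out <- .artifact(config, c("roh_incidence.tsv", "roh_islands.tsv"))
      if (!is.null(config$feature_file)) {
        write_island_table(annotate_islands(isl, config$feature_file),
                           .artifact(config, "island_annotation.tsv"))
        out <- c(out, .artifact(config, "island_annotation.tsv"))
      }
      out
    },
    pca = {
      ds <- .load_qcd(config)
      grm <- build_grm(ds)
      write_grm(grm, .artifact(config, "cohort"))
      pc <- grm_pca(grm, k = config$pca_k)
      scores <- data.frame(sample_id = grm$sample_id,
                           breed = ds$samples$breed, pc$scores)
      data.table::fwrite(scores, .artifact(config, "pca_scores.tsv"),
                         sep = "\t")
      .artifact(config, c("cohort.grm.txt", "cohort.grm.id",
                          "pca_scores.tsv"))
    },
    report = {
      ds <- .load_qcd(config)
      rs <- .read_rohset(config)
      .require_artifact(config, "inbreeding.tsv", "inbreed")
      rec <- data.table::fread(.artifact(config, "inbreeding.tsv"),
                               data.table = FALSE)
      lct <- length_class_table(rs, samples = ds$samples)
      tab1 <- lct$by_breed
      data.table::fwrite(tab1, .artifact(config, "table1_like.tsv"),
                         sep = "\t")
      data.table::fwrite(breed_summaries(rec),
                         .artifact(config, "table2_like.tsv"), sep = "\t")
      if (!is.null(lct$group_class_shares)) {
        gs <- as.data.frame(as.table(lct$group_class_shares * 100))
        names(gs) <- c("group", "class", "share_pct")
        data.table::fwrite(gs, .artifact(config, "group_shares.tsv"),
                           sep = "\t")
      }
      if (lct$grand_total == 0)
        warning("report generated over an empty ROH set")
      .artifact(config, c("table1_like.tsv", "table2_like.tsv",
                          "group_shares.tsv"))
    },
    stop("unknown stage: ", stage))
  .update_manifest(config, stage, written)
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_rohset <- function(config) {
  p <- .require_artifact(config, "roh_segments.tsv", "roh")
  df <- data.table::fread(p, data.table = FALSE,
                          colClasses = list(character = c("sample_id",
                                                          "breed", "chrom")))
  df$length_bp <- df$end_bp - df$start_bp + 1
  ds_samples <- data.table::fread(.require_artifact(config, "qcd.fam", "qc"),
                                  header = FALSE, data.table = FALSE,
                                  colClasses = "character")
  samples <- data.frame(sample_id = ds_samples[[2]], breed = ds_samples[[1]],
                        stringsAsFactors = FALSE)
  gm <- .read_groups(config)
  if (!is.null(gm))
    samples$group <- gm$group[match(samples$breed, gm$breed)]
  attr(df, "samples") <- samples
  class(df) <- c("roh_set", "data.frame")
  df
}

.update_manifest <- function(config, stage, files) {
  files <- files[file.exists(files)]
  rows <- data.frame(
    stage = stage, file = basename(files),
    md5 = as.character(tools::md5sum(files)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rohscan")),
    stringsAsFactors = FALSE)
  path <- .artifact(config, "manifest.tsv")
  old <- if (file.exists(path))
    data.table::fread(path, data.table = FALSE, colClasses = "character")
  else NULL
  if (!is.null(old)) old <- old[old$stage != stage, , drop = FALSE]
  data.table::fwrite(rbind(old, rows), path, sep = "\t")
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Chains `simulate` (or external load) -> `qc` -> `roh` -> `inbreed` ->
#' `islands` -> `pca` -> `report`. Deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @param stages Stage names, or `"all"`.
#' @return Invisibly, a named list of artifact paths per stage.
#' @export
run_pipeline <- function(config, stages = "all") {
  all_stages <- c("simulate", "qc", "roh", "inbreed", "islands", "pca",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- lapply(stages, run_stage, config = config)
  names(out) <- stages
  invisible(out)
}
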