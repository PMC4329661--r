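#' Load and validate a pipeline run configuration
#'
#' The configuration is a single YAML file (or an equivalent named list)
#' whose defaults are the published conventions of the analysis: E-value
#' threshold 1e-5, identity retention floor 0.55, high-identity counting
#' threshold 0.90, pseudocount 1, minimum summed relative abundance
#' 1e-4, unique-gene-tag threshold 5, 10 rarefaction replicates.
#' An empty override block therefore reproduces the standard analysis.
#'
#' Recognized top-level blocks (all optional except `out_dir`):
#' \describe{
#'   \item{seed}{integer; all randomness flows from it (default 1).}
#'   \item{out_dir}{output directory, created if needed.}
#'   \item{totals}{dataset read totals used for smallest-dataset
#'     normalization and percentages.}
#'   \item{simulate}{synthetic community block: `sample_id`, `n_reads`,
#'     `read_length_mean`, `read_length_sd`, `duplicate_rate`,
#'     `gc_dup_coupling`, and a `genomes` list of `{id, length, gc,
#'     abundance, divergence, lineage}` entries.}
#'   \item{reads}{path to an existing FASTA/FASTQ (alternative to
#'     `simulate`).}
#'   \item{qc}{`prefix_len`, `length_tolerance`, `gc_z`.}
#'   \item{profiles}{`taxonomic` / `functional` assignment TSV paths per
#'     sample, `rank`, `evalue`, plus scatter/unique/rarefaction knobs.}
#'   \item{recruit}{`references` FASTA path (or inline via `simulate`),
#'     optional `blast6` hits path, optional `counts` TSV
#'     (`genome_id`, `n_ge_high`) for ranking-only runs, `floor`,
#'     `high`, `k`.}
#' }
#'
#' @param x path to a YAML file, or a named list.
#' @return a validated `RunConfig` list (class `RunConfig`).
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x)
         else if (is.list(x)) x
         else mc_stop("config must be a YAML path or a named list")
  defaults <- list(seed = 1L, evalue = 1e-5, floor = 0.55, high = 0.90,
                   pseudocount = 1, min_rel_sum = 1e-4, unique_min = 5,
                   rarefaction_reps = 10L, qc = list())
  for (n in names(defaults))
    if (is.null(cfg[[n]])) cfg[[n]] <- defaults[[n]]
  if (is.null(cfg$out_dir)) mc_stop("config error: 'out_dir' is required")
  with(cfg, {
    if (floor < 0 || floor > 1 || high < 0 || high > 1 || high < floor)
      mc_stop("config error: need 0 <= floor <= high <= 1")
    if (evalue <= 0) mc_stop("config error: 'evalue' must be > 0")
    if (pseudocount < 0) mc_stop("config error: 'pseudocount' must be >= 0")
  })
  structure(cfg, class = "RunConfig")
}

#' Serialize a run configuration
#'
#' Configurations round-trip through YAML unchanged (up to numeric
#' representation), so a run can always be reproduced from the config
#' echoed into its output directory.
#'
#' @param cfg a `RunConfig`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[metacompare:%s] %s", stage, sprintf(fmt, ...)))
}

#' Execute the full analysis pipeline from one configuration
#'
#' Runs the configured stages in fixed order — simulate (optional), read
#' QC, profile comparison, fragment recruitment — writing every output
#' under `out_dir` and returning a manifest of all files written with
#' their MD5 checksums, the package version, and the seed. Identical
#' configurations produce identical manifests. On failure, files written
#' by the failed run are removed.
#'
#' @param config a `RunConfig`, YAML path, or named list.
#' @return invisibly, the manifest data.frame (`file`, `md5`); also
#'   written to `out_dir/manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(writer, ..., file) {
    path <- file.path(cfg$out_dir, file)
    writer(..., path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)

  genomes <- NULL; rs <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    genomes <- lapply(sim$genomes, function(g) {
      lin <- if (!is.null(g$lineage)) unlist(g$lineage)
             else c(superkingdom = "Bacteria")
      generate_genome(g$length, if (is.null(g$gc)) 0.5 else g$gc,
                      seed = cfg$seed + match(g$id,
                        vapply(sim$genomes, `[[`, "", "id")),
                      id = g$id, taxon_lineage = lin)
    })
    ab <- vapply(sim$genomes, function(g)
      if (is.null(g$abundance)) 1 / length(sim$genomes) else g$abundance, 0)
    dv <- vapply(sim$genomes, function(g)
      if (is.null(g$divergence)) 0 else g$divergence, 0)
    spec <- community_spec(
      genomes, ab / sum(ab), dv,
      read_length_mean = sim$read_length_mean %||% 387,
      read_length_sd = sim$read_length_sd %||% 50,
      n_reads = sim$n_reads %||% 1000L,
      duplicate_rate = sim$duplicate_rate %||% 0,
      gc_dup_coupling = sim$gc_dup_coupling %||% 0,
      sample_id = sim$sample_id %||% "sim", seed = cfg$seed)
    rs <- simulate_reads(spec)
    pipeline_log("simulate", "seed=%d reads=%d genomes=%d", cfg$seed,
                 rs$total_count, length(genomes))
    emit(write_reads, rs, file = "simulated_reads.fasta")
    emit(write_ground_truth, rs, file = "ground_truth.tsv")
    emit(write_genomes, genomes, file = "reference_genomes.fasta")
    emit(write_taxonomy, genomes, file = "reference_taxonomy.tsv")
  } else if (!is.null(cfg$reads)) {
    if (!file.exists(cfg$reads))
      mc_stop("missing input: ", cfg$reads)
    rs <- read_reads(cfg$reads)
  }

  if (!is.null(rs)) {
    qc <- run_qc(rs,
                 prefix_len = cfg$qc$prefix_len %||% 50L,
                 length_tolerance = cfg$qc$length_tolerance %||% 0.02,
                 z_cutoff = cfg$qc$gc_z %||% 3)
    pipeline_log("qc", "seed=%d in=%d dup=%d gc=%d out=%d", cfg$seed,
                 qc$report$input_reads, qc$report$duplicates_removed,
                 qc$report$gc_outliers_removed, qc$report$output_reads)
    emit(write_reads, qc$reads, file = "filtered_reads.fasta")
    emit(write_qc_report, qc$report, file = "qc_report.tsv")
    rs <- qc$reads
  }

  if (!is.null(cfg$profiles)) {
    pr <- cfg$profiles
    paths <- pr$taxonomic
    if (is.null(paths) || length(paths) < 2L)
      mc_stop("config error: profiles$taxonomic needs two sample tables")
    for (p in unlist(paths)) if (!file.exists(p)) mc_stop("missing input: ", p)
    rank <- pr$rank %||% "family"
    totals <- unlist(cfg$totals)
    if (is.null(totals) || length(totals) < 2L)
      mc_stop("config error: 'totals' required for profile comparison")
    recs <- lapply(paths, function(p)
      filter_by_evalue(read_assignments(p), cfg$evalue))
    profs <- mapply(function(r, tot, id) build_profile(r, rank, tot, id),
                    recs, as.list(totals[seq_along(recs)]),
                    as.list(names(paths) %||%
                              paste0("sample", seq_along(recs))),
                    SIMPLIFY = FALSE)
    norm <- normalize_to_smallest(profs)
    for (i in seq_along(norm))
      emit(write_profile, norm[[i]],
           file = sprintf("profile_%s_%s.tsv", norm[[i]]$sample_id, rank))
    sp <- scatter_points(norm[[1L]], norm[[2L]], cfg$pseudocount,
                         cfg$min_rel_sum)
    emit(write_recruitment_summary, sp, file = "scatter_points.tsv")
    uq <- unique_egts(norm[[1L]], norm[[2L]], cfg$unique_min)
    emit(function(x, path) {
      df <- data.frame(
        taxon = c(x$unique_to_a, x$unique_to_b),
        unique_to = rep(c(norm[[1L]]$sample_id, norm[[2L]]$sample_id),
                        c(length(x$unique_to_a), length(x$unique_to_b))))
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }, uq, file = "unique_egts.tsv")
    for (i in seq_along(recs)) {
      rc <- rarefy_assignments(recs[[i]], rank,
                               reps = cfg$rarefaction_reps,
                               seed = cfg$seed + i)
      emit(write_rarefaction, rc,
           file = sprintf("rarefaction_%s_%s.tsv", norm[[i]]$sample_id, rank))
    }
    pipeline_log("profiles", "rank=%s taxa=%d scatter_points=%d", rank,
                 length(union(names(norm[[1L]]$counts),
                              names(norm[[2L]]$counts))), nrow(sp))
  }

  if (!is.null(cfg$recruit)) {
    rec <- cfg$recruit
    totals <- unlist(cfg$totals)
    if (is.null(totals))
      mc_stop("config error: 'totals' required for recruitment")
    if (!is.null(rec$counts)) {
      if (!file.exists(rec$counts)) mc_stop("missing input: ", rec$counts)
      cn <- read.delim(rec$counts, stringsAsFactors = FALSE)
      rank_tbl <- data.frame(
        genome_id = cn$genome_id, n_ge_high = cn$n_ge_high,
        percentage = percentage_of_total(cn$n_ge_high, totals))
      rank_tbl <- rank_tbl[order(-rank_tbl$n_ge_high, rank_tbl$genome_id), ]
      emit(write_recruitment_summary, rank_tbl, file = "ranking.tsv")
      pipeline_log("recruit", "ranking-only mode, %d genomes", nrow(rank_tbl))
    } else {
      refs <- if (!is.null(rec$references)) {
        if (!file.exists(rec$references))
          mc_stop("missing input: ", rec$references)
        read_genomes(rec$references)
      } else genomes
      if (is.null(refs) || is.null(rs))
        mc_stop("config error: recruitment needs reads and references")
      hits <- if (!is.null(rec$blast6)) {
        if (!file.exists(rec$blast6)) mc_stop("missing input: ", rec$blast6)
        read_blast6(rec$blast6,
                    setNames(nchar(rs$reads$sequence), rs$reads$id))
      } else if (rs$total_count == 0L) {
        data.frame(read_id = character(), genome_id = character(),
                   identical_bases = integer(), read_length = integer(),
                   subject_start = integer(), subject_end = integer(),
                   strand = character(), score = integer(),
                   stringsAsFactors = FALSE)
      } else align_reads(rs, refs, k = rec$k %||% 15L)
      hits <- best_hit_per_read(filter_hits(hits, cfg$floor))
      summ <- summarize_recruitment(hits, totals, cfg$high, rec$top_k)
      emit(write_recruitment_summary, summ, file = "ranking.tsv")
      emit(write_recruitment_summary, recruitment_points(hits),
           file = "recruitment_points.tsv")
      hist <- identity_histogram(hits, totals, min(totals), rs$sample_id)
      emit(write_histogram, hist, file = "histogram.tsv")
      pipeline_log("recruit", "seed=%d hits=%d genomes=%d", cfg$seed,
                   nrow(hits), nrow(summ))
    }
  }

  emit(write_run_config, cfg, file = "config.yaml")
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  mpath <- file.path(cfg$out_dir, "manifest.tsv")
  write.table(cbind(manifest,
                    version = as.character(utils::packageVersion("metacompare")),
                    seed = cfg$seed),
              mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- TRUE
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
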