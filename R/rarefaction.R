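#' Monte-Carlo rarefaction of taxon richness
#'
#' Estimates mean taxon richness as a function of subsampling depth by
#' repeated random subsampling without replacement of the assigned reads.
#' Each replicate draws one random permutation of the reads and reports,
#' at every depth, the number of distinct taxa among the first `depth`
#' reads — a collector's-curve design, so every replicate's curve is
#' non-decreasing in depth while each depth is still a uniform
#' without-replacement subsample (the expectation follows the
#' hypergeometric closed form, see [rarefaction_expected()]).
#'
#' @param records data.frame of assignment records with `taxon` (or
#'   `pfam_acc`) and optionally `rank` columns; only records at `rank`
#'   are used when a `rank` column is present.
#' @param rank rank label (or `"pfam"`).
#' @param depths increasing integer subsample depths; default 10 evenly
#'   spaced depths up to the number of assigned reads.
#' @param reps number of Monte-Carlo replicates (default 10).
#' @param seed integer RNG seed.
#' @return an object of class `RarefactionCurve`: list with
#'   `rank_or_unit`, `depths`, `mean_richness`, `sd_richness`,
#'   `richness` (reps x depths matrix), `reps`, `seed`.
#' @export
rarefy_assignments <- function(records, rank, depths = NULL, reps = 10L,
                               seed = 1L) {
  unit <- if ("taxon" %in% names(records)) "taxon" else "pfam_acc"
  if ("rank" %in% names(records))
    records <- records[records$rank == rank, , drop = FALSE]
  taxa <- records[[unit]]
  n <- length(taxa)
  if (n == 0L) mc_stop("no assigned reads at rank '", rank, "'")
  if (reps < 1L) mc_stop("'reps' must be >= 1")
  if (is.null(depths))
    depths <- unique(pmax(1L, round(seq(n / 10, n, length.out = 10L))))
  depths <- as.integer(sort(unique(depths)))
  if (any(depths < 1L) || any(depths > n))
    mc_stop("'depths' must lie in [1, number of assigned reads]")
  rich <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(reps), function(r) {
      perm <- taxa[sample.int(n)]
      cum_rich <- cumsum(!duplicated(perm))
      cum_rich[depths]
    }, numeric(length(depths))))
  })
  structure(list(rank_or_unit = rank, depths = depths,
                 mean_richness = colMeans(rich),
                 sd_richness = apply(rich, 2L, sd),
                 richness = rich, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "RarefactionCurve")
}

#' @export
print.RarefactionCurve <- function(x, ...) {
  cat(sprintf(
    "<RarefactionCurve @%s: %d depths up to %s, %d reps, final richness %.1f>\n",
    x$rank_or_unit, length(x$depths),
    format(max(x$depths), big.mark = ","), x$reps,
    x$mean_richness[length(x$mean_richness)]))
  invisible(x)
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' For a profile with taxon counts `N_i` summing to `N`, the expected
#' number of distinct taxa in a uniform without-replacement subsample of
#' size `n` is `sum_i (1 - choose(N - N_i, n) / choose(N, n))`. Computed
#' on the log scale for numerical stability.
#'
#' @param counts (named) non-negative integer vector of taxon counts.
#' @param n subsample depth(s), each in `[0, sum(counts)]`.
#' @return numeric vector of expected richness values, one per depth.
#' @export
rarefaction_expected <- function(counts, n) {
  N <- sum(counts)
  vapply(n, function(d) {
    if (d > N) mc_stop("depth exceeds total count")
    sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  }, 0)
}

#' Export a rarefaction curve as TSV
#'
#' @param curve a `RarefactionCurve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rarefaction <- function(curve, path) {
  stopifnot(inherits(curve, "RarefactionCurve"))
  df <- data.frame(depth = curve$depths,
                   mean_richness = curve$mean_richness,
                   sd_richness = curve$sd_richness)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
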