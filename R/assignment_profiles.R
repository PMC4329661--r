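#' Read per-read assignment tables
#'
#' Taxonomic tables carry columns `read_id, rank, taxon, evalue`;
#' functional tables carry `read_id, pfam_acc, superkingdom, evalue`
#' (the output format of read-classifier pipelines such as CARMA-style
#' environmental-gene-tag annotation, consumed here as plain TSV).
#'
#' @param path TSV file with header.
#' @return a data.frame.
#' @export
read_assignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "evalue")
  if (!all(need %in% names(df)))
    mc_stop("assignment table must have columns 'read_id' and 'evalue'")
  if (!("taxon" %in% names(df)) && !("pfam_acc" %in% names(df)))
    mc_stop("assignment table must have a 'taxon' or 'pfam_acc' column")
  if ("pfam_acc" %in% names(df) &&
      !all(grepl("^PF\\d{5}$", df$pfam_acc)))
    mc_stop("'pfam_acc' entries must match PFxxxxx")
  if (any(!is.finite(df$evalue) | df$evalue <= 0))
    mc_stop("'evalue' must be finite and positive")
  df
}

#' Filter assignment records by E-value
#'
#' Retains records whose E-value is at or below the threshold (boundary
#' inclusive: an E-value of exactly 1e-5 is kept at the default threshold).
#'
#' @param records data.frame with an `evalue` column.
#' @param threshold positive E-value cutoff (default `1e-5`).
#' @return the filtered data.frame.
#' @export
filter_by_evalue <- function(records, threshold = 1e-5) {
  if (!is.numeric(threshold) || threshold <= 0)
    mc_stop("'threshold' must be > 0")
  records[records$evalue <= threshold, , drop = FALSE]
}

#' Build a count profile at one taxonomic rank
#'
#' Counts the reads assigned to each taxon at `rank`. `total_reads` is the
#' profile's denominator for relative abundances and normalization; reads
#' without an assignment at this rank contribute to the denominator only.
#' Each read may carry at most one assignment per rank; a duplicated
#' read id at the same rank is a hard error naming the read.
#'
#' @param records data.frame with columns `read_id`, `taxon` (or
#'   `pfam_acc`), and optionally `rank`.
#' @param rank rank label to subset on when a `rank` column is present; use
#'   `"pfam"` for functional records.
#' @param total_reads dataset size the counts are relative to.
#' @param sample_id sample label.
#' @return an object of class `Profile`.
#' @export
build_profile <- function(records, rank, total_reads, sample_id = "sample") {
  if (!is_count(total_reads) || total_reads < 0)
    mc_stop("'total_reads' must be a non-negative integer")
  unit <- if ("taxon" %in% names(records)) "taxon" else "pfam_acc"
  if ("rank" %in% names(records))
    records <- records[records$rank == rank, , drop = FALSE]
  if (nrow(records)) {
    dup <- records$read_id[duplicated(records$read_id)]
    if (length(dup))
      mc_stop("read '", dup[1L], "' has multiple assignments at rank '",
              rank, "'")
    if (nrow(records) > total_reads)
      mc_stop("more assigned reads than 'total_reads'")
  }
  cnt <- table(records[[unit]])
  profile(sample_id, rank,
          setNames(as.numeric(cnt), names(cnt)), total_reads)
}

#' Profile constructor
#'
#' @param sample_id sample label.
#' @param rank rank label (or `"pfam"`).
#' @param counts named non-negative numeric vector (taxon -> count; real
#'   after normalization).
#' @param total_reads denominator for relative abundances.
#' @return an object of class `Profile`.
#' @export
profile <- function(sample_id, rank, counts, total_reads) {
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    mc_stop("'counts' must be a named vector")
  if (any(counts < 0)) mc_stop("'counts' must be non-negative")
  if (any(counts > total_reads))
    mc_stop("no count may exceed 'total_reads'")
  structure(list(sample_id = sample_id, rank = rank,
                 counts = counts, total_reads = total_reads),
            class = "Profile")
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("<Profile %s @%s: %d taxa, %s assigned of %s reads>\n",
              x$sample_id, x$rank, length(x$counts),
              format(round(sum(x$counts)), big.mark = ","),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Relative abundances of a profile
#'
#' @param p a `Profile`.
#' @return named numeric vector `counts / total_reads`.
#' @export
relative_abundance <- function(p) {
  stopifnot(inherits(p, "Profile"))
  p$counts / p$total_reads
}

#' Normalize profiles to the smallest dataset
#'
#' Scales every profile's counts by `N_min / total_reads`, where `N_min`
#' is the smallest `total_reads` among the profiles, and sets all totals
#' to `N_min`. This makes counts from samples of unequal sequencing depth
#' directly comparable; within-sample relative abundances are preserved
#' exactly, and the smallest profile is returned unchanged. Counts become
#' real-valued.
#'
#' @param profiles list of >= 2 `Profile` objects with positive totals.
#' @return list of normalized `Profile` objects, in input order.
#' @export
normalize_to_smallest <- function(profiles) {
  if (length(profiles) < 2L)
    mc_stop("need at least two profiles to normalize")
  stopifnot(all(vapply(profiles, inherits, TRUE, "Profile")))
  totals <- vapply(profiles, `[[`, 0, "total_reads")
  if (any(totals <= 0)) mc_stop("all profile totals must be > 0")
  ## keep the smallest profile's own total (and storage type) as N_min
  n_min <- profiles[[which.min(totals)]]$total_reads
  lapply(profiles, function(p) {
    if (p$total_reads == n_min) return(p)
    profile(p$sample_id, p$rank, p$counts * (n_min / p$total_reads), n_min)
  })
}

#' Percentage of the smallest dataset total
#'
#' Reports `100 * count / min(totals)`, rounded half-up to two decimals —
#' the convention under which recruited-read counts are expressed as
#' percentages of the smaller of the two compared datasets, for both
#' samples.
#'
#' @param count non-negative numeric (vectorized).
#' @param totals positive integer vector of dataset totals.
#' @return percentage(s) rounded to 2 decimals.
#' @export
percentage_of_total <- function(count, totals) {
  if (!length(totals) || any(totals <= 0))
    mc_stop("'totals' must be non-empty and positive")
  if (any(count < 0)) mc_stop("'count' must be non-negative")
  round_half_up(100 * count / min(totals), 2)
}

#' Log-abundance scatter data for two normalized profiles
#'
#' For each taxon (or Pfam family) present in either profile, returns the
#' pseudocounted log10 normalized counts of the two samples, suitable for
#' an abundance scatter plot. A pseudocount of one is added before the
#' logarithm so absent taxa map to `log10(1) = 0`. Taxa are retained only
#' if the sum over the two samples of each sample's own relative
#' abundance reaches `min_rel_sum` (default 0.01%).
#'
#' @param a,b `Profile` objects normalized to the same total (see
#'   [normalize_to_smallest()]).
#' @param pseudocount added to each count before `log10` (default 1).
#' @param min_rel_sum minimum summed relative abundance (default `1e-4`).
#' @return data.frame with columns `taxon`, `x`, `y` (log10 counts for
#'   `a` and `b`).
#' @export
scatter_points <- function(a, b, pseudocount = 1, min_rel_sum = 1e-4) {
  stopifnot(inherits(a, "Profile"), inherits(b, "Profile"))
  if (a$total_reads != b$total_reads)
    mc_stop("profiles must be normalized to the same total; ",
            "call normalize_to_smallest() first")
  taxa <- union(names(a$counts), names(b$counts))
  ca <- setNames(rep(0, length(taxa)), taxa); ca[names(a$counts)] <- a$counts
  cb <- setNames(rep(0, length(taxa)), taxa); cb[names(b$counts)] <- b$counts
  rel <- ca / a$total_reads + cb / b$total_reads
  sel <- rel >= min_rel_sum
  data.frame(taxon = taxa[sel],
             x = log10(ca[sel] + pseudocount),
             y = log10(cb[sel] + pseudocount),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene tags unique to one of two samples
#'
#' A taxon or Pfam family is "unique to a" when it is absent from `b`
#' (count exactly zero — a raw zero stays zero under normalization) while
#' its normalized count in `a` is at least `min_abundance` (inclusive;
#' default 5). Symmetric for `b`.
#'
#' @param a,b `Profile` objects normalized to the same total.
#' @param min_abundance inclusive normalized-count threshold (default 5).
#' @return `list(unique_to_a = character, unique_to_b = character)`.
#' @export
unique_egts <- function(a, b, min_abundance = 5) {
  stopifnot(inherits(a, "Profile"), inherits(b, "Profile"))
  if (a$total_reads != b$total_reads)
    mc_stop("profiles must be normalized to the same total")
  absent <- function(p, t) !(t %in% names(p$counts)) || p$counts[[t]] == 0
  ua <- names(a$counts)[a$counts >= min_abundance &
                          vapply(names(a$counts), absent, TRUE, p = b)]
  ub <- names(b$counts)[b$counts >= min_abundance &
                          vapply(names(b$counts), absent, TRUE, p = a)]
  list(unique_to_a = ua, unique_to_b = ub)
}

#' Export a profile as TSV (plain or Krona-compatible)
#'
#' The plain export reports raw counts plus relative abundances against
#' both natural denominators (the dataset total and the assigned-read
#' total). The Krona export writes one row per taxon: count first, then
#' the lineage columns (root down to the profile's rank) expected by
#' Krona's text importer.
#'
#' @param p a `Profile`.
#' @param path output TSV.
#' @param lineage optional named list/vector mapping taxon -> character
#'   vector of ancestor names (for the Krona export); when missing, the
#'   taxon name alone is written.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "Profile"))
  assigned <- sum(p$counts)
  df <- data.frame(taxon = names(p$counts), count = as.numeric(p$counts),
                   rel_abund_total = as.numeric(p$counts) / p$total_reads,
                   rel_abund_assigned =
                     if (assigned > 0) as.numeric(p$counts) / assigned else 0,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$taxon), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
write_krona <- function(p, path, lineage = NULL) {
  stopifnot(inherits(p, "Profile"))
  lines <- vapply(names(p$counts), function(t) {
    lin <- if (!is.null(lineage) && t %in% names(lineage))
      lineage[[t]] else t
    paste(c(format(p$counts[[t]], scientific = FALSE), lin),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
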