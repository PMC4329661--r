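#' Validate a table of alignment hits
#'
#' An alignment-hit table has one row per (read, locus) alignment with
#' columns `read_id`, `genome_id`, `identical_bases`, `read_length`
#' (the FULL read length, not the aligned span), `subject_start`,
#' `subject_end` (1-based inclusive reference coordinates, start <= end),
#' `strand` (`"+"`/`"-"`) and optional `score` (used for tie-breaking;
#' defaults to `identical_bases`).
#'
#' @param hits data.frame of hits.
#' @param reference_lengths optional named vector of reference lengths for
#'   coordinate validation.
#' @return the validated data.frame (with a `score` column).
#' @export
alignment_hits <- function(hits, reference_lengths = NULL) {
  need <- c("read_id", "genome_id", "identical_bases", "read_length",
            "subject_start", "subject_end", "strand")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    mc_stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(hits$read_length <= 0)) mc_stop("'read_length' must be positive")
  if (any(hits$identical_bases < 0 |
          hits$identical_bases > hits$read_length))
    mc_stop("'identical_bases' must lie in [0, read_length]")
  if (any(hits$subject_start < 1 | hits$subject_start > hits$subject_end))
    mc_stop("need 1 <= subject_start <= subject_end")
  if (!all(hits$strand %in% c("+", "-")))
    mc_stop("'strand' must be '+' or '-'")
  if (!is.null(reference_lengths)) {
    lim <- reference_lengths[hits$genome_id]
    if (any(is.na(lim)) || any(hits$subject_end > lim))
      mc_stop("subject coordinates exceed reference length")
  }
  if (is.null(hits$score)) hits$score <- hits$identical_bases
  hits
}

#' Read-length identity of alignment hits
#'
#' The identity of a hit is the number of identical aligned bases divided
#' by the FULL length of the read — not by the aligned span. Short local
#' alignments of long reads therefore score low by construction, which is
#' the intended behaviour: a read must align near-globally to a closely
#' related reference to approach identity 1.
#'
#' @param hits data.frame of alignment hits (see [alignment_hits()]).
#' @return numeric vector of identities in `[0, 1]`.
#' @export
compute_identity <- function(hits) {
  if (any(hits$read_length == 0)) mc_stop("'read_length' must be positive")
  hits$identical_bases / hits$read_length
}

#' Discard hits below the identity retention floor
#'
#' Hits with read-length identity below the floor (default 55%) are
#' discarded; the boundary is inclusive, so a hit at exactly the floor is
#' retained.
#'
#' @param hits data.frame of alignment hits.
#' @param floor identity floor as a fraction (default 0.55).
#' @return the retained hits.
#' @export
filter_hits <- function(hits, floor = 0.55) {
  hits[compute_identity(hits) >= floor, , drop = FALSE]
}

#' Reduce hits to the best hit per read
#'
#' Retains, per (read, genome) pair — or per read when `scope =
#' "global"` — the single hit with the highest identity; ties are broken
#' by higher `score`, then lower `subject_start`, then lexicographically
#' smaller `genome_id`.
#'
#' @param hits data.frame of alignment hits.
#' @param scope `"per_genome"` (default) or `"global"`.
#' @return the reduced hit table (input row order of winners preserved).
#' @export
best_hit_per_read <- function(hits, scope = c("per_genome", "global")) {
  scope <- match.arg(scope)
  if (!nrow(hits)) return(hits)
  if (is.null(hits$score)) hits$score <- hits$identical_bases
  key <- if (scope == "per_genome")
    paste(hits$read_id, hits$genome_id, sep = "\r") else hits$read_id
  ident <- compute_identity(hits)
  ord <- order(key, -ident, -hits$score, hits$subject_start,
               hits$genome_id)
  first <- ord[!duplicated(key[ord])]
  hits[sort(first), , drop = FALSE]
}

#' Per-genome recruitment summary
#'
#' Counts, for each reference genome, the retained hits and the reads at
#' or above the high-identity threshold (default 90%, inclusive), and
#' expresses the latter as a percentage of the smallest supplied dataset
#' total via [percentage_of_total()] — the same minimum denominator is
#' used for every sample so percentages are directly comparable.
#'
#' @param hits hits already floored ([filter_hits()]) and reduced to best
#'   hit per (read, genome) ([best_hit_per_read()]).
#' @param totals integer vector of the compared datasets' read totals.
#' @param high high-identity counting threshold (default 0.90).
#' @param top_k optional; keep only the top `top_k` genomes.
#' @return data.frame (`RecruitmentSummary` rows) with columns
#'   `genome_id`, `n_hits_retained`, `n_ge_high`, `percentage`, sorted by
#'   `n_ge_high` descending.
#' @export
summarize_recruitment <- function(hits, totals, high = 0.90, top_k = NULL) {
  if (!nrow(hits)) {
    out <- data.frame(genome_id = character(), n_hits_retained = integer(),
                      n_ge_high = integer(), percentage = numeric())
    return(out)
  }
  ident <- compute_identity(hits)
  genomes <- sort(unique(hits$genome_id))
  n_ret <- as.integer(table(factor(hits$genome_id, levels = genomes)))
  n_high <- as.integer(table(factor(hits$genome_id[ident >= high],
                                    levels = genomes)))
  out <- data.frame(genome_id = genomes, n_hits_retained = n_ret,
                    n_ge_high = n_high,
                    percentage = percentage_of_total(n_high, totals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_ge_high, out$genome_id), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' Identity histogram of retained hits
#'
#' Bins hit identities into 1%-wide intervals spanning 55 to 100%
#' identity. Bin `i` covers `[edge_i, edge_i + 1)` percent except the
#' last, which is closed so hits at exactly 100% are counted. Raw counts
#' are scaled by `min(totals) / sample_total`, so the smallest sample's
#' histogram equals its raw histogram and larger samples are normalized
#' down to it.
#'
#' @param hits hits already floored at 55% identity.
#' @param totals integer vector of the compared datasets' totals.
#' @param sample_total the total of the dataset these hits come from.
#' @param sample_id sample label.
#' @return an object of class `HistogramBins`: list with `edges`
#'   (56 breakpoints 55..100), `counts` (45 normalized bin counts),
#'   `raw_counts`, `sample_id`, `norm_factor`.
#' @export
identity_histogram <- function(hits, totals, sample_total = min(totals),
                               sample_id = "sample") {
  ident <- compute_identity(hits) * 100
  if (length(ident) && (any(ident < 55) || any(ident > 100)))
    mc_stop("hit identity outside [55, 100]: apply filter_hits() first")
  edges <- 55:100
  bin <- pmin(floor(ident) - 55L, 44L) + 1L # identity 100 -> last bin
  raw <- tabulate(bin, nbins = 45L)
  f <- min(totals) / sample_total
  structure(list(edges = edges, counts = raw * f, raw_counts = raw,
                 sample_id = sample_id, norm_factor = f),
            class = "HistogramBins")
}

#' @export
print.HistogramBins <- function(x, ...) {
  cat(sprintf(
    "<HistogramBins %s: %s hits in 45 bins over [55, 100]%%, norm %.4f>\n",
    x$sample_id, format(sum(x$raw_counts), big.mark = ","), x$norm_factor))
  invisible(x)
}

#' Recruitment-plot points
#'
#' One point per retained hit: percent identity against the position of
#' the alignment on the reference. The abscissa is, by default, the
#' midpoint of the subject interval (1-based); `"start"` and `"end"` are
#' available alternatives.
#'
#' @param hits hits already floored at 55% identity.
#' @param position `"midpoint"` (default), `"start"` or `"end"`.
#' @return data.frame with columns `genome_id`, `read_id`, `position`,
#'   `identity` (percent).
#' @export
recruitment_points <- function(hits,
                               position = c("midpoint", "start", "end")) {
  position <- match.arg(position)
  ident <- compute_identity(hits) * 100
  if (length(ident) && any(ident < 55))
    mc_stop("below-floor hits present: apply filter_hits() first")
  pos <- switch(position,
                midpoint = (hits$subject_start + hits$subject_end) / 2,
                start = hits$subject_start,
                end = hits$subject_end)
  data.frame(genome_id = hits$genome_id, read_id = hits$read_id,
             position = pos, identity = ident,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Parse BLAST tabular (outfmt 6) hits
#'
#' Reads the standard 12-column tabular format (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) and
#' converts each row to the package's hit representation: the number of
#' identical bases is reconstructed as `round(pident * length / 100)`
#' (optionally minus the reported mismatches when `mismatch_correction =
#' TRUE`), while `read_length` is taken from the supplied read lengths —
#' never from the alignment span — as the read-length identity statistic
#' requires. Minus-strand hits (send < sstart) are normalized so
#' `subject_start <= subject_end`.
#'
#' @param path BLAST outfmt-6 TSV (no header).
#' @param read_lengths named integer vector: full length of every read id
#'   appearing in the file.
#' @param mismatch_correction logical, default `FALSE`.
#' @return a hit data.frame (see [alignment_hits()]) with `score` set to
#'   the bit score.
#' @export
read_blast6 <- function(path, read_lengths, mismatch_correction = FALSE) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.delim(path, header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  missing <- setdiff(unique(df$qseqid), names(read_lengths))
  if (length(missing))
    mc_stop("no read length supplied for read(s): ",
            paste(head(missing, 3L), collapse = ", "))
  idb <- round(df$pident * df$length / 100)
  if (mismatch_correction) idb <- idb - df$mismatch
  minus <- df$send < df$sstart
  hits <- data.frame(
    read_id = df$qseqid, genome_id = df$sseqid,
    identical_bases = pmax(0L, as.integer(idb)),
    read_length = as.integer(read_lengths[df$qseqid]),
    subject_start = ifelse(minus, df$send, df$sstart),
    subject_end = ifelse(minus, df$sstart, df$send),
    strand = ifelse(minus, "-", "+"),
    score = df$bitscore, stringsAsFactors = FALSE)
  hits$identical_bases <- pmin(hits$identical_bases, hits$read_length)
  alignment_hits(hits)
}

#' Write recruitment outputs as TSV
#'
#' @param x a summary data.frame, `HistogramBins`, or points data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recruitment_summary <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recruitment_summary
#' @export
write_histogram <- function(x, path) {
  stopifnot(inherits(x, "HistogramBins"))
  df <- data.frame(bin_lo = x$edges[-length(x$edges)],
                   bin_hi = x$edges[-1L],
                   count = x$counts, raw_count = x$raw_counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
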