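#' QC report constructor
#'
#' Book-keeping record for one filtering stage. The identity
#' `output_reads == input_reads - duplicates_removed - gc_outliers_removed`
#' always holds.
#'
#' @param sample_id sample label.
#' @param input_reads,duplicates_removed,gc_outliers_removed,output_reads counts.
#' @param mean_length_in,mean_length_out mean read length (bp) before/after.
#' @param stages character vector of stages applied, in order.
#' @return an object of class `QCReport`.
#' @export
qc_report <- function(sample_id, input_reads, duplicates_removed,
                      gc_outliers_removed, output_reads,
                      mean_length_in, mean_length_out, stages) {
  if (output_reads != input_reads - duplicates_removed - gc_outliers_removed)
    mc_stop("inconsistent QCReport counts")
  structure(list(sample_id = sample_id, input_reads = input_reads,
                 duplicates_removed = duplicates_removed,
                 gc_outliers_removed = gc_outliers_removed,
                 output_reads = output_reads,
                 mean_length_in = mean_length_in,
                 mean_length_out = mean_length_out, stages = stages),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(
    "<QCReport %s [%s]: %s in, %s duplicates, %s GC outliers, %s out>\n",
    x$sample_id, paste(x$stages, collapse = "+"),
    format(x$input_reads, big.mark = ","), x$duplicates_removed,
    x$gc_outliers_removed, format(x$output_reads, big.mark = ",")))
  invisible(x)
}

#' Write a QC report as a one-row TSV
#'
#' @param report a `QCReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- as.data.frame(report[setdiff(names(report), "stages")])
  df$stages <- paste(report$stages, collapse = "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

mean_len <- function(rs) if (rs$total_count) mean(nchar(rs$reads$sequence)) else 0

#' Remove emulsion-PCR duplicate reads
#'
#' 454 emulsion-PCR replicates start at the same template position, so they
#' share their 5' sequence and have near-identical lengths. Reads whose
#' first `prefix_len` bases are identical (case-insensitive) and whose
#' lengths agree within `length_tolerance` are clustered; each cluster
#' keeps its longest member (earliest on ties) and the rest are removed.
#' Reads with an `N` in the prefix never cluster with others, and reads
#' shorter than `prefix_len` are compared over their full sequence —
#' both choices are conservative toward retention. Output preserves the
#' input order of retained reads.
#'
#' @param rs a `ReadSet`.
#' @param prefix_len prefix length in bp (>= 20; default 50).
#' @param length_tolerance maximum relative length difference within a
#'   cluster (default 0.02).
#' @return `list(reads = ReadSet, report = QCReport)`.
#' @export
remove_duplicates <- function(rs, prefix_len = 50L, length_tolerance = 0.02) {
  stopifnot(inherits(rs, "ReadSet"))
  if (prefix_len < 20) mc_stop("'prefix_len' must be >= 20")
  n <- rs$total_count
  if (n == 0L)
    return(list(reads = rs,
                report = qc_report(rs$sample_id, 0L, 0L, 0L, 0L, 0, 0,
                                   "duplicates")))
  seqs <- toupper(rs$reads$sequence)
  lens <- nchar(seqs)
  key <- substr(seqs, 1L, prefix_len)
  short <- lens < prefix_len
  key[short] <- paste0("SHORT:", seqs[short])
  hasN <- grepl("N", substr(key, 1L, prefix_len), fixed = TRUE)
  key[hasN] <- paste0("N", seq_len(n)[hasN]) # unique keys: never clustered
  keep <- rep(TRUE, n)
  for (idx in split(seq_len(n), key)) {
    if (length(idx) < 2L) next
    ## greedy length sub-clustering against each sub-cluster's first member
    reps <- integer(0)
    assign_to <- integer(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]; placed <- FALSE
      for (r in seq_along(reps)) {
        L0 <- lens[reps[r]]; L1 <- lens[i]
        if (abs(L1 - L0) <= length_tolerance * max(L0, L1)) {
          assign_to[j] <- r; placed <- TRUE; break
        }
      }
      if (!placed) { reps <- c(reps, i); assign_to[j] <- length(reps) }
    }
    for (r in seq_along(reps)) {
      members <- idx[assign_to == r]
      if (length(members) < 2L) next
      best <- members[which.max(lens[members])] # which.max: earliest on ties
      keep[setdiff(members, best)] <- FALSE
    }
  }
  out <- read_set(rs$sample_id, rs$reads[keep, , drop = FALSE])
  rep_ <- qc_report(rs$sample_id, n, sum(!keep), 0L, out$total_count,
                    mean_len(rs), mean_len(out), "duplicates")
  list(reads = out, report = rep_)
}

#' Remove GC-content outlier reads
#'
#' Removes reads whose GC fraction lies more than `z_cutoff` sample
#' standard deviations from the sample mean, emulating the GC-bias
#' filtering applied to pyrosequencing libraries. By default the trim is
#' iterated to a fixed point (mean/SD recomputed after each pass until no
#' read is removed), which makes the operation idempotent; `iterate =
#' FALSE` gives a single literal pass. With fewer than two reads, or zero
#' GC variance, nothing is removed.
#'
#' @param rs a `ReadSet`.
#' @param z_cutoff positive z-score cutoff (default 3).
#' @param iterate logical; trim to a fixed point (default `TRUE`).
#' @return `list(reads = ReadSet, report = QCReport)`.
#' @export
filter_gc_bias <- function(rs, z_cutoff = 3, iterate = TRUE) {
  stopifnot(inherits(rs, "ReadSet"))
  if (!is.numeric(z_cutoff) || z_cutoff <= 0)
    mc_stop("'z_cutoff' must be > 0")
  n0 <- rs$total_count
  if (n0 < 2L) {
    warning("fewer than 2 reads: GC-bias filter is a no-op")
    return(list(reads = rs,
                report = qc_report(rs$sample_id, n0, 0L, 0L, n0,
                                   mean_len(rs), mean_len(rs), "gc")))
  }
  gc <- gc_fraction(rs$reads$sequence)
  keep <- rep(TRUE, n0)
  repeat {
    g <- gc[keep]
    if (length(g) < 2L) break
    s <- sd(g)
    if (!is.finite(s) || s == 0) break
    out <- abs(gc - mean(g)) > z_cutoff * s & keep
    if (!any(out)) break
    keep[out] <- FALSE
    if (!iterate) break
  }
  res <- read_set(rs$sample_id, rs$reads[keep, , drop = FALSE])
  rep_ <- qc_report(rs$sample_id, n0, 0L, sum(!keep), res$total_count,
                    mean_len(rs), mean_len(res), "gc")
  list(reads = res, report = rep_)
}

#' Run the full QC stage: duplicate removal, then GC-bias filtering
#'
#' The composition order is fixed (duplicates first) and recorded in the
#' combined report's `stages` field.
#'
#' @inheritParams remove_duplicates
#' @inheritParams filter_gc_bias
#' @return `list(reads = ReadSet, report = QCReport)` where the report
#'   aggregates both stages.
#' @export
run_qc <- function(rs, prefix_len = 50L, length_tolerance = 0.02,
                   z_cutoff = 3, iterate = TRUE) {
  d <- remove_duplicates(rs, prefix_len, length_tolerance)
  g <- if (d$reads$total_count >= 2L)
    filter_gc_bias(d$reads, z_cutoff, iterate)
  else list(reads = d$reads,
            report = qc_report(d$reads$sample_id, d$reads$total_count, 0L, 0L,
                               d$reads$total_count, mean_len(d$reads),
                               mean_len(d$reads), "gc"))
  rep_ <- qc_report(rs$sample_id, rs$total_count,
                    d$report$duplicates_removed,
                    g$report$gc_outliers_removed,
                    g$reads$total_count, mean_len(rs), mean_len(g$reads),
                    c("duplicates", "gc"))
  list(reads = g$reads, report = rep_)
}
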