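#' Align reads to reference genomes by exact k-mer seeding
#'
#' A small, self-contained nucleotide aligner for desk-scale recruitment
#' runs: non-overlapping exact k-mers of each read (default k = 15) are
#' matched against each reference on both strands; every seed match
#' proposes the unique ungapped placement of the full read, candidate
#' placements are de-duplicated and verified base-by-base over the whole
#' read span, and one hit per (read, genome, strand, offset) is emitted
#' with `identical_bases` counted over the full read. A read that is an
#' exact substring of a genome is guaranteed a hit with identity 1.0 at
#' the true coordinates. Reads whose seeds all miss (possible at high
#' divergence) are simply absent from the output. Placements must fit
#' entirely within the reference; no gapped extension is attempted.
#'
#' @param rs a `ReadSet` (or data.frame with `id` and `sequence`).
#' @param genomes list of `Genome` objects.
#' @param k seed length in bp (default 15).
#' @param min_identical optional verification cutoff: candidate
#'   placements with fewer identical bases are dropped (default 0 keeps
#'   all seeded placements; the 55% retention floor is applied later by
#'   [filter_hits()]).
#' @return a hit data.frame (see [alignment_hits()]); `score` equals
#'   `identical_bases`.
#' @export
align_reads <- function(rs, genomes, k = 15L, min_identical = 0L) {
  reads <- if (inherits(rs, "ReadSet")) rs$reads else rs
  if (!nrow(reads)) mc_stop("no reads to align")
  stopifnot(all(vapply(genomes, inherits, TRUE, "Genome")))
  seqs <- toupper(reads$sequence)
  lens <- nchar(seqs)
  if (any(lens < k)) mc_stop("all reads must be at least k bases long")
  rc <- revcomp(seqs)
  read_ints <- lapply(seqs, utf8ToInt)
  rc_ints <- lapply(rc, utf8ToInt)

  seed_tbl <- function(ss) {
    starts <- lapply(lens, function(L) seq.int(1L, L - k + 1L, by = k))
    ns <- lengths(starts)
    data.frame(read = rep.int(seq_along(ss), ns),
               offset = unlist(starts),
               seed = substring(ss[rep.int(seq_along(ss), ns)],
                                unlist(starts),
                                unlist(starts) + k - 1L))
  }
  fwd <- seed_tbl(seqs)
  rev_ <- seed_tbl(rc)

  out <- vector("list", length(genomes))
  for (g in seq_along(genomes)) {
    gseq <- genomes[[g]]$sequence
    glen <- nchar(gseq)
    gints <- utf8ToInt(gseq)
    hits_g <- list()
    for (strand in c("+", "-")) {
      st <- if (strand == "+") fwd else rev_
      useed <- unique(st$seed)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(useed))
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(gseq))
      nm <- S4Vectors::elementNROWS(m)
      if (!sum(nm)) next
      pos <- IRanges::start(unlist(m))
      ## join seed occurrences in reads with seed matches in the genome:
      ## matches in `pos` are blocked by pattern, so occurrence o of seed
      ## s picks the block pos[(cum[s]+1) .. (cum[s]+nm[s])]
      sidx <- match(st$seed, useed)
      n_per_occ <- nm[sidx]
      if (!sum(n_per_occ)) next
      cum <- c(0L, cumsum(nm))
      occ_rep <- rep.int(seq_len(nrow(st)), n_per_occ)
      take <- sequence(n_per_occ) + rep.int(cum[sidx], n_per_occ)
      cand_read <- st$read[occ_rep]
      cand_start <- pos[take] - st$offset[occ_rep] + 1L
      ok <- cand_start >= 1L & cand_start + lens[cand_read] - 1L <= glen
      cand_read <- cand_read[ok]; cand_start <- cand_start[ok]
      if (!length(cand_read)) next
      key <- paste(cand_read, cand_start)
      first <- !duplicated(key)
      cand_read <- cand_read[first]; cand_start <- cand_start[first]
      ints <- if (strand == "+") read_ints else rc_ints
      idb <- integer(length(cand_read))
      for (i in seq_along(cand_read)) {
        r <- cand_read[i]; a <- cand_start[i]
        idb[i] <- sum(ints[[r]] == gints[a:(a + lens[r] - 1L)])
      }
      keep <- idb >= min_identical
      if (!any(keep)) next
      hits_g[[strand]] <- data.frame(
        read_id = reads$id[cand_read[keep]],
        genome_id = genomes[[g]]$id,
        identical_bases = idb[keep],
        read_length = lens[cand_read[keep]],
        subject_start = cand_start[keep],
        subject_end = cand_start[keep] + lens[cand_read[keep]] - 1L,
        strand = strand, score = idb[keep],
        stringsAsFactors = FALSE)
    }
    out[[g]] <- if (length(hits_g)) do.call(rbind, hits_g) else NULL
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(read_id = character(), genome_id = character(),
                      identical_bases = integer(), read_length = integer(),
                      subject_start = integer(), subject_end = integer(),
                      strand = character(), score = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Exhaustive ungapped alignment (reference implementation)
#'
#' Slides each read over every offset of every genome on both strands and
#' returns, per (read, genome), the placement maximizing the number of
#' identical bases. Quadratic and intended only for small validation
#' instances; [align_reads()] is the scalable path.
#'
#' @inheritParams align_reads
#' @return a hit data.frame with one best row per (read, genome).
#' @export
align_reads_exhaustive <- function(rs, genomes) {
  reads <- if (inherits(rs, "ReadSet")) rs$reads else rs
  seqs <- toupper(reads$sequence)
  lens <- nchar(seqs)
  read_ints <- lapply(seqs, utf8ToInt)
  rc_ints <- lapply(revcomp(seqs), utf8ToInt)
  rows <- list()
  for (g in genomes) {
    gints <- utf8ToInt(g$sequence)
    glen <- length(gints)
    for (r in seq_along(seqs)) {
      L <- lens[r]
      if (L > glen) next
      best <- c(idb = -1L, start = 0L); best_strand <- "+"
      for (strand in c("+", "-")) {
        v <- if (strand == "+") read_ints[[r]] else rc_ints[[r]]
        ## mismatch profile over all offsets via base-wise shifts
        idb <- integer(glen - L + 1L)
        for (j in seq_len(L))
          idb <- idb + (gints[j:(glen - L + j)] == v[j])
        w <- which.max(idb)
        if (idb[w] > best["idb"]) {
          best <- c(idb = idb[w], start = w); best_strand <- strand
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = reads$id[r], genome_id = g$id,
        identical_bases = as.integer(best["idb"]), read_length = L,
        subject_start = as.integer(best["start"]),
        subject_end = as.integer(best["start"]) + L - 1L,
        strand = best_strand, score = as.integer(best["idb"]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
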