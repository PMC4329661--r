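#' Construct a reference genome object
#'
#' A `Genome` stands in for a completely sequenced reference organism: a
#' single contiguous DNA sequence plus an ordered taxonomic lineage
#' (superkingdom down to genus). Lineages may be populated only down to
#' some rank, but must not skip ranks in between.
#'
#' @param id character scalar, genome label.
#' @param sequence character scalar, DNA over A/C/G/T.
#' @param taxon_lineage named character vector; names are a contiguous
#'   prefix of `c("superkingdom","phylum","class","order","family","genus")`.
#' @param gc_target numeric in (0,1) or `NA`; the GC fraction the sequence
#'   was simulated at (informational).
#' @return an object of class `Genome`.
#' @export
genome <- function(id, sequence, taxon_lineage = c(superkingdom = "Bacteria"),
                   gc_target = NA_real_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    mc_stop("genome 'id' must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    mc_stop("genome 'sequence' must be a non-empty DNA string")
  if (grepl("[^ACGTacgt]", sequence))
    mc_stop("genome 'sequence' may only contain A/C/G/T")
  lr <- names(taxon_lineage)
  if (is.null(lr) || !all(lr %in% RANKS))
    mc_stop("taxon_lineage must be named with ranks among: ",
            paste(RANKS, collapse = ", "))
  pos <- sort(match(lr, RANKS))
  if (!identical(pos, seq_len(length(pos))))
    mc_stop("taxon_lineage must populate ranks contiguously from superkingdom")
  structure(
    list(id = id, sequence = toupper(sequence),
         taxon_lineage = taxon_lineage[RANKS[pos]], gc_target = gc_target),
    class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome %s: %s bp, GC %.3f, lineage %s>\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              gc_fraction(x$sequence),
              paste(x$taxon_lineage, collapse = ";")))
  invisible(x)
}

#' Simulate a random reference genome at a target GC content
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_target/2`, so for genomes
#' of 10 kb or more the realized GC fraction concentrates within ~0.02 of
#' the target. Deterministic for a given `seed`.
#'
#' @param length integer, genome length in bp (>= 1000).
#' @param gc_target numeric in (0,1).
#' @param seed integer RNG seed.
#' @param id genome label.
#' @param taxon_lineage passed to [genome()].
#' @return a `Genome`.
#' @export
generate_genome <- function(length, gc_target = 0.5, seed = 1L,
                            id = "genome1",
                            taxon_lineage = c(superkingdom = "Bacteria")) {
  if (!is_count(length) || length < 1000)
    mc_stop("'length' must be a positive integer >= 1000")
  if (!is.numeric(gc_target) || gc_target <= 0 || gc_target >= 1)
    mc_stop("'gc_target' must lie strictly between 0 and 1")
  seq <- withr::with_seed(as.integer(seed), {
    p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
           (1 - gc_target) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
          collapse = "")
  })
  genome(id, seq, taxon_lineage, gc_target = gc_target)
}

#' Derive a diverged copy of a genome
#'
#' Applies i.i.d. substitutions at the given rate (each substituted base is
#' replaced by one of the three other bases uniformly), producing a related
#' "strain" at a known average nucleotide divergence. Used to build
#' communities where resident populations differ from the reference.
#'
#' @param g a `Genome`.
#' @param rate substitution rate per base in `[0, 0.75)`.
#' @param seed integer RNG seed.
#' @param id label for the derived genome.
#' @return a `Genome` with the same lineage as `g`.
#' @export
mutate_genome <- function(g, rate, seed = 1L, id = paste0(g$id, "_mut")) {
  stopifnot(inherits(g, "Genome"))
  if (!is.numeric(rate) || rate < 0 || rate >= 0.75)
    mc_stop("'rate' must be in [0, 0.75)")
  seq <- withr::with_seed(as.integer(seed),
                          substitute_bases(g$sequence, rate))
  genome(id, seq, g$taxon_lineage, gc_target = g$gc_target)
}

## substitution-only error process: flips each base with prob `rate`
## to one of the 3 other bases, uniformly. Uses the current RNG stream.
substitute_bases <- function(s, rate) {
  if (rate <= 0) return(s)
  L <- nchar(s)
  k <- rbinom(1L, L, rate)
  if (k == 0L) return(s)
  pos <- sample.int(L, k)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  cur <- match(ch[pos], DNA_BASES)
  ch[pos] <- DNA_BASES[((cur - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
  paste(ch, collapse = "")
}

## optional 454-style homopolymer indel process: each homopolymer run of
## length >= 2 is extended or shortened by one base with prob `rate`.
homopolymer_indels <- function(s, rate) {
  if (rate <= 0) return(s)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  hp <- which(r$lengths >= 2L)
  if (!length(hp)) return(s)
  hit <- hp[runif(length(hp)) < rate]
  if (length(hit)) {
    delta <- sample(c(-1L, 1L), length(hit), replace = TRUE)
    r$lengths[hit] <- pmax(1L, r$lengths[hit] + delta)
  }
  paste(inverse.rle(r), collapse = "")
}

#' Specify a synthetic community and sequencing run
#'
#' Bundles the ground-truth description of a simulated metagenome sample:
#' which genomes are present, their relative abundances (log-spread in real
#' communities), how much each resident population diverges from its
#' reference sequence, the 454-like read-length distribution, the number of
#' reads, and the artifact model (emulsion-PCR duplicate rate and its
#' coupling to read GC content).
#'
#' @param genomes list of `Genome` objects with distinct ids.
#' @param abundances numeric vector summing to 1 (tolerance 1e-9), one per
#'   genome.
#' @param divergences per-genome substitution rate in `[0, 0.45)`; rates at
#'   or above 0.45 are rejected because such reads could not stay above the
#'   55% identity retention floor.
#' @param read_length_mean,read_length_sd read length distribution in bp;
#'   lengths are drawn from a normal truncated to `[50, 2 * mean]`.
#' @param n_reads total number of reads to simulate (duplicates included).
#' @param duplicate_rate fraction of reads in `[0, 1)` that are emulsion-PCR
#'   duplicates of other reads.
#' @param gc_dup_coupling non-negative real; duplicate parents are chosen
#'   with weight `exp(coupling * GC)`, so positive values concentrate
#'   duplicates on GC-rich reads (the GC bias the QC stage targets).
#' @param homopolymer_indel_rate optional 454 homopolymer indel rate per
#'   run (default 0 = substitution-only error model).
#' @param sample_id sample label carried into the `ReadSet`.
#' @param seed integer; the single seed from which all draws flow.
#' @return an object of class `CommunitySpec`.
#' @export
community_spec <- function(genomes, abundances, divergences = 0,
                           read_length_mean = 387, read_length_sd = 50,
                           n_reads = 1000L, duplicate_rate = 0,
                           gc_dup_coupling = 0,
                           homopolymer_indel_rate = 0,
                           sample_id = "sample1", seed = 1L) {
  if (!length(genomes) || !all(vapply(genomes, inherits, TRUE, "Genome")))
    mc_stop("'genomes' must be a non-empty list of Genome objects")
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) mc_stop("genome ids must be distinct")
  if (length(abundances) != length(genomes))
    mc_stop("'abundances' must have one entry per genome")
  if (abs(sum(abundances) - 1) > 1e-9)
    mc_stop("'abundances' must sum to 1 (tolerance 1e-9)")
  if (any(abundances < 0)) mc_stop("'abundances' must be non-negative")
  divergences <- rep_len(divergences, length(genomes))
  if (any(divergences < 0) || any(divergences >= 0.45))
    mc_stop("'divergences' must lie in [0, 0.45): rates >= 0.45 are not ",
            "resolvable above the 55% identity floor")
  if (!is_count(n_reads)) mc_stop("'n_reads' must be a non-negative integer")
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    mc_stop("'duplicate_rate' must lie in [0, 1)")
  if (gc_dup_coupling < 0) mc_stop("'gc_dup_coupling' must be >= 0")
  if (read_length_mean < 50) mc_stop("'read_length_mean' must be >= 50 bp")
  structure(
    list(genomes = genomes, abundances = abundances,
         divergences = divergences,
         read_length_mean = read_length_mean,
         read_length_sd = read_length_sd,
         n_reads = as.integer(n_reads), duplicate_rate = duplicate_rate,
         gc_dup_coupling = gc_dup_coupling,
         homopolymer_indel_rate = homopolymer_indel_rate,
         sample_id = sample_id, seed = as.integer(seed)),
    class = "CommunitySpec")
}

#' Construct a read set
#'
#' @param sample_id sample label.
#' @param reads data.frame with columns `id`, `sequence`, `truth_genome`,
#'   `truth_start` (0-based offset on the source genome, `NA` if unknown)
#'   and `is_duplicate_of` (`NA` for non-duplicates).
#' @return an object of class `ReadSet` with a `total_count` field equal to
#'   the number of reads.
#' @export
read_set <- function(sample_id, reads) {
  need <- c("id", "sequence", "truth_genome", "truth_start", "is_duplicate_of")
  miss <- setdiff(need, names(reads))
  for (m in miss)
    reads[[m]] <- rep(if (m == "truth_start") NA_integer_ else NA_character_,
                      nrow(reads))
  reads <- reads[, need]
  if (anyDuplicated(reads$id)) mc_stop("read ids must be unique")
  structure(list(sample_id = sample_id, reads = reads,
                 total_count = nrow(reads)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("<ReadSet %s: %s reads, mean length %.1f bp>\n", x$sample_id,
              format(x$total_count, big.mark = ","),
              if (x$total_count) mean(nchar(x$reads$sequence)) else 0))
  invisible(x)
}

## truncated-normal read lengths on [50, 2*mean], by rejection
draw_read_lengths <- function(n, mean, sd, max_len) {
  lo <- 50; hi <- 2 * mean
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n - length(out) + 16L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  pmin(as.integer(round(out[seq_len(n)])), max_len)
}

#' Simulate a 454-like read set from a community specification
#'
#' Non-duplicate reads pick a source genome with probability equal to its
#' abundance, a start position uniformly along that genome, and a length
#' from the truncated-normal model; per-base substitutions are applied at
#' the genome's divergence rate. Emulsion-PCR duplicates are then added up
#' to `round(duplicate_rate * n_reads)`: each copies the genome, start
#' coordinate and length of a parent read (chosen with weight
#' `exp(gc_dup_coupling * GC_parent)`) but receives independent fresh error
#' draws, and records its parent in `is_duplicate_of`. Originals are
#' emitted before duplicates; read order carries no other signal.
#'
#' @param spec a `CommunitySpec`.
#' @return a `ReadSet` with ground-truth columns filled in.
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "CommunitySpec"))
  n <- spec$n_reads
  empty <- data.frame(id = character(), sequence = character(),
                      truth_genome = character(), truth_start = integer(),
                      is_duplicate_of = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(read_set(spec$sample_id, empty))
  withr::with_seed(spec$seed, {
    n_dup <- as.integer(round(spec$duplicate_rate * n))
    n_orig <- n - n_dup
    gseqs <- vapply(spec$genomes, `[[`, "", "sequence")
    gids <- vapply(spec$genomes, `[[`, "", "id")
    glens <- nchar(gseqs)
    gi <- sample.int(length(gids), n_orig, replace = TRUE,
                     prob = spec$abundances)
    lens <- draw_read_lengths(n_orig, spec$read_length_mean,
                              spec$read_length_sd, min(glens))
    starts0 <- as.integer(floor(runif(n_orig) * (glens[gi] - lens + 1L)))
    raw <- substring(gseqs[gi], starts0 + 1L, starts0 + lens)
    div <- spec$divergences[gi]
    seqs <- character(n_orig)
    for (i in seq_len(n_orig)) {
      s <- substitute_bases(raw[i], div[i])
      if (spec$homopolymer_indel_rate > 0)
        s <- homopolymer_indels(s, spec$homopolymer_indel_rate)
      seqs[i] <- s
    }
    ids <- sprintf("%s_read%06d", spec$sample_id, seq_len(n))
    parent <- rep(NA_character_, n_orig)
    if (n_dup > 0L) {
      w <- exp(spec$gc_dup_coupling * gc_fraction(seqs))
      pidx <- sample.int(n_orig, n_dup, replace = TRUE, prob = w)
      draw <- substring(gseqs[gi[pidx]], starts0[pidx] + 1L,
                        starts0[pidx] + lens[pidx])
      dseqs <- character(n_dup)
      for (i in seq_len(n_dup)) {
        s <- substitute_bases(draw[i], div[pidx[i]])
        if (spec$homopolymer_indel_rate > 0)
          s <- homopolymer_indels(s, spec$homopolymer_indel_rate)
        dseqs[i] <- s
      }
      gi <- c(gi, gi[pidx]); starts0 <- c(starts0, starts0[pidx])
      seqs <- c(seqs, dseqs)
      parent <- c(parent, ids[pidx])
    }
    ## originals are emitted before their duplicates so that the QC
    ## stage's keep-first tie-break retains the parent read
    reads <- data.frame(id = ids, sequence = seqs,
                        truth_genome = gids[gi],
                        truth_start = starts0,
                        is_duplicate_of = parent,
                        stringsAsFactors = FALSE)
    read_set(spec$sample_id, reads)
  })
}

#' Write a read set as FASTA or FASTQ
#'
#' FASTQ output carries uniform Q30 qualities (the simulator has no
#' quality-coupled error model).
#'
#' @param rs a `ReadSet`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(rs, "ReadSet"))
  x <- Biostrings::DNAStringSet(setNames(rs$reads$sequence, rs$reads$id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  } else {
    q <- Biostrings::BStringSet(vapply(nchar(rs$reads$sequence),
                                       function(L) strrep("?", L), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Read a FASTA/FASTQ file into a `ReadSet`
#'
#' @param path input file.
#' @param sample_id sample label (default: file name without extension).
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   missing.
#' @return a `ReadSet` (truth columns `NA`).
#' @export
read_reads <- function(path, sample_id = NULL, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(x))
  read_set(sample_id, data.frame(id = ids, sequence = as.character(x),
                                 stringsAsFactors = FALSE))
}

#' Write simulation ground truth and genome metadata
#'
#' `write_ground_truth()` emits a TSV (read_id, truth_genome, truth_start,
#' is_duplicate_of); `write_genomes()` a multi-FASTA of references;
#' `write_taxonomy()` a TSV of genome lineages (genome_id, superkingdom..genus).
#'
#' @param rs a `ReadSet` from [simulate_reads()].
#' @param genomes list of `Genome` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  df <- rs$reads[, c("id", "truth_genome", "truth_start", "is_duplicate_of")]
  names(df)[1] <- "read_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
write_genomes <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(setNames(
    vapply(genomes, `[[`, "", "sequence"),
    vapply(genomes, `[[`, "", "id")))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
write_taxonomy <- function(genomes, path) {
  rows <- lapply(genomes, function(g) {
    v <- setNames(rep(NA_character_, length(RANKS)), RANKS)
    v[names(g$taxon_lineage)] <- g$taxon_lineage
    c(genome_id = g$id, v)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reference genomes from a multi-FASTA
#'
#' @param path multi-FASTA file.
#' @param taxonomy optional TSV as written by [write_taxonomy()].
#' @return list of `Genome` objects.
#' @export
read_genomes <- function(path, taxonomy = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  tax <- NULL
  if (!is.null(taxonomy)) {
    tax <- read.delim(taxonomy, stringsAsFactors = FALSE)
    rownames(tax) <- tax$genome_id
  }
  lapply(seq_along(x), function(i) {
    lin <- c(superkingdom = "Bacteria")
    if (!is.null(tax) && ids[i] %in% rownames(tax)) {
      v <- unlist(tax[ids[i], intersect(RANKS, names(tax))])
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v)) lin <- v
    }
    genome(ids[i], as.character(x[[i]]), lin)
  })
}
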