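# Shared fixtures: all synthetic, built in code at test time.

# two small reference genomes with distinct lineages
toy_genomes <- function(len = 10000L, seed = 101L) {
  list(
    generate_genome(len, 0.5, seed = seed, id = "gA",
                    taxon_lineage = c(superkingdom = "Archaea",
                                      phylum = "Euryarchaeota",
                                      class = "Methanomicrobia",
                                      order = "Methanomicrobiales",
                                      family = "Methanomicrobiaceae",
                                      genus = "Methanoculleus")),
    generate_genome(len, 0.6, seed = seed + 1L, id = "gB",
                    taxon_lineage = c(superkingdom = "Bacteria",
                                      phylum = "Firmicutes",
                                      class = "Clostridia",
                                      order = "Clostridiales",
                                      family = "Clostridiaceae",
                                      genus = "Clostridium")))
}

# hand-rolled ReadSet from plain sequences
rs_from_seqs <- function(seqs, sample_id = "s") {
  read_set(sample_id,
           data.frame(id = sprintf("r%03d", seq_along(seqs)),
                      sequence = seqs, stringsAsFactors = FALSE))
}

# number of identical bases between a read and its source genome at the
# recorded (0-based) truth offset -- the brute-force identity oracle
truth_identical_bases <- function(rs, genomes) {
  gseq <- setNames(vapply(genomes, `[[`, "", "sequence"),
                   vapply(genomes, `[[`, "", "id"))
  mapply(function(s, g, st) {
    ref <- substr(gseq[[g]], st + 1L, st + nchar(s))
    sum(utf8ToInt(s) == utf8ToInt(ref))
  }, rs$reads$sequence, rs$reads$truth_genome, rs$reads$truth_start,
  USE.NAMES = FALSE)
}

# random read sequence with exactly 25% each base (GC exactly 0.5)
balanced_read <- function(len = 100L) {
  stopifnot(len %% 4 == 0)
  paste(sample(rep(c("A", "C", "G", "T"), len / 4L)), collapse = "")
}

# minimal alignment-hit row
hit_row <- function(read_id = "r1", genome_id = "g1", identical_bases = 360L,
                    read_length = 400L, subject_start = 1L,
                    subject_end = subject_start + read_length - 1L,
                    strand = "+", score = identical_bases) {
  data.frame(read_id = read_id, genome_id = genome_id,
             identical_bases = identical_bases, read_length = read_length,
             subject_start = subject_start, subject_end = subject_end,
             strand = strand, score = score, stringsAsFactors = FALSE)
}

# assignment records data.frame
assign_df <- function(read_id, taxon, rank = "family",
                      evalue = 1e-10) {
  data.frame(read_id = read_id, rank = rank, taxon = taxon,
             evalue = evalue, stringsAsFactors = FALSE)
}

func_df <- function(read_id, pfam_acc, superkingdom = "Archaea",
                    evalue = 1e-10) {
  data.frame(read_id = read_id, pfam_acc = pfam_acc,
             superkingdom = superkingdom, evalue = evalue,
             stringsAsFactors = FALSE)
}
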