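test_that("identity is identical bases over the full read length", {
  expect_equal(compute_identity(hit_row(identical_bases = 400L)), 1)
  expect_equal(compute_identity(hit_row(identical_bases = 220L)), 0.55)
  expect_error(compute_identity(hit_row(read_length = 0L)), "positive")
  expect_error(alignment_hits(hit_row(identical_bases = 500L)),
               "identical_bases")
  expect_error(alignment_hits(hit_row(subject_start = 10L,
                                      subject_end = 5L)), "subject_start")
})

test_that("the 55% retention floor is inclusive", {
  h <- rbind(hit_row("r1", identical_bases = 219L),  # 0.5475
             hit_row("r2", identical_bases = 220L),  # 0.55 exactly
             hit_row("r3", identical_bases = 221L))
  kept <- filter_hits(h)
  expect_setequal(kept$read_id, c("r2", "r3"))
  expect_identical(nrow(filter_hits(h[0, ])), 0L)
})

test_that("best-hit reduction follows the stated tie-break order", {
  h <- rbind(hit_row("r1", "g1", 360L), hit_row("r1", "g1", 320L))
  expect_identical(best_hit_per_read(h)$identical_bases, 360L)
  # identity and score tie: lower subject_start wins
  t1 <- rbind(hit_row("r1", "g1", 300L, subject_start = 500L),
              hit_row("r1", "g1", 300L, subject_start = 100L))
  expect_identical(best_hit_per_read(t1)$subject_start, 100L)
  # global scope: genome_id breaks remaining ties lexicographically
  t2 <- rbind(hit_row("r1", "gB", 300L), hit_row("r1", "gA", 300L))
  expect_identical(best_hit_per_read(t2, scope = "global")$genome_id, "gA")
  expect_identical(nrow(best_hit_per_read(t2, scope = "per_genome")), 2L)
  # distinct reads are unaffected
  t3 <- rbind(hit_row("r1"), hit_row("r2"))
  expect_identical(nrow(best_hit_per_read(t3)), 2L)
})

test_that("recruitment summaries count >= 90% reads against the minimum total", {
  totals <- c(1347644L, 1532780L)
  h <- do.call(rbind, c(
    replicate(5, hit_row("rA", "gHigh", 380L), simplify = FALSE),
    list(hit_row("rB", "gHigh", 300L), hit_row("rC", "gLow", 250L))))
  h$read_id <- sprintf("r%d", seq_len(nrow(h)))
  s <- summarize_recruitment(h, totals)
  expect_identical(s$genome_id, c("gHigh", "gLow"))
  expect_identical(s$n_ge_high, c(5L, 0L))          # 0.75 < 0.90 <= 0.95
  expect_identical(s$n_hits_retained, c(6L, 1L))
  expect_identical(s$percentage[2L], 0)             # listed with 0.00
  # printed-count reproduction
  fake <- data.frame(read_id = sprintf("x%d", 1:2),
                     genome_id = c("M_bourgensis", "M_marisnigri"),
                     identical_bases = c(400L, 400L), read_length = 400L,
                     subject_start = 1L, subject_end = 400L, strand = "+")
  expect_identical(percentage_of_total(c(59969L, 3298L), totals),
                   c(4.45, 0.24))
  expect_identical(summarize_recruitment(fake, totals)$n_ge_high, c(1L, 1L))
})

test_that("identity histograms bin correctly, conserve counts, and normalize", {
  h <- rbind(hit_row("r1", identical_bases = 400L),   # 100%: last bin
             hit_row("r2", identical_bases = 380L),   # 95%
             hit_row("r3", identical_bases = 220L))   # 55%: first bin
  hb <- identity_histogram(h, totals = c(1000L, 2000L),
                           sample_total = 1000L)
  expect_identical(length(hb$counts), 45L)
  expect_identical(sum(hb$raw_counts), 3L)            # conservation
  expect_identical(hb$raw_counts[45L], 1L)
  expect_identical(hb$raw_counts[1L], 1L)
  expect_identical(hb$raw_counts[41L], 1L)            # [95, 96)
  expect_identical(hb$norm_factor, 1)                 # smallest sample: raw
  hb2 <- identity_histogram(h, totals = c(1000L, 2000L),
                            sample_total = 2000L)
  expect_equal(sum(hb2$counts), 3 * 0.5)
  expect_error(identity_histogram(hit_row(identical_bases = 100L),
                                  totals = 1000L), "filter_hits")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_histogram(hb, tf)
  expect_identical(nrow(read.delim(tf)), 45L)
})

test_that("recruitment points use the 1-based alignment midpoint", {
  h <- hit_row("r1", identical_bases = 300L, subject_start = 1L,
               subject_end = 401L, read_length = 400L)
  p <- recruitment_points(h)
  expect_equal(p$position, 201)
  expect_equal(p$identity, 75)
  p2 <- recruitment_points(h, position = "start")
  expect_equal(p2$position, 1)
  expect_error(recruitment_points(hit_row(identical_bases = 100L)),
               "filter_hits")
})

test_that("BLAST outfmt-6 hits reconstruct read-length identity", {
  b6 <- data.frame(q = c("r1", "r2"), s = c("gA", "gA"),
                   pident = c(97.5, 88), len = c(400L, 250L),
                   mm = c(10L, 30L), go = 0L, qs = 1L, qe = c(400L, 250L),
                   ss = c(101L, 900L), se = c(500L, 651L),
                   ev = 1e-50, bs = c(700, 300))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(b6, tf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  hits <- read_blast6(tf, read_lengths = c(r1 = 400L, r2 = 380L))
  expect_identical(hits$identical_bases, c(390L, 220L))
  expect_equal(compute_identity(hits), c(390 / 400, 220 / 380))
  # minus-strand hit normalized so start <= end
  expect_identical(hits$strand, c("+", "-"))
  expect_identical(hits$subject_start[2L], 651L)
  expect_identical(hits$subject_end[2L], 900L)
  expect_error(read_blast6(tf, read_lengths = c(r1 = 400L)), "r2")
})

test_that("k-mer aligner guarantees exact and reverse-complement recovery", {
  gs <- toy_genomes()
  g <- gs[[1L]]
  start0 <- 1234L
  frag <- substr(g$sequence, start0 + 1L, start0 + 300L)
  rs <- rs_from_seqs(c(frag, revcomp(frag)))
  hits <- align_reads(rs, gs)
  fwd <- hits[hits$read_id == "r001", ][1L, ]
  expect_identical(fwd$subject_start, start0 + 1L)
  expect_identical(fwd$genome_id, "gA")
  expect_equal(compute_identity(fwd), 1)
  rev_ <- hits[hits$read_id == "r002" & hits$strand == "-", ][1L, ]
  expect_identical(rev_$subject_start, start0 + 1L)
  expect_identical(rev_$subject_end, start0 + 300L)
  expect_equal(compute_identity(rev_), 1)
})

test_that("aligner identities equal the brute-force truth-offset oracle", {
  gs <- toy_genomes()
  spec <- community_spec(gs, c(0.5, 0.5), divergences = 0.05,
                         n_reads = 300L, read_length_mean = 400,
                         read_length_sd = 0.001, seed = 77L)
  rs <- simulate_reads(spec)
  hits <- best_hit_per_read(align_reads(rs, gs), scope = "global")
  expect_gte(nrow(hits) / rs$total_count, 0.99)   # seed survival ~ 1
  m <- merge(hits, data.frame(read_id = rs$reads$id,
                              idb_true = truth_identical_bases(rs, gs),
                              start_true = rs$reads$truth_start,
                              genome_true = rs$reads$truth_genome))
  at_truth <- m$subject_start == m$start_true + 1L &
    m$genome_id == m$genome_true
  expect_gte(mean(at_truth), 0.99)
  expect_identical(m$identical_bases[at_truth], m$idb_true[at_truth])
})

test_that("seeded and exhaustive aligners agree end to end on small instances", {
  g <- generate_genome(5000L, 0.5, seed = 55L, id = "gX")
  spec <- community_spec(list(g), 1, divergences = 0.04, n_reads = 50L,
                         read_length_mean = 80, read_length_sd = 5,
                         seed = 56L)
  rs <- simulate_reads(spec)
  fast <- best_hit_per_read(filter_hits(align_reads(rs, list(g), k = 9L)))
  slow <- best_hit_per_read(filter_hits(align_reads_exhaustive(rs, list(g))))
  expect_identical(nrow(fast), nrow(slow))
  key <- function(h) {
    d <- h[order(h$read_id), c("read_id", "identical_bases")]
    rownames(d) <- NULL
    d
  }
  expect_identical(key(fast), key(slow))
  totals <- c(1000L, 2000L)
  expect_identical(summarize_recruitment(fast, totals),
                   summarize_recruitment(slow, totals))
  expect_identical(identity_histogram(fast, totals)$raw_counts,
                   identity_histogram(slow, totals)$raw_counts)
})

test_that("flooring before or after best-hit selection is equivalent", {
  withr::local_seed(88)
  n <- 500L
  h <- data.frame(
    read_id = sprintf("r%d", sample.int(60L, n, TRUE)),
    genome_id = sample(c("gA", "gB"), n, TRUE),
    identical_bases = sample.int(400L, n, TRUE), read_length = 400L,
    subject_start = sample.int(5000L, n, TRUE), strand = "+",
    stringsAsFactors = FALSE)
  h$subject_end <- h$subject_start + 399L
  h$score <- h$identical_bases
  a <- best_hit_per_read(filter_hits(h))
  b <- filter_hits(best_hit_per_read(h))
  expect_identical(a[order(a$read_id, a$genome_id, a$subject_start), ],
                   b[order(b$read_id, b$genome_id, b$subject_start), ])
})

test_that("recruitment is specific: close reads go to the close reference", {
  gA <- generate_genome(20000L, 0.5, seed = 61L, id = "gA")
  gB <- mutate_genome(gA, 0.20, seed = 62L, id = "gB")
  spec <- community_spec(list(gA), 1, divergences = 0.02, n_reads = 400L,
                         read_length_mean = 300, read_length_sd = 20,
                         seed = 63L)
  rs <- simulate_reads(spec)
  hits <- best_hit_per_read(filter_hits(align_reads(rs, list(gA, gB))),
                            scope = "global")
  high <- hits[compute_identity(hits) >= 0.90, ]
  expect_gte(nrow(high) / rs$total_count, 0.9)
  expect_gte(mean(high$genome_id == "gA"), 0.99)
})
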