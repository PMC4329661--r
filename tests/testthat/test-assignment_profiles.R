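test_that("E-value filtering is boundary-inclusive at the threshold", {
  recs <- assign_df(c("r1", "r2", "r3"), c("a", "b", "c"),
                    evalue = c(1e-6, 1e-4, 1e-5))
  kept <- filter_by_evalue(recs, 1e-5)
  expect_setequal(kept$read_id, c("r1", "r3"))
  expect_identical(nrow(filter_by_evalue(recs[0, ], 1e-5)), 0L)
  expect_error(filter_by_evalue(recs, 0), "> 0")
})

test_that("profiles count taxa per rank and reject conflicting assignments", {
  recs <- assign_df(c("r1", "r2", "r3"), c("Clostridia", "Clostridia",
                                           "Bacilli"), rank = "class")
  p <- build_profile(recs, "class", 10L)
  expect_identical(p$counts, c(Bacilli = 1, Clostridia = 2))
  expect_equal(unname(relative_abundance(p)[c("Clostridia", "Bacilli")]),
               c(0.2, 0.1))
  # no records at the rank: empty counts, total preserved
  p0 <- build_profile(recs, "family", 10L)
  expect_identical(length(p0$counts), 0L)
  expect_identical(p0$total_reads, 10L)
  # duplicated read at the same rank is a hard error naming the read
  bad <- rbind(recs, assign_df("r1", "Bacilli", rank = "class"))
  expect_error(build_profile(bad, "class", 10L), "r1")
})

test_that("profiles at genus rank recover simulated truth frequencies", {
  gs <- toy_genomes()
  spec <- community_spec(gs, c(0.8, 0.2), divergences = 0,
                         n_reads = 1000L, seed = 31L)
  rs <- simulate_reads(spec)
  genus_of <- c(gA = "Methanoculleus", gB = "Clostridium")
  recs <- assign_df(rs$reads$id, unname(genus_of[rs$reads$truth_genome]),
                    rank = "genus")
  p <- build_profile(recs, "genus", rs$total_count)
  truth <- table(genus_of[rs$reads$truth_genome])
  expect_identical(p$counts[names(truth)],
                   setNames(as.numeric(truth), names(truth)))
})

test_that("smallest-dataset normalization scales counts and fixes the minimum", {
  a <- profile("WF", "family", c(fam1 = 100, fam2 = 50), 1532780L)
  b <- profile("DF", "family", c(fam1 = 80), 1347644L)
  nn <- normalize_to_smallest(list(a, b))
  expect_equal(nn[[1L]]$counts[["fam1"]], 100 * 1347644 / 1532780,
               tolerance = 1e-12)
  expect_equal(nn[[1L]]$counts[["fam1"]], 87.92, tolerance = 1e-4)
  expect_identical(nn[[2L]], b)              # smallest profile untouched
  expect_identical(nn[[1L]]$total_reads, 1347644L)
  # within-sample relative abundances preserved exactly
  expect_identical(relative_abundance(nn[[1L]]), relative_abundance(a))
  # sum of scaled counts never exceeds N_min
  expect_lte(sum(nn[[1L]]$counts), 1347644)
  # equal totals: identity
  c2 <- profile("X", "family", c(f = 5), 1000L)
  d2 <- profile("Y", "family", c(f = 9), 1000L)
  expect_identical(normalize_to_smallest(list(c2, d2)), list(c2, d2))
  expect_error(normalize_to_smallest(list(a)), "at least two")
  z <- profile("Z", "family", setNames(numeric(0), character(0)), 0L)
  expect_error(normalize_to_smallest(list(a, z)), "> 0")
})

test_that("percentages use the smallest total and half-up rounding", {
  totals <- c(1347644L, 1532780L)
  expect_identical(percentage_of_total(59969, totals), 4.45)
  expect_identical(percentage_of_total(15992, totals), 1.19)
  expect_identical(percentage_of_total(0, totals), 0)
  expect_error(percentage_of_total(-1, totals), "non-negative")
  expect_error(percentage_of_total(5, integer(0)), "non-empty")
  # half-up at an exactly representable midpoint: 0.125% -> 0.13
  expect_identical(percentage_of_total(1, c(800L, 900L)), 0.13)
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_identical(round_half_up(-0.125, 2), -0.13)
})

test_that("scatter points pseudocount, filter and mirror symmetry", {
  a <- profile("A", "family", c(absent_in_b = 999, shared = 10,
                                rare = 0.05), 100000L)
  b <- profile("B", "family", c(shared = 20, rare = 0.04), 100000L)
  sp <- scatter_points(a, b, pseudocount = 1, min_rel_sum = 1e-4)
  row <- sp[sp$taxon == "absent_in_b", ]
  expect_equal(row$x, 3)               # log10(999 + 1)
  expect_equal(row$y, 0)               # log10(0 + 1): pseudocount identity
  expect_false("rare" %in% sp$taxon)   # summed rel. abundance < 0.01%
  # swapping samples reflects the points across y = x
  sp2 <- scatter_points(b, a)
  m <- merge(sp, sp2, by = "taxon")
  expect_equal(m$x.x, m$y.y)
  expect_equal(m$y.x, m$x.y)
  # identical profiles sit on the diagonal
  self <- scatter_points(a, a)
  expect_equal(self$x, self$y)
  # unnormalized (unequal totals) inputs are rejected
  expect_error(scatter_points(a, profile("C", "family", c(x = 1), 99L)),
               "normalize")
  expect_gte(min(c(sp$x, sp$y)), 0)
})

test_that("unique gene tags need abundance >= 5 in one sample and 0 in the other", {
  mk <- function(ca, cb) list(
    profile("A", "pfam", c(tag = ca, other = 10), 1000L),
    profile("B", "pfam", c(tag = cb, other = 10), 1000L))
  u <- function(ca, cb) unique_egts(mk(ca, cb)[[1L]], mk(ca, cb)[[2L]])
  expect_identical(u(5, 0)$unique_to_a, "tag")
  expect_identical(u(4.9, 0)$unique_to_a, character(0))  # below threshold
  expect_identical(u(5, 1)$unique_to_a, character(0))    # not absent
  # symmetric swap
  p <- mk(7, 0)
  expect_identical(unique_egts(p[[1L]], p[[2L]])$unique_to_a,
                   unique_egts(p[[2L]], p[[1L]])$unique_to_b)
})

test_that("assignment tables round-trip through TSV with validation", {
  recs <- assign_df(c("r1", "r2"), c("Clostridiaceae", "Methanomicrobiaceae"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(recs, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_assignments(tf)
  expect_identical(back$taxon, recs$taxon)
  bad <- func_df("r1", "PF1")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_assignments(tf2), "PFxxxxx")
})

test_that("profile and Krona exports carry both denominators and lineages", {
  p <- profile("A", "family", c(Clostridiaceae = 30, Ruminococcaceae = 10),
               100L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, tf)
  tab <- read.delim(tf)
  expect_equal(tab$rel_abund_total, c(0.3, 0.1))
  expect_equal(tab$rel_abund_assigned, c(0.75, 0.25))
  kf <- withr::local_tempfile(fileext = ".tsv")
  write_krona(p, kf, lineage = list(
    Clostridiaceae = c("Bacteria", "Firmicutes", "Clostridia",
                       "Clostridiales", "Clostridiaceae")))
  lines <- readLines(kf)
  expect_match(lines[1L], "^30\tBacteria\tFirmicutes")
})
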