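test_that("exact-match alignment reports maximal matches in 0-based half-open coords", {
  aln <- exact_match_alignments(c(ctg = "ACGT"), genome("AACGTT"), min_len = 3)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$ref_start, 1L)
  expect_identical(aln$ref_end, 5L)
  expect_identical(aln$aligned_length, 4L)

  # a contig equal to a rotation of a circular chromosome aligns full length
  circ <- genome("ACGTTGCA", circular = TRUE)
  rot <- "GTTGCAAC" # rotation by 2
  aln2 <- exact_match_alignments(c(r = rot), circ, min_len = 3)
  expect_true(any(aln2$aligned_length == nchar(rot)))

  # chimeric contig: one factor per source chromosome, none full length
  gen <- genome(c("AAACCCGGGTTT", "TTTGGGCCCAAA"), id = c("c1", "c2"))
  chim <- paste0(substr(gen$sequence[1], 1, 6), substr(gen$sequence[2], 7, 12))
  aln3 <- exact_match_alignments(c(chim = chim), gen, min_len = 4)
  expect_setequal(unique(aln3$chromosome_id), c("c1", "c2"))
  expect_true(all(aln3$aligned_length < nchar(chim)))
})

test_that("the coverage profile takes the longest covering alignment per position", {
  gen <- genome(strrep("A", 100)) # only lengths matter for the sweep
  mk <- function(s, e) data.frame(contig_id = "c", chromosome_id = "chr1",
                                  ref_start = s, ref_end = e,
                                  contig_start = 0L, contig_end = e - s,
                                  aligned_length = e - s)
  # full single coverage
  p1 <- ea_profile(mk(0L, 100L), gen)
  expect_identical(eaxmax(p1, c(50, 75)), c(100, 100))
  # one length-60 alignment: half the genome covered at 60, rest uncovered
  p2 <- ea_profile(mk(0L, 60L), gen)
  expect_identical(eaxmax(p2, 50), 60)
  expect_identical(eaxmax(p2, 75), 0)
  # overlapping 80 and 40: best = 80 on [0,80), 40 on [80,100)
  p3 <- ea_profile(rbind(mk(0L, 80L), mk(60L, 100L)), gen)
  expect_identical(unname(p3$best[["chr1"]][c(1, 61, 80, 81, 100)]),
                   c(80L, 80L, 80L, 40L, 40L))
  expect_identical(eaxmax(p3, 50), 80)
  # 80% of positions have best >= 80, so the 75th percentile is still 80
  expect_identical(eaxmax(p3, 75), 80)
  expect_identical(eaxmax(p3, 90), 40)
  # EA0max equals the longest alignment; the curve is non-increasing
  curve <- ea_curve(p3)
  expect_identical(curve$eaxmax[1], 80)
  expect_true(all(diff(curve$eaxmax) <= 0))
})

test_that("genome fraction and duplication ratio", {
  gen <- genome(strrep("A", 100))
  mk <- function(s, e) data.frame(contig_id = "c", chromosome_id = "chr1",
                                  ref_start = s, ref_end = e,
                                  contig_start = 0L, contig_end = e - s,
                                  aligned_length = e - s)
  expect_equal(unname(coverage_stats(mk(0L, 100L), gen)), c(100, 1))
  expect_equal(unname(coverage_stats(rbind(mk(0L, 100L), mk(0L, 100L)), gen)),
               c(100, 2))
  expect_equal(unname(coverage_stats(mk(0L, 50L), gen)), c(50, 1))
})

test_that("misassembly breakpoints are deduplicated per reference position", {
  bp <- data.frame(chromosome_id = c("c1", "c1", "c1", "c2"),
                   position = c(10L, 10L, 10L, 10L))
  expect_identical(dedup_misassemblies(bp), 2L)
  expect_identical(dedup_misassemblies(bp[0, ]), 0L)
  expect_identical(dedup_misassemblies(data.frame(chromosome_id = c("c1", "c1"),
                                                  position = c(3L, 7L))), 2L)

  # a crafted chimera yields a breakpoint; dedup keeps it single across contigs
  gen <- genome(c("AAACCCGGGTTT", "TTTGGGCCCAAA"), id = c("c1", "c2"))
  chim <- paste0(substr(gen$sequence[1], 1, 6), substr(gen$sequence[2], 7, 12))
  aln <- exact_match_alignments(c(a = chim, b = chim), gen, min_len = 4)
  bps <- alignment_breakpoints(aln, c(a = nchar(chim), b = nchar(chim)))
  expect_gte(nrow(bps), 2L)
  expect_lte(dedup_misassemblies(bps), nrow(bps))
})

test_that("full evaluation report on an error-free circular assembly", {
  gen <- generate_genome(genome_spec(length_range = c(400L, 400L),
                                     circular = TRUE,
                                     planted = list(plant_bubble(
                                       arm_len = 30L, flank_len = 60L))),
                         seed = 31)
  k <- 15L
  ev_u <- evaluate_contigs(assemble_genome(gen, k, mode = "unitigs"), gen, k)
  ev_s <- evaluate_contigs(assemble_genome(gen, k), gen, k)
  expect_identical(ev_s$misassemblies, 0L)
  expect_equal(ev_s$genome_fraction, 100)
  # overlapping simple omnitigs duplicate flanks: duplication ratio not below unitigs
  expect_gte(ev_s$duplication_ratio, ev_u$duplication_ratio)
  # dominance at every percentile
  expect_true(all(ev_s$curve$eaxmax >= ev_u$curve$eaxmax))
})

test_that("homopolymer-compressed evaluation compresses both sides", {
  gen <- genome("AAACCCGGGTTTAAACCC")
  ev <- evaluate_contigs(c(x = "ACGTAC"), gen, k = 3, hpc = TRUE)
  expect_equal(ev$genome_fraction, 100) # compressed genome is ACGTAC
  expect_identical(ev$misassemblies, 0L)
})
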