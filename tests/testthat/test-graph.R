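test_that("homopolymer compression collapses runs and is idempotent", {
  expect_identical(compress_homopolymers("AAACCGTT"), "ACGT")
  expect_identical(compress_homopolymers("ACGT"), "ACGT")
  expect_identical(compress_homopolymers(""), "")
  # property: idempotent and length-non-increasing on random strings
  set.seed(11)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(0:40, 1), replace = TRUE),
               collapse = "")
    h <- compress_homopolymers(s)
    expect_lte(nchar(h), nchar(s))
    expect_identical(compress_homopolymers(h), h)
    expect_false(grepl("(.)\\1", h))
  }
})

test_that("k-spectrum enumerates windows, wraps circular chromosomes, skips non-alphabet windows", {
  expect_identical(k_spectrum(genome("ACGTA"), 3)$kmers, c("ACG", "CGT", "GTA"))
  expect_identical(k_spectrum(genome("ACGT", circular = TRUE), 3)$kmers,
                   sort(c("ACG", "CGT", "GTA", "TAC")))
  sp <- k_spectrum(genome("ACNGT"), 3)
  expect_identical(sp$kmers, character(0))
  expect_identical(attr(sp, "skipped"), 3L)
  expect_error(k_spectrum(genome("AC"), 3), "chr1")
  expect_error(k_spectrum(genome("ACGT"), 1), "at least 2")
})

test_that("de Bruijn graph has one arc per k-mer joining prefix to suffix", {
  g <- build_de_bruijn(structure(list(k = 3L, kmers = c("ACG", "CGT")),
                                 class = "k_spectrum"))
  expect_identical(g$labels, c("AC", "CG", "GT"))
  expect_identical(g$m, 2L)
  expect_identical(g$labels[g$tail], c("AC", "CG"))
  expect_identical(g$labels[g$head], c("CG", "GT"))

  # circular ACGT at k = 3: one 4-cycle, every node degree (1, 1)
  gc <- build_de_bruijn(k_spectrum(genome("ACGT", circular = TRUE), 3))
  expect_identical(gc$n, 4L)
  expect_identical(gc$m, 4L)
  expect_true(all(gc$indeg == 1L) && all(gc$outdeg == 1L))

  # single k-mer with equal prefix and suffix: a self-loop
  gl <- build_de_bruijn(structure(list(k = 3L, kmers = "AAA"),
                                  class = "k_spectrum"))
  expect_identical(gl$labels, "AA")
  expect_identical(c(gl$tail, gl$head), c(1L, 1L))
})

test_that("degree profiles and split/join predicates follow the definitions", {
  g <- build_de_bruijn(structure(list(k = 3L, kmers = c("ACG", "CGT")),
                                 class = "k_spectrum"))
  expect_identical(unname(degree_profile(g, "AC")), c(0L, 1L))
  expect_false(is_split(g, "AC"))
  expect_false(is_join(g, "AC"))
  expect_error(degree_profile(g, "ZZ"), "unknown node")

  centre <- label_graph(c("a", "b", "v"), c("v", "v", "c"))
  expect_true(is_join(centre, "v"))
  expect_false(is_split(centre, "v"))

  loop <- build_de_bruijn(structure(list(k = 3L, kmers = "AAA"),
                                    class = "k_spectrum"))
  expect_identical(unname(degree_profile(loop, "AA")), c(1L, 1L))
  expect_false(is_split(loop, "AA"))
  expect_false(is_join(loop, "AA"))
})

test_that("arc counts and degree sums match the genome model", {
  # linear, all k-mers distinct: m = L - k + 1; circular: m = L
  gen <- generate_genome(genome_spec(length_range = c(300L, 300L)), seed = 5)
  k <- 21L
  g <- build_de_bruijn(k_spectrum(gen, k))
  expect_identical(g$m, nchar(gen$sequence[1]) - k + 1L)
  genc <- generate_genome(genome_spec(length_range = c(300L, 300L),
                                      circular = TRUE), seed = 6)
  gc <- build_de_bruijn(k_spectrum(genc, k))
  expect_identical(gc$m, nchar(genc$sequence[1]))
  # degree sums equal m on random graphs
  for (s in 1:20) {
    rg <- random_digraph(8, 15, seed = s)
    expect_identical(sum(rg$indeg), rg$m)
    expect_identical(sum(rg$outdeg), rg$m)
  }
})

test_that("every chromosome induces a walk in its de Bruijn graph", {
  gen <- generate_genome(genome_spec(n_chromosomes = 3L,
                                     length_range = c(100L, 300L)), seed = 9)
  k <- 7L
  g <- build_de_bruijn(k_spectrum(gen, k))
  for (i in seq_len(nrow(gen))) {
    s <- gen$sequence[i]
    nodes <- substring(s, 1:(nchar(s) - k + 2L), (1:(nchar(s) - k + 2L)) + k - 2L)
    # resolve_walk validates consecutive-node adjacency and errors otherwise
    expect_silent(simpleomni:::resolve_walk(g, nodes))
    expect_identical(spell(g, nodes), s)
  }
})

test_that("edge-list reader builds a labelled digraph and skips comments", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "a\tb", "b\tc", "", "b\tb  # trailing"), f)
  g <- read_edge_list(f)
  expect_identical(g$n, 3L)
  expect_identical(g$m, 3L)
  expect_identical(unname(degree_profile(g, "b")), c(2L, 2L))
  expect_error(read_edge_list({
    f2 <- tempfile(); writeLines("a b c", f2); f2
  }), "malformed")
})

test_that("FASTA round trip preserves ids, case and circular flags", {
  gen <- genome(c("acgtACGTacgt", "TTTTCCCC"), id = c("plasmid", "chr"),
                circular = c(TRUE, FALSE))
  f <- tempfile(fileext = ".fasta")
  write_genome_fasta(gen, f)
  back <- read_genome_fasta(f)
  expect_identical(back$id, gen$id)
  expect_identical(back$sequence, c("ACGTACGTACGT", "TTTTCCCC"))
  expect_identical(back$circular, c(TRUE, FALSE))
})
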