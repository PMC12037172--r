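test_that("core_of finds the last inner split and first inner join", {
  fx <- structure_fixtures()$annotated_walk
  co <- core_of(fx$graph, paste0("w", 1:10))
  expect_true(co$present)
  expect_identical(co$j, 4L)
  expect_identical(co$i, 6L)
  expect_identical(labels_of(fx$graph, co$core), c("w4", "w5", "w6"))

  path <- label_graph(c("a", "b"), c("b", "c"))
  co2 <- core_of(path, c("a", "b", "c"))
  expect_true(co2$present)
  expect_identical(c(co2$j, co2$i), c(1L, 3L))
  expect_identical(labels_of(path, co2$core), c("a", "b", "c"))

  sj <- split_join_graph()
  co3 <- core_of(sj, c("x", "v", "y"))
  expect_false(co3$present)
  expect_identical(c(co3$j, co3$i), c(2L, 2L))

  expect_error(core_of(path, "a"), "single-node")
})

test_that("simple omnitig predicate follows the core definition", {
  fx <- structure_fixtures()$annotated_walk
  expect_true(is_simple_omnitig(fx$graph, paste0("w", 1:10)))
  expect_true(is_simple_omnitig(fx$graph, c("w1", "w2"))) # any single arc
  expect_false(is_simple_omnitig(split_join_graph(), c("x", "v", "y")))
})

test_that("maximal unitigs partition the arcs and stop at branching nodes", {
  fx <- structure_fixtures()$bubble
  mu <- maximal_unitigs(fx$graph)
  expect_setequal(sigs(mu), walk_sigs(list(
    c("a", "s"), c("s", "v1", "j"), c("s", "v2", "j"), c("j", "b")
  ), kind = "maximal_unitig"))

  # pure cycle: one circular unitig covering all four arcs
  gc <- build_de_bruijn(k_spectrum(genome("ACGT", circular = TRUE), 3))
  mc <- maximal_unitigs(gc)
  expect_identical(mc$kind, "circular_unitig")
  expect_identical(length(mc$walks[[1]]), 5L)
  expect_identical(mc$walks[[1]][1], mc$walks[[1]][5])
  expect_identical(spell(gc, mc$walks[[1]]), "ACGTAC")

  single <- label_graph("u", "v")
  expect_identical(sigs(maximal_unitigs(single)),
                   walk_sigs(list(c("u", "v")), kind = "maximal_unitig"))

  # arc partition on random graphs
  for (s in 1:25) {
    g <- random_digraph(9, 18, seed = 100 + s)
    mu <- maximal_unitigs(g)
    pairs <- unlist(lapply(mu$walks, function(w)
      paste(w[-length(w)], w[-1], sep = ">")))
    expect_identical(sort(pairs), sort(paste(g$tail, g$head, sep = ">")))
  }
})

test_that("core-of-maximal-simple-omnitig conditions on unitig endpoints", {
  fx <- structure_fixtures()$bubble
  g <- fx$graph
  expect_true(is_core_of_maximal_simple_omnitig(g, c("s", "v1", "j")))
  expect_true(is_core_of_maximal_simple_omnitig(g, c("s", "v2", "j")))
  expect_false(is_core_of_maximal_simple_omnitig(g, c("a", "s"))) # head is a split with in-degree 1
  path <- label_graph(c("a", "b"), c("b", "c"))
  expect_true(is_core_of_maximal_simple_omnitig(path, c("a", "b", "c")))
  expect_error(is_core_of_maximal_simple_omnitig(fx$graph, c("a", "s", "v1")),
               "not a unitig")
})

test_that("univocal extension runs through degree-one flanks and covers cycles once", {
  fx <- structure_fixtures()$bubble
  ext <- univocal_extension(fx$graph, c("s", "v1", "j"))
  expect_identical(labels_of(fx$graph, ext), c("a", "s", "v1", "j", "b"))

  path <- label_graph(c("a", "b"), c("b", "c"))
  expect_identical(labels_of(path, univocal_extension(path, "b")),
                   c("a", "b", "c"))

  gc <- build_de_bruijn(k_spectrum(genome("ACGT", circular = TRUE), 3))
  w <- univocal_extension(gc, c("AC", "CG"))
  expect_identical(length(w), 5L)
  expect_identical(w[1], w[5])
  expect_identical(anyDuplicated(paste(w[-5], w[-1])), 0L) # no arc repeated
})

test_that("maximal simple omnitigs match the fixture expectations", {
  fx <- structure_fixtures()
  expect_setequal(sigs(maximal_simple_omnitigs(fx$bubble$graph)),
                  walk_sigs(fx$bubble$expected))
  expect_setequal(sigs(maximal_simple_omnitigs(fx$`repeat`$graph)),
                  walk_sigs(fx$`repeat`$expected))
  expect_setequal(sigs(maximal_simple_omnitigs(fx$annotated_walk$graph)),
                  walk_sigs(fx$annotated_walk$expected))

  path <- label_graph(c("a", "b"), c("b", "c"))
  expect_setequal(sigs(maximal_simple_omnitigs(path)),
                  walk_sigs(list(c("a", "b", "c"))))
})

test_that("without branching, simple omnitigs degenerate to unitigs", {
  # two disjoint paths plus one isolated cycle
  g <- digraph(c(1, 2, 4, 5, 7, 8, 9), c(2, 3, 5, 6, 8, 9, 7), n_nodes = 9)
  expect_setequal(sigs(maximal_simple_omnitigs(g)),
                  sub("^maximal_unitig", "maximal_simple_omnitig",
                      sigs(maximal_unitigs(g))))
})

test_that("extension is idempotent away from cycles", {
  g <- simpleomni:::bubble_chain_graph(4L)
  set.seed(3)
  for (rep in 1:10) {
    e <- sample.int(g$m, 1)
    w1 <- univocal_extension(g, c(g$tail[e], g$head[e]))
    expect_identical(univocal_extension(g, w1), w1)
  }
})

test_that("spelling a walk appends one character per arc", {
  g <- build_de_bruijn(structure(list(k = 3L, kmers = c("ACG", "CGT")),
                                 class = "k_spectrum"))
  expect_identical(spell(g, c("AC", "CG", "GT")), "ACGT")
  expect_identical(spell(g, "AC"), "AC")
  expect_error(spell(random_digraph(3, 3, seed = 1), c(1L, 2L)), "label")
})
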