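#' Property suites at configurable scale
#'
#' These functions drive the package's own verification experiments; the test
#' suite and the `selftest` subcommand call them at different scales. Each is
#' deterministic given `base_seed` (per-case seeds are derived arithmetically
#' from it).
#'
#' `oracle_equivalence_suite()` draws seeded random digraphs and compares
#' [maximal_simple_omnitigs()] with the brute-force oracle
#' [maximal_simple_omnitigs_bruteforce()] by set equality of node sequences,
#' also checking three structural invariants on the fast path: the arcs of
#' the maximal unitigs partition the arc set, every maximal unitig is a
#' subwalk of some output walk, and no output walk is a subwalk of another.
#' Graphs on which no finite maximal simple omnitig set exists (the oracle
#' reports truncation: a non-isolated all-out-degree-one or all-in-degree-one
#' cycle) are skipped and replaced by further seeds until `n_graphs`
#' applicable graphs have been compared.
#'
#' @param n_graphs number of applicable random graphs to compare.
#' @param base_seed integer seed.
#' @param n_range node-count range for the random graphs.
#' @param m_max maximum arc count.
#' @return list of counters: `tested`, `mismatches`, `skipped`,
#'   `partition_violations`, `containment_violations`, `antichain_violations`.
#' @export
oracle_equivalence_suite <- function(n_graphs = 200L, base_seed = 1L,
                                     n_range = c(3L, 12L), m_max = 25L) {
  tested <- 0L; mismatches <- 0L; skipped <- 0L
  part_bad <- 0L; cont_bad <- 0L; anti_bad <- 0L
  i <- 0L
  while (tested < n_graphs) {
    i <- i + 1L
    seed_i <- derive_seed(base_seed, i)
    par <- with_seed(seed_i, {
      n <- sample(n_range[1L]:n_range[2L], 1L)
      list(n = n, m = sample.int(min(m_max, n * n), 1L))
    })
    g <- random_digraph(par$n, par$m, seed = seed_i + 1L)
    oracle <- tryCatch(maximal_simple_omnitigs_bruteforce(g),
                       simpleomni_budget = function(e) NULL)
    if (is.null(oracle) || isTRUE(attr(oracle, "truncated"))) {
      skipped <- skipped + 1L
      next
    }
    tested <- tested + 1L
    fast <- maximal_simple_omnitigs(g)
    if (!identical(contig_signatures(fast), contig_signatures(oracle))) {
      mismatches <- mismatches + 1L
    }
    inv <- contig_invariants(g, fast)
    part_bad <- part_bad + !inv$partition
    cont_bad <- cont_bad + !inv$containment
    anti_bad <- anti_bad + !inv$antichain
  }
  list(tested = tested, mismatches = mismatches, skipped = skipped,
       partition_violations = part_bad, containment_violations = cont_bad,
       antichain_violations = anti_bad)
}

# Structural invariants of the fast path on one graph.
contig_invariants <- function(g, sos = maximal_simple_omnitigs(g)) {
  mu <- maximal_unitigs(g)
  # arc partition: consecutive node pairs of all unitigs = arc multiset
  pair_of <- function(w) if (length(w) >= 2L)
    paste(w[-length(w)], w[-1L], sep = ">") else character(0)
  pairs <- unlist(lapply(mu$walks, pair_of))
  arcs <- paste(g$tail, g$head, sep = ">")
  partition <- identical(sort(pairs), sort(arcs))
  # containment: every maximal unitig is a subwalk of some output walk
  # (closed circular walks are compared over their doubled node sequence so
  #  any rotation of the same cycle counts as contained)
  target <- lapply(seq_along(sos$walks), function(idx) {
    w <- sos$walks[[idx]]
    if (sos$kind[idx] == "circular_unitig") c(w, w[-1L]) else w
  })
  containment <- all(vapply(mu$walks, function(u)
    any(vapply(target, function(t) is_subwalk(u, t), TRUE)), TRUE))
  # antichain: no output walk is a proper subwalk of another
  antichain <- TRUE
  ww <- sos$walks
  if (length(ww) >= 2L) {
    for (a in seq_along(ww)) {
      for (b in seq_along(ww)) {
        if (a != b && length(ww[[a]]) <= length(ww[[b]]) &&
            !identical(ww[[a]], ww[[b]]) && is_subwalk(ww[[a]], ww[[b]])) {
          antichain <- FALSE
          break
        }
      }
      if (!antichain) break
    }
  }
  list(partition = partition, containment = containment, antichain = antichain)
}

#' @rdname oracle_equivalence_suite
#' @param n_genomes number of random genomes.
#' @param ks word sizes cycled over the genomes.
#' @return `linear_safety_suite()` / `circular_safety_suite()`: list with
#'   `genomes`, `contigs_checked`, `violations`, `exempt`.
#' @export
linear_safety_suite <- function(n_genomes = 100L, base_seed = 1L,
                                ks = c(5L, 9L, 15L)) {
  violations <- 0L; checked <- 0L; exempt <- 0L
  for (i in seq_len(n_genomes)) {
    seed_i <- derive_seed(base_seed, 1000L + i)
    k <- ks[(i - 1L) %% length(ks) + 1L]
    nchr <- with_seed(seed_i, sample(2:4, 1L))
    gen <- generate_genome(genome_spec(n_chromosomes = nchr,
                                       length_range = c(200L, 2000L)),
                           seed = seed_i + 1L)
    contigs <- assemble_genome(gen, k)
    rep <- verify_safety(contigs, gen, k)
    s <- attr(rep, "summary")
    checked <- checked + nrow(rep)
    exempt <- exempt + s[["exempt_touches_L"]]
    violations <- violations + s[["unsafe"]]
  }
  list(genomes = n_genomes, contigs_checked = checked,
       violations = violations, exempt = exempt)
}

#' @rdname oracle_equivalence_suite
#' @export
circular_safety_suite <- function(n_genomes = 100L, base_seed = 1L,
                                  ks = c(5L, 9L, 15L)) {
  violations <- 0L; checked <- 0L; exempt <- 0L
  for (i in seq_len(n_genomes)) {
    seed_i <- derive_seed(base_seed, 2000L + i)
    k <- ks[(i - 1L) %% length(ks) + 1L]
    gen <- generate_genome(genome_spec(n_chromosomes = 1L,
                                       length_range = c(200L, 2000L),
                                       circular = TRUE),
                           seed = seed_i)
    contigs <- assemble_genome(gen, k)
    rep <- verify_safety(contigs, gen, k)
    s <- attr(rep, "summary")
    checked <- checked + nrow(rep)
    exempt <- exempt + s[["exempt_touches_L"]]
    violations <- violations + s[["unsafe"]]
  }
  list(genomes = n_genomes, contigs_checked = checked,
       violations = violations, exempt = exempt)
}

#' @rdname oracle_equivalence_suite
#' @param k word size for the contiguity comparison.
#' @return `eaxmax_dominance_suite()`: list with `genomes`,
#'   `dominance_violations`, `strict_improvements`, and the mean EA50max of
#'   both contig classes.
#' @export
eaxmax_dominance_suite <- function(n_genomes = 20L, base_seed = 1L, k = 15L) {
  dom_bad <- 0L; strict <- 0L
  ea50_sos <- numeric(n_genomes); ea50_utg <- numeric(n_genomes)
  for (i in seq_len(n_genomes)) {
    seed_i <- derive_seed(base_seed, 3000L + i)
    spec <- genome_spec(
      n_chromosomes = 1L, length_range = c(1600L, 2400L), circular = TRUE,
      planted = list(plant_bubble(arm_len = 50L, divergences = 1L,
                                  flank_len = 120L),
                     plant_repeat(copies = 2L, repeat_len = 100L,
                                  flank_len = 120L))
    )
    gen <- generate_genome(spec, seed = seed_i)
    g <- build_de_bruijn(k_spectrum(gen, k))
    utg <- maximal_unitigs(g)
    sos <- maximal_simple_omnitigs(g)
    ev_u <- evaluate_contigs(utg, gen, k)
    ev_s <- evaluate_contigs(sos, gen, k)
    diff <- ev_s$curve$eaxmax - ev_u$curve$eaxmax
    if (any(diff < 0)) dom_bad <- dom_bad + 1L
    branching <- any(g$outdeg >= 2L | g$indeg >= 2L)
    if (branching && any(diff > 0)) strict <- strict + 1L
    ea50_sos[i] <- ev_s$ea50max
    ea50_utg[i] <- ev_u$ea50max
  }
  list(genomes = n_genomes, dominance_violations = dom_bad,
       strict_improvements = strict,
       mean_ea50max_simple_omnitigs = mean(ea50_sos),
       mean_ea50max_unitigs = mean(ea50_utg))
}

#' @rdname oracle_equivalence_suite
#' @param n_bubbles sizes of the growing bubble-chain graph family.
#' @return `complexity_trend()`: data frame with columns `m`, `out`, `ops`
#'   (work counter of [maximal_simple_omnitigs()]).
#' @export
complexity_trend <- function(n_bubbles = c(5L, 10L, 20L, 40L, 80L, 160L)) {
  rows <- lapply(n_bubbles, function(b) {
    g <- bubble_chain_graph(b)
    sos <- maximal_simple_omnitigs(g)
    data.frame(m = g$m, out = sum(lengths(sos$walks)),
               ops = attr(sos, "ops"))
  })
  do.call(rbind, rows)
}

# A chain of b bubbles: ... -> s_i -> {v_i, v_i'} -> j_i -> s_{i+1} -> ...
bubble_chain_graph <- function(b) {
  # nodes per bubble: s, v, v', j ; j_i connects to s_{i+1}
  tails <- integer(0); heads <- integer(0)
  for (i in seq_len(b)) {
    o <- (i - 1L) * 4L
    s <- o + 1L; v1 <- o + 2L; v2 <- o + 3L; j <- o + 4L
    tails <- c(tails, s, s, v1, v2)
    heads <- c(heads, v1, v2, j, j)
    if (i < b) {
      tails <- c(tails, j)
      heads <- c(heads, o + 5L)
    }
  }
  digraph(tails, heads, n_nodes = 4L * b)
}

# Derived per-case seed, kept inside 32-bit integer range.
derive_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) * 48271 + as.double(i) * 7919) %% 2147483647)
}
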