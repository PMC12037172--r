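#' Synthetic genome specification
#'
#' Describes an error-free genome to simulate: chromosome count, length
#' range, circularity and planted structures (exact repeats and
#' heterozygous-style bubbles). Generation is a pure function of
#' (spec, seed). Planted structures are placed on the first chromosome;
#' remaining chromosomes are plain random sequence.
#'
#' @param n_chromosomes number of chromosomes.
#' @param length_range two-element integer vector of chromosome lengths
#'   (drawn uniformly).
#' @param circular logical, recycled across chromosomes.
#' @param planted list of structure specs from [plant_repeat()] /
#'   [plant_bubble()].
#' @param alphabet characters for the random background.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 1L, length_range = c(1000L, 2000L),
                        circular = FALSE, planted = list(),
                        alphabet = c("A", "C", "G", "T")) {
  stopifnot(n_chromosomes >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L])
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 length_range = as.integer(length_range),
                 circular = rep_len(as.logical(circular), n_chromosomes),
                 planted = planted, alphabet = alphabet),
            class = "genome_spec")
}

#' Planted structure specs
#'
#' `plant_repeat()` plants `copies` exact copies of one random repeat
#' sequence, separated by random flanks (genome layout `A X B ... C X D`):
#' for k below the repeat length the de Bruijn graph gains a join entering
#' and a split leaving the collapsed repeat. `plant_bubble()` plants two
#' copies of a flanked arm that differ at `divergences` positions (layout
#' `F1 V1 F2 ... F1 V2 F2`): the graph gains a split where the arms diverge
#' and a join where they reconverge.
#'
#' @param copies number of exact repeat copies (>= 2).
#' @param repeat_len length of the repeated sequence.
#' @param flank_len length of the random separators around/between copies.
#' @return a structure spec for [genome_spec()].
#' @export
plant_repeat <- function(copies = 2L, repeat_len = 100L, flank_len = 200L) {
  stopifnot(copies >= 2L, repeat_len >= 1L, flank_len >= 1L)
  structure(list(type = "repeat", copies = as.integer(copies),
                 repeat_len = as.integer(repeat_len),
                 flank_len = as.integer(flank_len)),
            class = "planted_structure")
}

#' @rdname plant_repeat
#' @param arm_len length of each bubble arm.
#' @param divergences number of positions at which the two arms differ.
#' @export
plant_bubble <- function(arm_len = 50L, divergences = 1L, flank_len = 200L) {
  stopifnot(arm_len >= 1L, divergences >= 1L, divergences <= arm_len,
            flank_len >= 1L)
  structure(list(type = "bubble", arm_len = as.integer(arm_len),
                 divergences = as.integer(divergences),
                 flank_len = as.integer(flank_len)),
            class = "planted_structure")
}

rand_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Total sequence length a planted structure contributes.
structure_length <- function(st) {
  switch(st$type,
    "repeat" = st$copies * st$repeat_len + (st$copies - 1L) * st$flank_len,
    "bubble" = 2L * (st$arm_len + 2L * st$flank_len) + st$flank_len
  )
}

# Realise one planted structure as a string (pure given the RNG state).
realise_structure <- function(st, alphabet) {
  if (st$type == "repeat") {
    rep_seq <- rand_seq(st$repeat_len, alphabet)
    parts <- character(0)
    for (cp in seq_len(st$copies)) {
      parts <- c(parts, rep_seq)
      if (cp < st$copies) parts <- c(parts, rand_seq(st$flank_len, alphabet))
    }
    paste(parts, collapse = "")
  } else {
    f1 <- rand_seq(st$flank_len, alphabet)
    f2 <- rand_seq(st$flank_len, alphabet)
    v1 <- rand_seq(st$arm_len, alphabet)
    v2c <- strsplit(v1, "")[[1L]]
    at <- sample.int(st$arm_len, st$divergences)
    for (p in at) {
      v2c[p] <- sample(setdiff(alphabet, v2c[p]), 1L)
    }
    mid <- rand_seq(st$flank_len, alphabet)
    paste0(f1, v1, f2, mid, f1, paste(v2c, collapse = ""), f2)
  }
}

#' Generate a synthetic genome
#'
#' Random background sequence with the spec's planted structures spliced into
#' the first chromosome, padded with random sequence to the drawn target
#' length. Reproducible: the same (spec, seed) always yields a byte-identical
#' genome.
#'
#' @param spec a [genome_spec].
#' @param seed integer seed.
#' @return a [genome].
#' @export
generate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  struct_len <- sum(vapply(spec$planted, structure_length, 1L))
  if (struct_len > spec$length_range[2L]) {
    stop(sprintf(paste0("infeasible spec: planted structures need %d bp but ",
                        "the maximum chromosome length is %d"),
                 struct_len, spec$length_range[2L]))
  }
  with_seed(seed, {
    seqs <- character(spec$n_chromosomes)
    for (i in seq_len(spec$n_chromosomes)) {
      target <- spec$length_range[1L] +
        sample.int(spec$length_range[2L] - spec$length_range[1L] + 1L, 1L) - 1L
      if (i == 1L && length(spec$planted)) {
        target <- max(target, struct_len)
        pad_total <- target - struct_len
        # split the padding around the structures
        n_gaps <- length(spec$planted) + 1L
        cuts <- sort(sample.int(pad_total + 1L, n_gaps - 1L, replace = TRUE) - 1L)
        gaps <- diff(c(0L, cuts, pad_total))
        parts <- rand_seq(gaps[1L], spec$alphabet)
        for (si in seq_along(spec$planted)) {
          parts <- c(parts, realise_structure(spec$planted[[si]], spec$alphabet),
                     rand_seq(gaps[si + 1L], spec$alphabet))
        }
        seqs[i] <- paste(parts, collapse = "")
      } else {
        seqs[i] <- rand_seq(target, spec$alphabet)
      }
    }
    genome(seqs, circular = spec$circular)
  })
}

#' Seeded random digraph
#'
#' Erdos-Renyi-style arc sampling: `m` ordered pairs drawn uniformly without
#' replacement from the `n^2` possible arcs (self-loops included; parallel
#' arcs excluded). Used by the oracle-equivalence suites.
#'
#' @param n number of nodes.
#' @param m number of arcs (at most `n^2`).
#' @param seed integer seed.
#' @return a [digraph].
#' @export
random_digraph <- function(n, m, seed = 1L) {
  stopifnot(m <= n * n)
  with_seed(seed, {
    pairs <- sample.int(n * n, m)
    digraph(((pairs - 1L) %/% n) + 1L, ((pairs - 1L) %% n) + 1L, n_nodes = n)
  })
}

#' Hand-built structural fixtures with known maximal simple omnitigs
#'
#' Three small abstract digraphs exercising the canonical shapes:
#' \describe{
#'   \item{annotated_walk}{a ten-node walk `w1..w10` whose node `w4` carries
#'     one extra outgoing arc (to sink `x`, making it the last inner split)
#'     and whose node `w6` carries one extra incoming arc (from source `y`,
#'     making it the first inner join), so the walk is a maximal simple
#'     omnitig with core `(w4, w5, w6)`;}
#'   \item{bubble}{two length-matched arms `V1`/`V2` between a split and a
#'     join, with entry flank `A` and exit flank `B`: the maximal simple
#'     omnitigs are exactly `A.V1.B` and `A.V2.B`, each arm carried through
#'     both flanks;}
#'   \item{repeat}{a repeat node `X` with two entries (`A`, `C`) and two
#'     exits (`B`, `D`): the maximal simple omnitigs are exactly `A.X`,
#'     `C.X`, `X.B` and `X.D`.}
#' }
#' The expected outputs attached here are hand-derived and are cross-checked
#' against the brute-force oracle in the test suite.
#'
#' @return named list; each element has fields `graph`, `expected` (list of
#'   label vectors, the maximal simple omnitigs) and optionally `core`.
#' @export
structure_fixtures <- function() {
  wn <- paste0("w", 1:10)
  annotated <- digraph_from_labels(
    tails = c(wn[1:9], "w4", "y"),
    heads = c(wn[2:10], "x", "w6")
  )
  bubble <- digraph_from_labels(
    tails = c("a", "s", "v1", "s", "v2", "j"),
    heads = c("s", "v1", "j", "v2", "j", "b")
  )
  rep_g <- digraph_from_labels(
    tails = c("A", "C", "X", "X"),
    heads = c("X", "X", "B", "D")
  )
  list(
    annotated_walk = list(
      graph = annotated,
      expected = list(wn, c(wn[1:4], "x"), c("y", wn[6:10])),
      core = c("w4", "w5", "w6")
    ),
    bubble = list(
      graph = bubble,
      expected = list(c("a", "s", "v1", "j", "b"), c("a", "s", "v2", "j", "b"))
    ),
    "repeat" = list(
      graph = rep_g,
      expected = list(c("A", "X"), c("C", "X"), c("X", "B"), c("X", "D"))
    )
  )
}
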