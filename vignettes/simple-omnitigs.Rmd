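---
title: "Simple omnitigs: safe overlapping contigs from de Bruijn graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simple omnitigs: safe overlapping contigs from de Bruijn graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`simpleomni` works on directed multigraphs. In genome assembly the graph of
interest is the arc-centric de Bruijn graph of a k-spectrum: nodes are the
(k-1)-mers, and every k-mer contributes one arc from its (k-1)-prefix to its
(k-1)-suffix. A walk spells a string by writing its first node and then the
last character of each subsequent node. The classical contig notion is the
*maximal unitig*: a walk whose interior nodes all have in- and out-degree
one, extended as far as possible. Unitigs are safe — under an error-free,
perfect-coverage model their spelled strings occur in the genome — but they
stop at every branching node, which fragments assemblies around repeats and
bubbles.

A *split* is a node with at least two outgoing arcs; a *join* has at least
two incoming arcs. For a walk `W = (w_1, ..., w_l)`, let `w_i` be its first
inner join (default `w_l`) and `w_j` its last inner split (default `w_1`).
When `j < i`, the subwalk from `w_j` to `w_i` is the *core* of `W` — always
a unitig — and a walk possessing a core is a *simple omnitig*. Equivalently:
right of the core every node but the last has out-degree one, and left of
the core every node but the first has in-degree one, so any genome walk that
traverses the core's first arc must traverse the whole simple omnitig.
Simple omnitigs therefore stay safe while running *through* the flanks of
repeats and bubbles, at the price of overlapping one another.

## The algorithm

A *maximal* simple omnitig is one that is not a subwalk of another simple
omnitig. The package computes them in three steps, in time `O(m + out)`
(`m` arcs, `out` = total node length of the output):

1. **Unitig compaction** (`maximal_unitigs()`): start a traversal at every
   node whose in- or out-degree differs from one; each outgoing arc is
   extended through degree-(1,1) nodes. The resulting walks partition the
   arc set. Components with no branching node at all (branch-free cycles,
   including single self-loops) are emitted once each as closed
   `circular_unitig` walks.
2. **Core test** (`is_core_of_maximal_simple_omnitig()`): a maximal unitig
   is the core of a maximal simple omnitig iff (a) it is its own core
   (automatic for unitigs, still asserted), (b) if its first node has
   exactly one outgoing arc then it has no incoming arcs, and (c) if its
   last node has exactly one incoming arc then it has no outgoing arcs.
   Constant time per unitig given the degree vectors.
3. **Univocal extension** (`univocal_extension()`): each surviving core is
   extended forward while the head has exactly one outgoing arc and backward
   while the tail has exactly one incoming arc, which yields exactly the
   maximal simple omnitigs.

Simply extending *every* maximal unitig would be wrong: a simple omnitig can
contain several unitigs, so extensions of non-core unitigs are non-maximal
(in the bubble fixture, the entry flank extends into both arms and is
absorbed by both arm omnitigs). The core test is what removes them.

### Termination and cyclic corner cases

The defining iteration of the univocal extension does not terminate when a
direction enters a cycle whose nodes all have out-degree one (forward) or
all in-degree one (backward). Those are exactly the graphs in which simple
omnitigs are unbounded — walks may circle such a cycle indefinitely without
ever acquiring an inner split after a join — so *no finite maximal simple
omnitig set exists there at all*. Our conventions:

* Each extension direction stops before revisiting a node that this
  direction has already visited. On every graph whose simple omnitigs are
  bounded this guard provably never fires (a revisit would exhibit a
  univocal cycle), so it changes nothing where the notion is well defined.
  A guard per *direction* matters: a maximal simple omnitig may traverse
  the same arc once left and once right of its core (e.g. core `(v, u)` on
  mutually reachable `u`, `v` extends to `(u, v, u, v)`), which a combined
  two-direction guard would wrongly truncate — this case is exercised by
  the random-graph oracle suite.
* A core lying on a branch-free cycle extends forward around the cycle
  exactly once, producing a closed walk; the backward pass, which would
  deterministically re-cover the same cycle, is skipped. Isolated
  branch-free cycle components never reach the extension at all: they are
  passed through as `circular_unitig` walks, rotated to start at the
  lexicographically smallest node — the usual assembler convention for
  plasmid-like components.
* Single-node walks are never contigs: a zero-arc walk spells only a
  (k-1)-mer, and cores are undefined below two nodes.
* With parallel arcs, two parallel unitigs have identical node sequences;
  both are kept by `maximal_unitigs()` (the arc-partition invariant needs
  them) but the simple-omnitig output is deduplicated by node sequence so
  it remains an antichain.

## The brute-force oracle

`maximal_simple_omnitigs_bruteforce()` is a deliberately independent
reference: depth-first enumeration of all simple omnitigs followed by a
subwalk-maximality filter. Two facts make it exact rather than heuristic:

* every subwalk — in particular every prefix — of a simple omnitig is a
  simple omnitig, so the DFS may prune a branch the moment the walk stops
  being one without losing any longer candidate;
* a finite maximal simple omnitig has at most `n + 2` core nodes plus at
  most `n` nodes per extension direction, so the enumeration cap of
  `3n + 4` nodes is unreachable when the notion is well defined. By prefix
  closure, some enumerated walk reaches the cap *iff* simple omnitigs are
  unbounded, so the `truncated` attribute is an exact test of
  applicability, not a tuning knob. The random-graph equivalence suite
  draws seeded graphs and skips truncated ones (about a third of uniform
  draws at `n <= 12`, `m <= 25`), replacing them deterministically with
  further seeds.

## Safety verification

Under the error-free, perfect-coverage model the graph is the de Bruijn
graph of the genome's k-spectrum. For a genome of linear chromosomes, let
`L` be the set of (k-1)-mers occurring first or last on some chromosome
(`end_kmer_set()`). A simple omnitig none of whose *inner* nodes lies in
`L` is guaranteed to spell a substring of some chromosome; for a single
circular chromosome every simple omnitig is safe. `verify_safety()` makes
this executable: contigs avoiding `L` internally must be substrings
(verdict `safe_substring`; anything else is a bug in the contig algorithm,
and the suites assert zero such violations), while contigs with an inner
node in `L` are reported as `exempt_touches_L` — the guarantee is silent
about them, and some are safe anyway, so their substring status is recorded
but never asserted. Following the statement of the guarantee literally,
only *inner* nodes are tested against `L`; a contig merely starting or
ending on a chromosome end is not exempted.

Substring queries against circular chromosomes use the rotation closure:
the sequence followed by `|s| - 1` wrap characters drawn from its periodic
extension, so a query may start at any rotation and span one traversal plus
wrap. The contig algorithm never emits walks covering a cycle more than
once, so this convention never blesses an over-assembled contig.

The verifier is shown to be non-vacuous by a negative control
(`missing_branch_control()`): a crafted two-chromosome genome whose node
`ACGT` has two incoming and two outgoing arcs. Removing the single k-mer
behind one outgoing arc — missing coverage in miniature — leaves a join
over which a simple omnitig extends, splicing a prefix of one chromosome
onto a suffix of the other; the verifier flags it unsafe while the unitig
baseline on the same damaged graph stays safe.

## Contiguity metrics for overlapping contigs

Because simple omnitigs overlap, per-contig length statistics double-count
and classical NGA-style metrics mislead. The package implements the
EAxmax family instead: align all contigs, record for every reference
position the length of the longest alignment covering it (0 if uncovered),
and report `EAxmax` = the largest `l` such that at least `x` percent of all
genome positions carry a best-alignment length of at least `l` (ties
resolved toward the larger `l`; the total is the haploid genome length).
`EA0max` is thus the longest alignment, and the curve is non-increasing in
`x`. Alignments are maximal exact matches of at least `k` bases (the
evaluation operates on error-free synthetic data; an indel-tolerant aligner
would add nothing but noise here), found by anchoring left-maximal seeds
and extending right, so each maximal match is reported exactly once.
Misassembly breakpoints — consecutive exact factors of one contig that are
not colinear on the reference — are deduplicated to at most one per
reference position, because many overlapping omnitigs would otherwise
re-count a single unitig error. Genome fraction and duplication ratio
follow the usual definitions; duplication above one is expected and
desired for simple omnitigs, since one flank may give context to several
structures. Evaluation can optionally run in homopolymer-compressed space
(`compress_homopolymers()` applied to both sides), the standard device for
avoiding spurious mismatch calls in long homopolymer runs.

On a single error-free circular chromosome the dominance property holds
pointwise: every maximal unitig is a subwalk of some maximal simple
omnitig, so the per-position best length can only grow, i.e.
`EAxmax(simple omnitigs) >= EAxmax(unitigs)` for every `x`, strictly at
some `x` whenever the graph branches. The test suite checks this on twenty
planted genomes.

## The synthetic generator

`generate_genome()` realises the error-free, perfect-coverage study model:
uniform random ACGT background with planted structures, a pure function of
(spec, seed). `plant_repeat()` inserts exact copies of one random repeat
(collapsing to a join-unitig-split in the graph for `k` below the repeat
length); `plant_bubble()` inserts two copies of a flanked arm differing at
a chosen number of positions. Planting both arm versions inside one
chromosome necessarily makes the shared flanks exact repeats, so a planted
bubble contributes two splits and two joins (arm divergence plus flank
boundaries) rather than the minimal one-of-each — the audit tests assert
these true counts. Defaults (arm 50 bp, one divergent position, flanks
~100-200 bp, repeats 100 bp in 200-2000 bp chromosomes, k in {5, 9, 15})
were chosen once as a desk-scale caricature of heterozygous variants and
interspersed repeats; they are deliberately small enough for exhaustive
verification.

What the generator does *not* emulate bounds what the passing suites show:
no sequencing errors, no coverage gaps (except the deliberate negative
control), no reverse-complement strand ambiguity, no diploid phasing, no
read-length effects. The guarantees verified here are exactly the
idealised-model guarantees; on real data, missing branches make simple
omnitigs — like unitigs — only approximately safe.

## Problem sizes and numerical choices

The shipped verification (test suite and `scripts/acceptance.R`) uses: 200
applicable random digraphs (`n` in 3-12, `m <= 25`) for oracle equivalence
plus the three structural fixtures; 100 linear multi-chromosome genomes
(2-4 chromosomes, 200-2000 bp, k cycling {5, 9, 15}) and 100 single
circular chromosomes for the safety suites (tens of thousands of contigs,
zero tolerance); 20 planted circular genomes for EAxmax dominance; and a
six-point bubble-chain family (5-160 bubbles) for the work-linearity
regression, where the work counter (unitig arc visits plus output node
length) fits `m + out` with R^2 > 0.999. These sizes keep the whole
verification around a minute on one CPU while leaving each property
non-trivially exercised. All randomness flows through explicit integer
seeds; per-case seeds are derived arithmetically so every run is
reproducible.

Other conventions worth knowing: k-mer windows containing a non-ACGT
character are skipped (with a logged count) rather than split and
reassembled — the simplest rule consistent with an error-free model; the
spectrum has set semantics (one arc per distinct k-mer) because the input
model is a spectrum, not a read multiset; sequences are used single-strand,
with no reverse complementation anywhere; contig output is sorted by
(kind, spelled sequence) so FASTA/GFA files diff reproducibly.

## Limitations

General (non-simple) omnitigs are out of scope except through the
brute-force oracle; the oracle itself is for graphs of roughly fifteen
nodes and below. The maximality semantics on graphs with univocal cycles is
a convention (finite maximal simple omnitigs do not exist there); the
oracle is authoritative for the implemented behaviour. The aligner is
exact-match only and the misassembly model correspondingly minimal: numeric
agreement with full evaluation pipelines on real, error-containing data is
not claimed.
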