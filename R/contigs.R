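#' Contig sets
#'
#' A `contig_set` bundles a list of walks (integer node-id vectors) over one
#' graph, with a kind tag per walk: `maximal_unitig`, `maximal_simple_omnitig`
#' or `circular_unitig`. Circular unitigs are closed walks written with their
#' first node repeated at the end, starting at the node with the
#' lexicographically smallest label (or smallest id on unlabelled graphs).
#'
#' @param g the [digraph] the walks live in.
#' @param walks list of integer node-id vectors.
#' @param kind character vector of kind tags, one per walk.
#' @return an object of class `contig_set`.
#' @export
contig_set <- function(g, walks, kind) {
  stopifnot(length(walks) == length(kind))
  structure(list(graph = g, walks = walks, kind = kind), class = "contig_set")
}

#' @export
length.contig_set <- function(x) length(x$walks)

#' @export
print.contig_set <- function(x, ...) {
  tab <- table(x$kind)
  cat(sprintf("contig set: %d walk(s) [%s]\n", length(x$walks),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Spell every contig of a set
#'
#' @param contigs a [contig_set] over a labelled de Bruijn graph.
#' @return named character vector; names are `sot_<i>` in set order.
#' @export
spell_contigs <- function(contigs) {
  out <- vapply(contigs$walks, function(w) spell(contigs$graph, w), "")
  names(out) <- paste0("sot_", seq_along(out))
  out
}

#' Subwalk test
#'
#' TRUE iff walk `a`'s node sequence occurs as a contiguous subsequence of
#' walk `b`'s.
#'
#' @param a,b integer node-id vectors (or label vectors with `g` supplied).
#' @param g optional graph for label resolution.
#' @return logical.
#' @export
is_subwalk <- function(a, b, g = NULL) {
  if (!is.null(g)) {
    a <- resolve_node(g, a)
    b <- resolve_node(g, b)
  }
  la <- length(a)
  lb <- length(b)
  if (la > lb) return(FALSE)
  for (s in 0:(lb - la)) {
    if (all(b[s + seq_len(la)] == a)) return(TRUE)
  }
  FALSE
}

# Canonical string signature of one walk (for set comparisons / sorting).
walk_signature <- function(g, w) {
  if (!is.null(g$labels)) paste(g$labels[w], collapse = ">")
  else paste(w, collapse = ">")
}

# Signatures "kind|n1>n2>..." of a whole contig set, sorted.
contig_signatures <- function(contigs) {
  sort(paste(contigs$kind, vapply(contigs$walks, function(w)
    walk_signature(contigs$graph, w), ""), sep = "|"))
}

# Sort a contig set by (kind, signature) for reproducible output.
sort_contig_set <- function(contigs) {
  key <- paste(contigs$kind,
               vapply(contigs$walks, function(w)
                 walk_signature(contigs$graph, w), ""), sep = "|")
  o <- order(key, method = "radix")
  contig_set(contigs$graph, contigs$walks[o], contigs$kind[o])
}

#' Write contigs to FASTA
#'
#' Record ids follow the pattern
#' `sot_<i> kind=<kind> len=<spelled length> walklen=<nodes>`.
#'
#' @param contigs a [contig_set] over a de Bruijn graph.
#' @param path output path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  seqs <- spell_contigs(contigs)
  ids <- sprintf("sot_%d kind=%s len=%d walklen=%d", seq_along(seqs),
                 contigs$kind, nchar(seqs), lengths(contigs$walks))
  x <- Biostrings::BStringSet(unname(seqs))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write contigs as GFA1
#'
#' One S-line per maximal unitig of the graph (sequence = spelled unitig),
#' L-lines with `(k-1)M` overlaps between unitigs adjacent in the graph, and
#' one P-line per maximal simple omnitig listing its constituent maximal
#' unitigs. Orientation is always `+` (single-strand model).
#'
#' @param contigs a [contig_set] of maximal simple omnitigs.
#' @param path output path.
#' @export
write_contigs_gfa <- function(contigs, path) {
  g <- contigs$graph
  if (is.null(g$k)) stop("GFA output requires a de Bruijn graph")
  mu <- maximal_unitigs(g)
  useq <- vapply(mu$walks, function(w) spell(g, w), "")
  uname <- paste0("utg", seq_along(mu$walks))
  ukey <- vapply(mu$walks, function(w) walk_signature(g, w), "")
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%s\t%s", uname, useq))
  # adjacency between unitigs: unitig u precedes unitig v when head(u) = tail(v)
  heads <- vapply(mu$walks, function(w) w[length(w)], 1L)
  tails <- vapply(mu$walks, function(w) w[1L], 1L)
  ov <- sprintf("%dM", g$k - 1L)
  for (i in seq_along(mu$walks)) {
    succ <- which(tails == heads[i])
    for (j in succ) {
      lines <- c(lines, sprintf("L\t%s\t+\t%s\t+\t%s", uname[i], uname[j], ov))
    }
  }
  sel <- which(contigs$kind == "maximal_simple_omnitig")
  pn <- 0L
  for (i in sel) {
    segs <- decompose_into_unitigs(g, contigs$walks[[i]])
    ids <- uname[match(vapply(segs, function(w) walk_signature(g, w), ""), ukey)]
    if (anyNA(ids)) next # guard-truncated walks may not decompose cleanly
    pn <- pn + 1L
    lines <- c(lines, sprintf("P\tsot_%d\t%s\t*", i,
                              paste0(ids, "+", collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

# Cut a walk at its interior branching nodes, yielding the chain of maximal
# unitigs it traverses.
decompose_into_unitigs <- function(g, w) {
  l <- length(w)
  if (l < 2L) return(list(w))
  interior <- which(g$indeg[w] != 1L | g$outdeg[w] != 1L)
  cuts <- sort(unique(c(1L, interior[interior > 1L & interior < l], l)))
  segs <- list()
  for (p in seq_len(length(cuts) - 1L)) {
    segs[[p]] <- w[cuts[p]:cuts[p + 1L]]
  }
  segs
}
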