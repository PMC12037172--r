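#' Arc-centric de Bruijn graph of a k-spectrum
#'
#' Nodes are the (k-1)-mers occurring as a prefix or suffix of some spectrum
#' member; each k-mer contributes exactly one arc from its length-(k-1) prefix
#' to its length-(k-1) suffix, so the arc count equals the spectrum size.
#' Node labels hold the (k-1)-mers; nodes and arcs are sorted
#' lexicographically, which makes construction deterministic.
#'
#' @param spectrum a [k_spectrum] (non-empty).
#' @return a labelled [digraph] with the word size stored in field `k`.
#' @examples
#' sp <- k_spectrum(genome("ACGTA"), k = 3)
#' g <- build_de_bruijn(sp)
#' @export
build_de_bruijn <- function(spectrum) {
  kmers <- spectrum$kmers
  if (!length(kmers)) stop("cannot build a de Bruijn graph from an empty spectrum")
  k <- spectrum$k
  pref <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  labels <- sort(unique(c(pref, suf)))
  g <- digraph(match(pref, labels), match(suf, labels),
               n_nodes = length(labels), labels = labels)
  g$k <- k
  g
}

#' Spell the string of a walk in a de Bruijn graph
#'
#' Writes the first node's (k-1)-mer, then the last character of each
#' subsequent node. The result has length `(k-1) + (l-1)` for a walk of `l`
#' nodes.
#'
#' @param g a labelled [digraph] whose labels have uniform width.
#' @param w a walk: vector of node ids or labels.
#' @return the spelled string.
#' @export
spell <- function(g, w) {
  if (is.null(g$labels)) stop("walk spelling requires a node-labelled graph")
  w <- resolve_walk(g, w, check = FALSE)
  labs <- g$labels[w]
  wd <- nchar(labs[1L])
  if (any(nchar(labs) != wd)) {
    stop("walk spelling requires node labels of uniform width")
  }
  if (length(labs) == 1L) return(labs)
  paste0(labs[1L], paste(substr(labs[-1L], wd, wd), collapse = ""))
}
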