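#' Directed multigraph with stable integer node ids
#'
#' A minimal arc-list digraph. Nodes are the integers `1..n_nodes`; arcs are
#' ordered `(tail, head)` pairs and may include parallel arcs and self-loops.
#' Nodes may optionally carry unique string labels (for de Bruijn graphs these
#' are the (k-1)-mers). In- and out-adjacency lists and degree vectors are
#' precomputed, so all degree queries are O(1).
#'
#' @param tail,head integer vectors of equal length; arc i runs tail[i] -> head[i].
#' @param n_nodes number of nodes (defaults to the largest endpoint id).
#' @param labels optional character vector of unique node labels, length `n_nodes`.
#' @return an object of class `digraph` with fields `n`, `m`, `tail`, `head`,
#'   `labels`, `out_arcs`, `in_arcs`, `outdeg`, `indeg`.
#' @examples
#' g <- digraph(c(1, 2), c(2, 3), labels = c("AC", "CG", "GT"))
#' degree_profile(g, "CG")
#' @export
digraph <- function(tail, head, n_nodes = NULL, labels = NULL) {
  tail <- as.integer(tail)
  head <- as.integer(head)
  if (length(tail) != length(head)) {
    stop("tail and head must have the same length")
  }
  if (length(tail) && min(tail, head) < 1L) {
    stop("arc endpoints must be positive node ids")
  }
  if (is.null(n_nodes)) {
    n_nodes <- if (length(tail)) max(tail, head) else if (!is.null(labels)) length(labels) else 0L
  }
  n <- as.integer(n_nodes)
  if (length(tail) && max(tail, head) > n) {
    stop("arc endpoint exceeds the number of registered nodes")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels must have length n_nodes")
    if (anyDuplicated(labels)) stop("node labels must be unique")
  }
  m <- length(tail)
  arc_ids <- seq_len(m)
  structure(
    list(
      n = n, m = m, tail = tail, head = head, labels = labels,
      out_arcs = split(arc_ids, factor(tail, levels = seq_len(n))),
      in_arcs = split(arc_ids, factor(head, levels = seq_len(n))),
      outdeg = tabulate(tail, n), indeg = tabulate(head, n),
      k = NULL
    ),
    class = "digraph"
  )
}

#' @export
print.digraph <- function(x, ...) {
  kind <- if (!is.null(x$k)) sprintf("de Bruijn (k = %d)", x$k) else "abstract"
  cat(sprintf("digraph (%s): %d nodes, %d arcs\n", kind, x$n, x$m))
  invisible(x)
}

# Resolve a node given as integer id or label to its integer id.
resolve_node <- function(g, v) {
  if (is.character(v)) {
    if (is.null(g$labels)) stop("graph has no node labels; address nodes by id")
    id <- match(v, g$labels)
    if (anyNA(id)) stop(sprintf("unknown node label '%s'", v[which(is.na(id))[1]]))
    return(id)
  }
  id <- as.integer(v)
  if (anyNA(id) || any(id < 1L) || any(id > g$n)) stop("unknown node id")
  id
}

# Resolve a walk (ids or labels) and check the adjacency invariant.
resolve_walk <- function(g, w, check = TRUE) {
  w <- resolve_node(g, w)
  if (check && length(w) >= 2L) {
    for (p in seq_len(length(w) - 1L)) {
      if (!any(g$head[g$out_arcs[[w[p]]]] == w[p + 1L])) {
        stop(sprintf("not a walk: no arc %s -> %s", w[p], w[p + 1L]))
      }
    }
  }
  w
}

#' Node degrees and branching predicates
#'
#' `degree_profile()` returns the in- and out-degree of a node; `is_split()`
#' tests for at least two outgoing arcs and `is_join()` for at least two
#' incoming arcs. A self-loop counts once towards each side.
#'
#' @param g a [digraph].
#' @param v a node id or label.
#' @return `degree_profile()`: a named integer vector `c(in_degree, out_degree)`;
#'   the predicates return a single logical.
#' @export
degree_profile <- function(g, v) {
  v <- resolve_node(g, v)
  c(in_degree = g$indeg[v], out_degree = g$outdeg[v])
}

#' @rdname degree_profile
#' @export
in_degree <- function(g, v) g$indeg[resolve_node(g, v)]

#' @rdname degree_profile
#' @export
out_degree <- function(g, v) g$outdeg[resolve_node(g, v)]

#' @rdname degree_profile
#' @export
is_split <- function(g, v) out_degree(g, v) >= 2L

#' @rdname degree_profile
#' @export
is_join <- function(g, v) in_degree(g, v) >= 2L

#' Read an abstract digraph from an edge-list file
#'
#' One `tail<TAB>head` pair per line (any whitespace accepted); `#` starts a
#' comment. Node names become labels; ids are assigned in order of first
#' appearance.
#'
#' @param path path to the edge-list file.
#' @return a labelled [digraph].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(digraph(integer(), integer(), n_nodes = 0L))
  parts <- strsplit(lines, "[ \t]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop(sprintf("malformed edge-list line: '%s'", lines[which(bad)[1]]))
  tails <- vapply(parts, `[[`, "", 1L)
  heads <- vapply(parts, `[[`, "", 2L)
  labels <- unique(c(rbind(tails, heads)))
  digraph(match(tails, labels), match(heads, labels), n_nodes = length(labels),
          labels = labels)
}

# Build a digraph directly from label pairs (test/fixture convenience).
digraph_from_labels <- function(tails, heads, extra_nodes = character()) {
  labels <- unique(c(c(rbind(tails, heads)), extra_nodes))
  digraph(match(tails, labels), match(heads, labels), n_nodes = length(labels),
          labels = labels)
}
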