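#' Exhaustive walk enumeration (test oracle)
#'
#' Depth-first enumeration of every walk with between 2 and `max_len` nodes.
#' Walks are node sequences: parallel arcs do not multiply the output. Aborts
#' with an error of class `simpleomni_budget` if more than `budget` walks are
#' generated, guarding against combinatorial blow-up.
#'
#' @param g a [digraph].
#' @param max_len maximum node count per walk (at least 2).
#' @param budget maximum number of walks before aborting.
#' @return list of integer node-id vectors.
#' @export
enumerate_walks <- function(g, max_len, budget = 1e5) {
  stopifnot(max_len >= 2L)
  acc <- new.env(parent = emptyenv())
  acc$walks <- vector("list", 256L)
  acc$count <- 0L
  push <- function(w) {
    acc$count <- acc$count + 1L
    if (acc$count > budget) {
      stop(structure(class = c("simpleomni_budget", "error", "condition"),
                     list(message = "walk enumeration exceeded budget",
                          call = sys.call(-1))))
    }
    if (acc$count > length(acc$walks)) {
      acc$walks <- c(acc$walks, vector("list", length(acc$walks)))
    }
    acc$walks[[acc$count]] <- w
  }
  extend <- function(w) {
    nexts <- unique(g$head[g$out_arcs[[w[length(w)]]]])
    for (nh in sort(nexts)) {
      w2 <- c(w, nh)
      push(w2)
      if (length(w2) < max_len) extend(w2)
    }
  }
  starts <- unique(data.frame(t = g$tail, h = g$head))
  for (r in seq_len(nrow(starts))) {
    w <- c(starts$t[r], starts$h[r])
    push(w)
    if (max_len > 2L) extend(w)
  }
  walks <- acc$walks[seq_len(acc$count)]
  walks[!duplicated(vapply(walks, paste, "", collapse = ","))]
}

# Detect branch-free cycle components: cycles whose every node has in- and
# out-degree one. Such components are closed (no arcs touch the rest of the
# graph). Returns a list of canonical closed walks plus the involved node set.
isolated_cycles <- function(g) {
  state <- integer(g$n) # 0 unknown, 1 on-cycle, 2 not-on-cycle
  cycles <- list()
  thru <- g$indeg == 1L & g$outdeg == 1L
  for (v in seq_len(g$n)) {
    if (state[v] != 0L || !thru[v]) next
    path <- v
    cur <- v
    ok <- TRUE
    repeat {
      cur <- g$head[g$out_arcs[[cur]][1L]]
      if (cur == v) break
      if (!thru[cur] || length(path) > g$n) { ok <- FALSE; break }
      path <- c(path, cur)
    }
    if (ok) {
      state[path] <- 1L
      s <- if (!is.null(g$labels)) order(g$labels[path])[1L] else which.min(path)
      rot <- c(path[s:length(path)], path[seq_len(s - 1L)])
      cycles[[length(cycles) + 1L]] <- c(rot, rot[1L])
    } else {
      state[path] <- 2L
    }
  }
  nodes <- if (length(cycles)) unique(unlist(lapply(cycles, function(w) w[-1L])))
           else integer(0)
  list(walks = cycles, nodes = nodes)
}

#' Brute-force maximal simple omnitigs (test oracle)
#'
#' Reference implementation used only for testing: enumerates all simple
#' omnitigs up to `max_len` nodes by depth-first search (pruning branches as
#' soon as the walk stops being a simple omnitig, which is sound because
#' every prefix of a simple omnitig is a simple omnitig), then removes every
#' walk that is a proper contiguous subwalk of another retained walk.
#' Branch-free cycle components are reported once each as canonical
#' `circular_unitig` walks, matching the convention of
#' [maximal_simple_omnitigs()].
#'
#' In graphs containing a non-isolated cycle whose nodes all have out-degree
#' one (or all in-degree one), simple omnitigs are unbounded and no finite
#' maximal set exists; there the enumeration is truncated by `max_len` and
#' the result carries attribute `truncated = TRUE`. Callers must treat
#' truncated results as "oracle not applicable".
#'
#' @param g a [digraph].
#' @param max_len walk-length cap in nodes; defaults to `3n + 4`, beyond the
#'   length any finite maximal simple omnitig can reach (its core holds at
#'   most n + 2 nodes and each univocal extension at most n more). Because
#'   every prefix of a simple omnitig is a simple omnitig, some enumerated
#'   walk reaches the cap if and only if simple omnitigs are unbounded, so
#'   the `truncated` flag separates the two cases exactly.
#' @param budget abort threshold on the number of enumerated simple omnitigs.
#' @return a [contig_set] with attribute `truncated`.
#' @export
maximal_simple_omnitigs_bruteforce <- function(g, max_len = NULL, budget = 5e4) {
  if (is.null(max_len)) max_len <- 3L * g$n + 4L
  cyc <- isolated_cycles(g)
  on_cycle <- logical(g$n)
  on_cycle[cyc$nodes] <- TRUE

  acc <- new.env(parent = emptyenv())
  acc$walks <- vector("list", 256L)
  acc$count <- 0L
  push <- function(w) {
    acc$count <- acc$count + 1L
    if (acc$count > budget) {
      stop(structure(class = c("simpleomni_budget", "error", "condition"),
                     list(message = "simple omnitig enumeration exceeded budget",
                          call = sys.call(-1))))
    }
    if (acc$count > length(acc$walks)) {
      acc$walks <- c(acc$walks, vector("list", length(acc$walks)))
    }
    acc$walks[[acc$count]] <- w
  }
  extend <- function(w) {
    for (nh in sort(unique(g$head[g$out_arcs[[w[length(w)]]]]))) {
      w2 <- c(w, nh)
      if (!is_simple_omnitig(g, w2)) next # prefixes of SOs are SOs: safe prune
      push(w2)
      if (length(w2) < max_len) extend(w2)
    }
  }
  pairs <- unique(data.frame(t = g$tail, h = g$head))
  pairs <- pairs[!on_cycle[pairs$t], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    w <- c(pairs$t[r], pairs$h[r]) # every single arc is a simple omnitig
    push(w)
    extend(w)
  }
  walks <- acc$walks[seq_len(acc$count)]
  walks <- walks[!duplicated(vapply(walks, paste, "", collapse = ","))]
  # maximality: drop proper subwalks of retained walks
  if (length(walks)) {
    lens <- lengths(walks)
    o <- order(lens, decreasing = TRUE)
    walks <- walks[o]
    lens <- lens[o]
    keep <- rep(TRUE, length(walks))
    for (i in seq_along(walks)) {
      for (j in seq_along(walks)) {
        if (i == j || !keep[j] || lens[j] < lens[i]) next
        if (lens[j] == lens[i] && j > i) next
        if (is_subwalk(walks[[i]], walks[[j]])) { keep[i] <- FALSE; break }
      }
    }
    walks <- walks[keep]
    lens <- lens[keep]
    truncated <- any(lens >= max_len)
  } else {
    truncated <- FALSE
  }
  out <- contig_set(g, c(walks, cyc$walks),
                    c(rep("maximal_simple_omnitig", length(walks)),
                      rep("circular_unitig", length(cyc$walks))))
  out <- sort_contig_set(out)
  attr(out, "truncated") <- truncated
  out
}
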