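# Build a labelled digraph from parallel vectors of tail/head labels.
label_graph <- function(tails, heads, extra_nodes = character()) {
  labels <- unique(c(c(rbind(tails, heads)), extra_nodes))
  digraph(match(tails, labels), match(heads, labels),
          n_nodes = length(labels), labels = labels)
}

# Node labels of a walk.
labels_of <- function(g, w) g$labels[w]

# Sorted canonical "kind|l1>l2>..." signatures of a contig set.
sigs <- function(cs) {
  g <- cs$graph
  lab <- function(w) {
    if (!is.null(g$labels)) paste(g$labels[w], collapse = ">")
    else paste(w, collapse = ">")
  }
  sort(paste(cs$kind, vapply(cs$walks, lab, ""), sep = "|"))
}

# Expected-set signatures from a list of label (or id) vectors.
walk_sigs <- function(walks, kind = "maximal_simple_omnitig") {
  sort(paste(kind, vapply(walks, paste, "", collapse = ">"), sep = "|"))
}

# x -> v -> y with v both a split and a join (second in- and out-arc added).
split_join_graph <- function() {
  label_graph(c("x", "x2", "v", "v"), c("v", "v", "y", "y2"))
}
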