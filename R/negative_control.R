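#' Missing-branch negative control
#'
#' A crafted two-chromosome linear genome in which the (k-1)-mer `ACGT`
#' (k = 5) has two incoming and two outgoing arcs. Dropping the single k-mer
#' that forms its second outgoing arc emulates missing coverage: the node
#' keeps both incoming arcs but loses one branch, so a simple omnitig can
#' extend across it and spell a chimera of the two chromosomes. Verifying
#' the resulting contigs against the unperturbed genome must flag at least
#' one contig as unsafe, which demonstrates that the safety verifier detects
#' real unsafety (unitigs stop at the node and remain safe).
#'
#' @return list with fields `genome`, `k`, `spectrum` (full),
#'   `spectrum_perturbed` (one k-mer dropped), `dropped_kmer` and
#'   `branch_node` (the (k-1)-mer whose out-arc is removed).
#' @export
missing_branch_control <- function() {
  k <- 5L
  # chr1 = P1 . ACGT . S1 ; chr2 = P2 . ACGT . S2, all other 4-mers unique
  gen <- genome(c("TTCAGGAACGTTTGCAAC", "GGATTCCACGTGAGGTTG"))
  sp <- k_spectrum(gen, k)
  dropped <- "ACGTG" # the arc ACGT -> CGTG used only by chr2
  stopifnot(dropped %in% sp$kmers)
  sp2 <- structure(list(k = k, kmers = setdiff(sp$kmers, dropped)),
                   class = "k_spectrum")
  list(genome = gen, k = k, spectrum = sp, spectrum_perturbed = sp2,
       dropped_kmer = dropped, branch_node = "ACGT")
}
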