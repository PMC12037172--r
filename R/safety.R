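#' Chromosome-end (k-1)-mer set
#'
#' The set `L` of (k-1)-mers that occur as the first or last (k-1)-mer of
#' some linear chromosome. Circular chromosomes have no ends and contribute
#' nothing; an all-circular genome yields the empty set. Simple omnitigs with
#' no inner node in `L` are guaranteed substrings of the genome.
#'
#' @param genome a [genome].
#' @param k word size (linear chromosomes must have length >= k-1).
#' @return sorted character vector of (k-1)-mers.
#' @export
end_kmer_set <- function(genome, k) {
  k <- as.integer(k)
  members <- character(0)
  lin <- which(!genome$circular)
  for (i in lin) {
    s <- genome$sequence[i]
    len <- nchar(s)
    if (len < k - 1L) {
      stop(sprintf("chromosome '%s' is shorter than k-1 = %d", genome$id[i], k - 1L))
    }
    members <- c(members, substr(s, 1L, k - 1L), substr(s, len - k + 2L, len))
  }
  sort(unique(members))
}

# Rotation closure of a circular sequence for substring queries of length
# `qlen`: the sequence followed by qlen-1 wrap characters (repeating the
# sequence as needed).
rotation_closure <- function(s, qlen) {
  len <- nchar(s)
  wrap <- qlen - 1L
  if (wrap <= 0L) return(s)
  reps <- strrep(s, ceiling(wrap / len))
  paste0(s, substr(reps, 1L, wrap))
}

#' Does a string occur in a genome?
#'
#' TRUE iff `s` occurs in some linear chromosome, or in some circular
#' chromosome's rotation closure (the sequence plus `nchar(s) - 1` wrap
#' characters), i.e. within one full traversal plus wrap.
#'
#' @param s query string.
#' @param genome a [genome].
#' @return logical.
#' @export
is_substring_of_genome <- function(s, genome) {
  !is.na(match_chromosome(s, genome))
}

# Id of the first chromosome containing s (rotation closure for circular),
# or NA if none does.
match_chromosome <- function(s, genome) {
  for (i in seq_len(nrow(genome))) {
    target <- if (genome$circular[i]) {
      rotation_closure(genome$sequence[i], nchar(s))
    } else {
      genome$sequence[i]
    }
    if (grepl(s, target, fixed = TRUE)) return(genome$id[i])
  }
  NA_character_
}

#' Verify contig safety against a source genome
#'
#' Executable form of the safety guarantee for simple omnitigs on error-free
#' perfect-coverage data: a contig none of whose inner (k-1)-mers lies in the
#' chromosome-end set `L` must spell a substring of some chromosome. Each
#' contig receives one verdict:
#' \describe{
#'   \item{safe_substring}{inner nodes avoid `L` and the contig is a
#'     substring of some chromosome (any other outcome for such a contig
#'     indicates a bug in the contig algorithm, not a data property);}
#'   \item{unsafe}{inner nodes avoid `L` but the contig is not a substring;}
#'   \item{exempt_touches_L}{some inner node is in `L`: the guarantee does
#'     not apply (such contigs can still be safe; the substring check result
#'     is recorded but carries no assertion).}
#' }
#' The inner (k-1)-mers are recovered directly from the spelled string, so
#' contigs may be given either as a [contig_set] or as plain sequences (e.g.
#' read back from FASTA).
#'
#' @param contigs a [contig_set] or character vector of contig sequences.
#' @param genome the source [genome].
#' @param k the word size the contigs were built with.
#' @return a data frame (class `safety_report`) with columns `contig`,
#'   `verdict`, `substring`, `chromosome`; summary counts in attribute
#'   `summary`.
#' @export
verify_safety <- function(contigs, genome, k) {
  k <- as.integer(k)
  if (inherits(contigs, "contig_set")) {
    if (!is.null(contigs$graph$k) && contigs$graph$k != k) {
      stop(sprintf("contigs were built with k = %d, not k = %d",
                   contigs$graph$k, k))
    }
    seqs <- spell_contigs(contigs)
  } else {
    seqs <- as.character(contigs)
    if (is.null(names(seqs)) && length(seqs)) {
      names(seqs) <- paste0("sot_", seq_along(seqs))
    }
  }
  if (length(seqs) && any(nchar(seqs) < k - 1L)) {
    stop("contig shorter than k-1: k mismatch between contigs and genome?")
  }
  L <- end_kmer_set(genome, k)
  verdict <- character(length(seqs))
  substr_ok <- logical(length(seqs))
  chrom <- character(length(seqs))
  for (ci in seq_along(seqs)) {
    s <- seqs[ci]
    nn <- nchar(s) - k + 2L # number of walk nodes
    inner <- if (nn >= 3L) substring(s, 2:(nn - 1L), (2:(nn - 1L)) + k - 2L)
             else character(0)
    hit <- match_chromosome(s, genome)
    substr_ok[ci] <- !is.na(hit)
    chrom[ci] <- if (is.na(hit)) "-" else hit
    verdict[ci] <- if (length(inner) && any(inner %in% L)) {
      "exempt_touches_L"
    } else if (substr_ok[ci]) "safe_substring" else "unsafe"
  }
  out <- data.frame(contig = if (length(seqs)) names(seqs) else character(0),
                    verdict = verdict, substring = substr_ok,
                    chromosome = chrom, stringsAsFactors = FALSE)
  class(out) <- c("safety_report", "data.frame")
  attr(out, "summary") <- c(
    safe_substring = sum(verdict == "safe_substring"),
    unsafe = sum(verdict == "unsafe"),
    exempt_touches_L = sum(verdict == "exempt_touches_L")
  )
  out
}

#' @export
print.safety_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("safety report: %d contig(s) | safe: %d, unsafe: %d, exempt: %d\n",
              nrow(x), s[["safe_substring"]], s[["unsafe"]],
              s[["exempt_touches_L"]]))
  invisible(x)
}
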