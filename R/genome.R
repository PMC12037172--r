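#' Genome container
#'
#' A genome is an ordered collection of chromosomes, each a sequence with a
#' circular/linear flag. Stored as a data frame with columns `id`, `sequence`
#' and `circular`. Sequences are case-folded to upper case.
#'
#' @param sequence character vector of chromosome sequences.
#' @param id chromosome ids (defaults to `chr1, chr2, ...`).
#' @param circular logical, recycled across chromosomes.
#' @return an object of class `genome` (also a `data.frame`).
#' @examples
#' g <- genome(c("ACGTACGT", "TTTTAAAA"), circular = c(TRUE, FALSE))
#' @export
genome <- function(sequence, id = NULL, circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (is.null(id)) id <- paste0("chr", seq_along(sequence))
  circular <- rep_len(as.logical(circular), length(sequence))
  out <- data.frame(id = as.character(id), sequence = sequence,
                    circular = circular, stringsAsFactors = FALSE)
  class(out) <- c("genome", "data.frame")
  out
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d chromosome(s)\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s  %d bp  %s\n", x$id[i], nchar(x$sequence[i]),
                if (x$circular[i]) "circular" else "linear"))
  }
  invisible(x)
}

#' Read a genome from a multi-record FASTA file
#'
#' Record ids are preserved (first whitespace-delimited token). A record whose
#' id carries the suffix `:circular` is flagged circular (and the suffix is
#' stripped); otherwise the global `circular` flag applies.
#'
#' @param path FASTA file path.
#' @param circular default circularity for records without an id suffix.
#' @return a [genome].
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  recs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(recs), "[ \t]"), `[[`, "", 1L)
  circ <- rep_len(circular, length(recs))
  tagged <- grepl(":circular$", ids)
  circ[tagged] <- TRUE
  ids[tagged] <- sub(":circular$", "", ids[tagged])
  genome(as.character(recs), id = ids, circular = circ)
}

#' Write a genome to FASTA
#'
#' Circular chromosomes are written with the `:circular` id suffix so that a
#' read/write round trip preserves the flags.
#'
#' @param g a [genome].
#' @param path output path.
#' @export
write_genome_fasta <- function(g, path) {
  ids <- ifelse(g$circular, paste0(g$id, ":circular"), g$id)
  x <- Biostrings::BStringSet(g$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Homopolymer compression
#'
#' Collapses every maximal run of identical characters to a single character,
#' e.g. `"AAACCGTT"` becomes `"ACGT"`. Idempotent; the empty string maps to
#' itself. Vectorised over its input.
#'
#' @param sequence character vector.
#' @return character vector of compressed sequences.
#' @export
compress_homopolymers <- function(sequence) {
  gsub("(.)\\1+", "\\1", sequence)
}

# Apply homopolymer compression to every chromosome of a genome.
compress_genome <- function(g) {
  g$sequence <- compress_homopolymers(g$sequence)
  g
}

#' k-spectrum of a genome
#'
#' The set of all length-`k` substrings of the chromosomes. Circular
#' chromosomes are scanned over their rotation closure (the sequence followed
#' by its first k-1 characters), so wrap-around k-mers are included. Any
#' window containing a character outside `alphabet` is skipped; the number of
#' skipped windows is recorded in the `skipped` attribute.
#'
#' @param genome a [genome].
#' @param k integer word size, at least 2.
#' @param alphabet allowed characters (default A, C, G, T).
#' @return an object of class `k_spectrum`: list with `k` and sorted unique
#'   `kmers`.
#' @export
k_spectrum <- function(genome, k, alphabet = c("A", "C", "G", "T")) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  bad_class <- paste0("[^", paste(alphabet, collapse = ""), "]")
  kmers <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(genome))) {
    s <- genome$sequence[i]
    len <- nchar(s)
    if (len < k) {
      stop(sprintf("chromosome '%s' is shorter than k = %d", genome$id[i], k))
    }
    if (genome$circular[i]) {
      s <- paste0(s, substr(s, 1L, k - 1L))
      nwin <- len
    } else {
      nwin <- len - k + 1L
    }
    w <- substring(s, seq_len(nwin), seq_len(nwin) + k - 1L)
    ok <- !grepl(bad_class, w)
    skipped <- skipped + sum(!ok)
    kmers <- c(kmers, w[ok])
  }
  structure(list(k = k, kmers = sort(unique(kmers))),
            class = "k_spectrum", skipped = skipped)
}

#' @export
print.k_spectrum <- function(x, ...) {
  cat(sprintf("k-spectrum: k = %d, %d distinct k-mers\n", x$k, length(x$kmers)))
  invisible(x)
}

#' Randomly remove k-mers from a spectrum
#'
#' Removes `floor(fraction * |spectrum|)` k-mers chosen uniformly at random.
#' Used for missing-coverage negative controls: deleting k-mers can make a
#' branching node lose a branch, which lets contigs extend across it unsafely.
#'
#' @param spectrum a [k_spectrum].
#' @param fraction fraction of k-mers to drop, in `[0, 1]`.
#' @param seed integer seed; the drop is a pure function of (spectrum, seed).
#' @return a [k_spectrum] with the surviving k-mers.
#' @export
drop_kmers <- function(spectrum, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_drop <- floor(fraction * length(spectrum$kmers))
  if (n_drop == 0L) return(spectrum)
  keep <- with_seed(seed, {
    drop <- sample.int(length(spectrum$kmers), n_drop)
    setdiff(seq_along(spectrum$kmers), drop)
  })
  structure(list(k = spectrum$k, kmers = spectrum$kmers[sort(keep)]),
            class = "k_spectrum")
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards (keeps generators pure functions of their seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
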