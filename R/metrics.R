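#' Exact-match alignments of contigs against a reference
#'
#' The evaluation model is error-free, so alignments are maximal exact
#' matches: for each contig, every maximal exact occurrence of length at
#' least `min_len` in each chromosome is reported (rotation closure for
#' circular chromosomes, with wrap `nchar(contig) - 1`). A contig that is a
#' full substring yields alignments of its own full length; a chimeric
#' contig yields its maximal exact factors. Matches are found by anchoring
#' left-maximal `min_len`-mers and extending rightward, which reports each
#' maximal match exactly once.
#'
#' Reference coordinates are 0-based half-open; for circular chromosomes they
#' live in rotation-closure space (positions are reduced modulo the
#' chromosome length during the coverage sweep).
#'
#' @param contigs a [contig_set] or (named) character vector of sequences.
#' @param genome a [genome].
#' @param min_len minimum reported match length (typically `k`).
#' @return data frame with columns `contig_id`, `chromosome_id`, `ref_start`,
#'   `ref_end`, `contig_start`, `contig_end`, `aligned_length`.
#' @export
exact_match_alignments <- function(contigs, genome, min_len) {
  seqs <- if (inherits(contigs, "contig_set")) spell_contigs(contigs)
          else as.character(contigs)
  if (is.null(names(seqs)) && length(seqs)) {
    names(seqs) <- paste0("sot_", seq_along(seqs))
  }
  rows <- list()
  for (gi in seq_len(nrow(genome))) {
    ref_plain <- genome$sequence[gi]
    for (ci in seq_along(seqs)) {
      q <- seqs[[ci]]
      ref <- if (genome$circular[gi]) rotation_closure(ref_plain, nchar(q))
             else ref_plain
      mm <- find_maximal_matches(q, ref, min_len)
      if (nrow(mm)) {
        mm$contig_id <- names(seqs)[ci]
        mm$chromosome_id <- genome$id[gi]
        rows[[length(rows) + 1L]] <- mm
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(0), chromosome_id = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      contig_start = integer(0), contig_end = integer(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[, c("contig_id", "chromosome_id", "ref_start", "ref_end",
          "contig_start", "contig_end", "aligned_length")]
}

# All maximal exact matches of length >= min_len between q and r
# (0-based half-open coordinates).
find_maximal_matches <- function(q, r, min_len) {
  min_len <- as.integer(min_len)
  empty <- data.frame(ref_start = integer(0), ref_end = integer(0),
                      contig_start = integer(0), contig_end = integer(0),
                      aligned_length = integer(0), stringsAsFactors = FALSE)
  nq <- nchar(q)
  nr <- nchar(r)
  if (nq < min_len || nr < min_len) return(empty)
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  ridx <- new.env(hash = TRUE, parent = emptyenv())
  rk <- substring(r, seq_len(nr - min_len + 1L), seq_len(nr - min_len + 1L) + min_len - 1L)
  for (p in seq_along(rk)) {
    ridx[[rk[p]]] <- c(ridx[[rk[p]]], p)
  }
  qk <- substring(q, seq_len(nq - min_len + 1L), seq_len(nq - min_len + 1L) + min_len - 1L)
  rs_list <- list(); re_list <- list(); qs_list <- list(); qe_list <- list()
  for (qs in seq_along(qk)) {
    hits <- ridx[[qk[qs]]]
    if (is.null(hits)) next
    for (rs in hits) {
      if (qs > 1L && rs > 1L && qc[qs - 1L] == rc[rs - 1L]) next # not left-maximal
      qe <- qs + min_len - 1L
      re <- rs + min_len - 1L
      while (qe < nq && re < nr && qc[qe + 1L] == rc[re + 1L]) {
        qe <- qe + 1L
        re <- re + 1L
      }
      i <- length(rs_list) + 1L
      rs_list[[i]] <- rs; re_list[[i]] <- re
      qs_list[[i]] <- qs; qe_list[[i]] <- qe
    }
  }
  if (!length(rs_list)) return(empty)
  rs <- unlist(rs_list); re <- unlist(re_list)
  qs <- unlist(qs_list); qe <- unlist(qe_list)
  data.frame(ref_start = rs - 1L, ref_end = re,
             contig_start = qs - 1L, contig_end = qe,
             aligned_length = re - rs + 1L, stringsAsFactors = FALSE)
}

#' Per-position best-alignment profile and EAxmax percentiles
#'
#' For every reference position, records the length of the longest alignment
#' covering it (0 where uncovered); positions of circular chromosomes are
#' obtained by reducing rotation-closure coordinates modulo the chromosome
#' length. EAxmax is the largest length `l` such that at least x percent of
#' all genome positions are covered by an alignment of length at least `l`
#' (ties resolved toward the larger `l`); uncovered positions count with
#' value 0, and the total is the summed chromosome length of the haploid
#' reference.
#'
#' @param alignments output of [exact_match_alignments()].
#' @param genome the reference [genome].
#' @return an object of class `ea_profile`: list with `best` (named list of
#'   per-chromosome integer vectors) and `total` (genome length).
#' @export
ea_profile <- function(alignments, genome) {
  best <- lapply(seq_len(nrow(genome)), function(i)
    integer(nchar(genome$sequence[i])))
  names(best) <- genome$id
  for (r in seq_len(nrow(alignments))) {
    ch <- alignments$chromosome_id[r]
    len_chr <- length(best[[ch]])
    pos <- alignments$ref_start[r]:(alignments$ref_end[r] - 1L)
    if (genome$circular[match(ch, genome$id)]) pos <- pos %% len_chr
    pos <- unique(pos) + 1L
    best[[ch]][pos] <- pmax(best[[ch]][pos], alignments$aligned_length[r])
  }
  structure(list(best = best, total = sum(lengths(best))),
            class = "ea_profile")
}

#' EAxmax percentile of a coverage profile
#'
#' @param profile an [ea_profile].
#' @param x percentile(s) in `[0, 100]`; vectorised.
#' @return numeric vector of EAxmax values (non-increasing in `x`).
#' @export
eaxmax <- function(profile, x) {
  b <- unlist(profile$best, use.names = FALSE)
  total <- profile$total
  lv <- sort(unique(c(0L, b)), decreasing = TRUE)
  # count of positions with best >= l, for each candidate l
  cnt <- cumsum(tabulate(match(b, lv), length(lv)))
  vapply(x, function(xi) {
    need <- xi / 100 * total
    ok <- which(cnt >= need)
    if (length(ok)) lv[ok[1L]] else 0L
  }, numeric(1))
}

#' @rdname eaxmax
#' @param xs grid of percentiles (default 0..100 in 1 percent steps).
#' @return `ea_curve()`: data frame with columns `x` and `eaxmax`.
#' @export
ea_curve <- function(profile, xs = 0:100) {
  data.frame(x = xs, eaxmax = eaxmax(profile, xs))
}

#' Genome fraction and duplication ratio
#'
#' `genome_fraction` is the percentage of reference positions covered by at
#' least one alignment; `duplication_ratio` is total aligned bases divided by
#' covered positions (> 1 when contigs overlap).
#'
#' @inheritParams ea_profile
#' @return named numeric vector `c(genome_fraction, duplication_ratio)`.
#' @export
coverage_stats <- function(alignments, genome) {
  prof <- ea_profile(alignments, genome)
  b <- unlist(prof$best, use.names = FALSE)
  covered <- sum(b > 0L)
  total_aligned <- sum(alignments$aligned_length)
  c(genome_fraction = if (prof$total > 0L) 100 * covered / prof$total else 0,
    duplication_ratio = if (covered > 0L) total_aligned / covered else 0)
}

#' Misassembly breakpoints of chimeric contigs
#'
#' For each contig, orders its exact-match factors along the contig and
#' reports a breakpoint wherever two consecutive factors are not colinear on
#' the reference (different chromosome, or reference gap unequal to the
#' contig gap). The breakpoint is placed at the reference end position of the
#' earlier factor. Contigs with a full-length alignment have no breakpoints.
#'
#' @param alignments output of [exact_match_alignments()].
#' @param contig_lengths named integer vector of contig lengths (to recognise
#'   full-length alignments); optional.
#' @return data frame with columns `chromosome_id`, `position`.
#' @export
alignment_breakpoints <- function(alignments, contig_lengths = NULL) {
  out <- data.frame(chromosome_id = character(0), position = integer(0),
                    stringsAsFactors = FALSE)
  for (cid in unique(alignments$contig_id)) {
    rec <- alignments[alignments$contig_id == cid, , drop = FALSE]
    if (!is.null(contig_lengths) && cid %in% names(contig_lengths) &&
        any(rec$aligned_length == contig_lengths[[cid]])) {
      next
    }
    rec <- rec[order(rec$contig_start, rec$ref_start), , drop = FALSE]
    if (nrow(rec) < 2L) next
    for (p in seq_len(nrow(rec) - 1L)) {
      a <- rec[p, ]
      b <- rec[p + 1L, ]
      colinear <- a$chromosome_id == b$chromosome_id &&
        (b$ref_start - a$ref_end) == (b$contig_start - a$contig_end)
      if (!colinear) {
        out <- rbind(out, data.frame(chromosome_id = a$chromosome_id,
                                     position = a$ref_end,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Deduplicated misassembly count
#'
#' Overlapping contigs replicate the same breakpoint, so at most one
#' misassembly is counted per reference position: the count of distinct
#' `(chromosome, position)` pairs.
#'
#' @param breakpoints data frame with columns `chromosome_id`, `position`.
#' @return integer count.
#' @export
dedup_misassemblies <- function(breakpoints) {
  if (!nrow(breakpoints)) return(0L)
  nrow(unique(breakpoints[, c("chromosome_id", "position")]))
}

#' Full contig evaluation report
#'
#' Aligns contigs to the reference, sweeps the per-position best-alignment
#' profile and reports EA50max/EA75max, the EAx curve at 1 percent steps,
#' genome fraction, duplication ratio and the deduplicated misassembly
#' count. With `hpc = TRUE` the evaluation runs in homopolymer-compressed
#' space (both reference and contigs are compressed first).
#'
#' @param contigs a [contig_set] or character vector of sequences.
#' @param genome the reference [genome].
#' @param k word size (used as the minimum reported match length).
#' @param hpc evaluate in homopolymer-compressed space.
#' @return list with fields `ea50max`, `ea75max`, `curve`, `genome_fraction`,
#'   `duplication_ratio`, `misassemblies`, `n_alignments`.
#' @export
evaluate_contigs <- function(contigs, genome, k, hpc = FALSE) {
  seqs <- if (inherits(contigs, "contig_set")) spell_contigs(contigs)
          else as.character(contigs)
  if (is.null(names(seqs)) && length(seqs)) {
    names(seqs) <- paste0("sot_", seq_along(seqs))
  }
  if (hpc) {
    genome <- compress_genome(genome)
    seqs <- vapply(seqs, compress_homopolymers, "")
  }
  aln <- exact_match_alignments(seqs, genome, min_len = k)
  prof <- ea_profile(aln, genome)
  cov <- coverage_stats(aln, genome)
  mis <- dedup_misassemblies(alignment_breakpoints(aln, nchar(seqs)))
  list(ea50max = eaxmax(prof, 50), ea75max = eaxmax(prof, 75),
       curve = ea_curve(prof),
       genome_fraction = unname(cov["genome_fraction"]),
       duplication_ratio = unname(cov["duplication_ratio"]),
       misassemblies = mis, n_alignments = nrow(aln))
}
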