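# Canonical tetranucleotide enumeration, double-stranded k-mer counting,
# TETRA-style z-values and Pearson correlation between z-vectors.

.tetra_cache <- new.env(parent = emptyenv())

.all_kmers <- function(k) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

.revcomp_strings <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Precomputed index maps used by zvalues(); built once per session.
.tetra_maps <- function() {
  if (!is.null(.tetra_cache$maps)) {
    return(.tetra_cache$maps)
  }
  k4 <- .all_kmers(4)
  k3 <- .all_kmers(3)
  k2 <- .all_kmers(2)
  canon <- canonical_tetranucleotides()
  maps <- list(
    k4 = k4, k3 = k3, k2 = k2,
    # permutation sending counts(w) -> counts(revcomp(w))
    rc4 = match(.revcomp_strings(k4), k4),
    rc3 = match(.revcomp_strings(k3), k3),
    rc2 = match(.revcomp_strings(k2), k2),
    canon = canon,
    i_w   = match(canon, k4),
    i_pre = match(substr(canon, 1, 3), k3),
    i_suf = match(substr(canon, 2, 4), k3),
    i_mid = match(substr(canon, 2, 3), k2)
  )
  .tetra_cache$maps <- maps
  maps
}

.sieve_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "tetrasieve_error")))
}

#' Canonical tetranucleotide index
#'
#' Enumerates the 136 canonical tetranucleotides obtained by collapsing each
#' of the 256 tetranucleotides with its reverse complement and keeping the
#' lexicographically smaller member of every pair (the 16 reverse-complement
#' palindromes are self-canonical). All z-vectors produced by this package
#' are aligned to this index, which is deterministic and sorted.
#'
#' @return A character vector of length 136, lexicographically sorted.
#' @examples
#' idx <- canonical_tetranucleotides()
#' length(idx) # 136
#' @export
canonical_tetranucleotides <- function() {
  if (!is.null(.tetra_cache$canon)) {
    return(.tetra_cache$canon)
  }
  k4 <- .all_kmers(4)
  rc <- .revcomp_strings(k4)
  canon <- sort(unique(pmin(k4, rc)))
  .tetra_cache$canon <- canon
  canon
}

.as_dna <- function(seq) {
  if (inherits(seq, "DNAString")) {
    return(seq)
  }
  if (is.character(seq) && length(seq) == 1L) {
    return(Biostrings::DNAString(toupper(seq)))
  }
  .sieve_error("tetrasieve_input_error",
               "expected a single nucleotide string or DNAString")
}

#' Double-stranded k-mer counts
#'
#' Counts k-mer occurrences over a sequence and its reverse complement
#' summed together, so that `count(w) == count(revcomp(w))` for every word.
#' Windows containing non-ACGT characters (IUPAC ambiguity codes) are
#' skipped on both strands.
#'
#' @param seq A nucleotide string or `DNAString`.
#' @param k Word size; one of 2, 3 or 4.
#' @return Named integer vector of length `4^k` (lexicographic order).
#' @export
count_kmers <- function(seq, k) {
  if (!k %in% c(2L, 3L, 4L)) {
    .sieve_error("tetrasieve_input_error", "k must be 2, 3 or 4")
  }
  s <- .as_dna(seq)
  n <- Biostrings::oligonucleotideFrequency(s, width = k)
  maps <- .tetra_maps()
  rc <- switch(as.character(k), "2" = maps$rc2, "3" = maps$rc3, "4" = maps$rc4)
  n + n[rc]
}

#' Tetranucleotide z-values of a sequence
#'
#' Computes the 136 canonical tetranucleotide z-values of a sequence under
#' the maximal-order Markov model: for word w = w1w2w3w4 with double-stranded
#' counts n(.),
#' `E = n(w1w2w3) * n(w2w3w4) / n(w2w3)`,
#' `var = E * (1 - n(w1w2w3)/n(w2w3)) * (1 - n(w2w3w4)/n(w2w3))`,
#' `z = (n(w) - E) / sqrt(var)`.
#' Whenever `n(w2w3) = 0` or `var <= 0` the z-value is set to 0 (a neutral
#' value that cannot create spurious correlation). Counting is
#' double-stranded, so z-values are exactly strand-symmetric and nothing is
#' lost by reporting only the 136 canonical words.
#'
#' @param seq A nucleotide string or `DNAString`, length >= 4.
#' @return Named numeric vector of length 136 aligned to
#'   [canonical_tetranucleotides()], with attribute `source_length_bp`.
#' @export
zvalues <- function(seq) {
  s <- .as_dna(seq)
  if (length(s) < 4L) {
    .sieve_error("tetrasieve_input_error",
                 "sequence must be at least 4 bp for tetranucleotide z-values")
  }
  maps <- .tetra_maps()
  n4 <- Biostrings::oligonucleotideFrequency(s, width = 4)
  n3 <- Biostrings::oligonucleotideFrequency(s, width = 3)
  n2 <- Biostrings::oligonucleotideFrequency(s, width = 2)
  d4 <- as.numeric(n4 + n4[maps$rc4])
  d3 <- as.numeric(n3 + n3[maps$rc3])
  d2 <- as.numeric(n2 + n2[maps$rc2])

  pre <- d3[maps$i_pre]
  suf <- d3[maps$i_suf]
  mid <- d2[maps$i_mid]
  e <- ifelse(mid > 0, pre * suf / mid, 0)
  v <- ifelse(mid > 0, e * (1 - pre / mid) * (1 - suf / mid), 0)
  z <- ifelse(mid > 0 & v > 0, (d4[maps$i_w] - e) / sqrt(v), 0)
  z[!is.finite(z)] <- 0
  names(z) <- maps$canon
  attr(z, "source_length_bp") <- length(s)
  z
}

#' Pearson correlation between two z-vectors (PCCD)
#'
#' The similarity measure used throughout the sieve: the plain Pearson
#' correlation coefficient of two 136-dimensional z-vectors. Despite the
#' historical name "distance" (PCCD), higher values mean more similar
#' signatures, and the sieve keeps pairs whose PCCD is at or above a cutoff
#' (TETRA-lineage methods use r >= 0.99 the same way).
#'
#' @param a,b Numeric vectors of equal length (typically 136 z-values).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pccd <- function(a, b) {
  if (length(a) != length(b)) {
    .sieve_error("tetrasieve_input_error", "z-vectors differ in length")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    .sieve_error("tetrasieve_undefined_correlation",
                 "correlation undefined: zero-variance z-vector")
  }
  stats::cor(a, b)
}
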