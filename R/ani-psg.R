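# NUCmer ".delta" parsing and the alignment-based pair statistics:
# average nucleotide identity (ANI) and percentage of shared genome (PSG).

#' Parse a NUCmer delta file
#'
#' Reads a nucleotide (NUCMER) delta file. Each alignment block has a
#' seven-value header -- start and end in the reference, start and end in
#' the query, the number of errors (non-identities + indels), the number
#' of similarity errors, and the stop-codon count -- followed by one
#' signed indel digit per line, terminated by a 0. A negative digit is a
#' gap (deletion) in the reference. Coordinates are stored exactly as
#' written (1-based inclusive; reverse-strand alignments keep
#' `q_start > q_end`).
#'
#' @param path Path to a `.delta` file.
#' @return A data.frame with one row per alignment: `ref_id`, `query_id`,
#'   `ref_start`, `ref_end`, `q_start`, `q_end`, `n_errors`,
#'   `n_sim_errors`, `n_stop` and a list-column `digits` (terminator not
#'   stored). Sequence lengths from the `>` headers are kept in
#'   attributes `ref_lengths` and `query_lengths`.
#' @export
parse_delta <- function(path) {
  if (!file.exists(path)) {
    .sieve_error("tetrasieve_input_error", "file not found: %s", path)
  }
  lines <- readLines(path)
  if (length(lines) < 2L) {
    .sieve_error("tetrasieve_delta_parse_error", "truncated delta file: %s", path)
  }
  if (!grepl("NUCMER", lines[2], fixed = TRUE)) {
    .sieve_error("tetrasieve_delta_parse_error",
                 "not a nucleotide (NUCMER) delta file: header '%s'", lines[2])
  }
  rows <- list()
  ref_lengths <- numeric(0)
  query_lengths <- numeric(0)
  ref_id <- query_id <- NA_character_
  i <- 3L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      f <- strsplit(sub("^>", "", ln), "\\s+")[[1]]
      if (length(f) != 4L) {
        .sieve_error("tetrasieve_delta_parse_error",
                     "line %d: malformed sequence header '%s'", i, ln)
      }
      ref_id <- f[1]
      query_id <- f[2]
      ref_lengths[ref_id] <- as.numeric(f[3])
      query_lengths[query_id] <- as.numeric(f[4])
      i <- i + 1L
      next
    }
    f <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (length(f) != 7L || anyNA(f)) {
      .sieve_error("tetrasieve_delta_parse_error",
                   "line %d: expected a 7-value alignment header, got '%s'",
                   i, ln)
    }
    hdr_line <- i
    digits <- numeric(0)
    i <- i + 1L
    terminated <- FALSE
    while (i <= length(lines)) {
      d <- suppressWarnings(as.numeric(trimws(lines[i])))
      if (is.na(d)) {
        .sieve_error("tetrasieve_delta_parse_error",
                     "line %d: expected indel digit, got '%s'", i, lines[i])
      }
      i <- i + 1L
      if (d == 0) {
        terminated <- TRUE
        break
      }
      digits <- c(digits, d)
    }
    if (!terminated) {
      .sieve_error("tetrasieve_delta_parse_error",
                   "alignment block at line %d misses its 0 terminator",
                   hdr_line)
    }
    rows[[length(rows) + 1L]] <- list(
      ref_id = ref_id, query_id = query_id,
      ref_start = f[1], ref_end = f[2], q_start = f[3], q_end = f[4],
      n_errors = f[5], n_sim_errors = f[6], n_stop = f[7], digits = digits
    )
  }
  out <- data.frame(
    ref_id = vapply(rows, `[[`, character(1), "ref_id"),
    query_id = vapply(rows, `[[`, character(1), "query_id"),
    ref_start = vapply(rows, `[[`, numeric(1), "ref_start"),
    ref_end = vapply(rows, `[[`, numeric(1), "ref_end"),
    q_start = vapply(rows, `[[`, numeric(1), "q_start"),
    q_end = vapply(rows, `[[`, numeric(1), "q_end"),
    n_errors = vapply(rows, `[[`, numeric(1), "n_errors"),
    n_sim_errors = vapply(rows, `[[`, numeric(1), "n_sim_errors"),
    n_stop = vapply(rows, `[[`, numeric(1), "n_stop")
  )
  out$digits <- lapply(rows, `[[`, "digits")
  attr(out, "ref_lengths") <- ref_lengths
  attr(out, "query_lengths") <- query_lengths
  out
}

#' Write alignments back to delta format (fixture writer)
#'
#' Serializes alignments in the canonical layout produced by
#' [parse_delta()]; parse -> write -> parse round-trips exactly. Intended
#' for building synthetic fixtures, not for feeding MUMmer tools.
#'
#' @param alignments A data.frame as returned by [parse_delta()].
#' @param path Output path.
#' @param ref_path,query_path File paths for the first header line.
#' @return `path`, invisibly.
#' @export
write_delta <- function(alignments, path, ref_path = "ref.fa",
                        query_path = "qry.fa") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(ref_path, query_path), "NUCMER"), con)
  ref_lengths <- attr(alignments, "ref_lengths")
  query_lengths <- attr(alignments, "query_lengths")
  last <- ""
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    key <- paste(a$ref_id, a$query_id)
    if (key != last) {
      writeLines(sprintf(">%s %s %d %d", a$ref_id, a$query_id,
                         as.integer(ref_lengths[[a$ref_id]]),
                         as.integer(query_lengths[[a$query_id]])), con)
      last <- key
    }
    writeLines(paste(a$ref_start, a$ref_end, a$q_start, a$q_end,
                     a$n_errors, a$n_sim_errors, a$n_stop), con)
    writeLines(as.character(c(alignments$digits[[i]], 0)), con)
  }
  invisible(path)
}

#' Average nucleotide identity from delta alignments
#'
#' Reference-based ANI pooled over all alignment blocks:
#' `ANI = sum(stretch + negatives - errors) / sum(stretch + negatives)`,
#' where `stretch = ref_end - ref_start + 1` is the aligned stretch length
#' in the reference and `negatives` is the number of negative indel
#' digits (gaps in the reference). Blocks pool additively -- this is not
#' the mean of per-block identities.
#'
#' @param alignments A data.frame as returned by [parse_delta()].
#' @return ANI as a percentage in `[0, 100]`.
#' @export
ani <- function(alignments) {
  if (nrow(alignments) < 1L) {
    .sieve_error("tetrasieve_input_error", "need at least one alignment")
  }
  stretch <- alignments$ref_end - alignments$ref_start + 1
  n_neg <- vapply(alignments$digits, function(d) sum(d < 0), numeric(1))
  den <- sum(stretch + n_neg)
  if (den <= 0) {
    .sieve_error("tetrasieve_input_error", "zero total aligned length")
  }
  100 * sum(stretch + n_neg - alignments$n_errors) / den
}

.union_width <- function(starts, ends, L, what) {
  if (any(starts < 1 | ends > L)) {
    .sieve_error("tetrasieve_input_error",
                 "%s interval outside [1, %d]", what, L)
  }
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = starts,
                                                      end = ends))))
}

#' Percentage of shared genome (PSG) from delta alignments
#'
#' `PSG = (aligned positions in the query + aligned positions in the
#' reference) / (L1 + L2)`, where aligned positions are counted once per
#' genome via interval union, so overlapping alignments (repeats,
#' paralogs) do not inflate the estimate. Reverse-strand alignments
#' (`q_start > q_end`) are normalized before the union.
#'
#' @param alignments A data.frame as returned by [parse_delta()].
#' @param L1 Total query genome length in bp.
#' @param L2 Total reference genome length in bp.
#' @return PSG as a percentage in `[0, 100]`.
#' @export
psg <- function(alignments, L1, L2) {
  if (L1 <= 0 || L2 <= 0) {
    .sieve_error("tetrasieve_input_error", "genome lengths must be positive")
  }
  qs <- pmin(alignments$q_start, alignments$q_end)
  qe <- pmax(alignments$q_start, alignments$q_end)
  rs <- pmin(alignments$ref_start, alignments$ref_end)
  re <- pmax(alignments$ref_start, alignments$ref_end)
  q_cov <- .union_width(qs, qe, L1, "query")
  r_cov <- .union_width(rs, re, L2, "reference")
  100 * (q_cov + r_cov) / (L1 + L2)
}
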