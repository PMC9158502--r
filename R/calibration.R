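# Length-specific calibration: empirical intraspecific PCCD distributions
# per genome-size bin, feeding the LSC1/LSC2 cutoffs.

#' Validate a calibration table
#'
#' @param table A data.frame with columns `kb`, `mean_intra`, `sd_intra`,
#'   `n_samples`.
#' @param min_samples Minimum draws required per row (default 2; the
#'   shipped default table uses 200).
#' @return The validated table (invisibly the same object).
#' @export
validate_calibration <- function(table, min_samples = 2) {
  need <- c("kb", "mean_intra", "sd_intra", "n_samples")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    .sieve_error("tetrasieve_format_error",
                 "calibration table needs columns: %s",
                 paste(need, collapse = ", "))
  }
  if (nrow(table) == 0L) {
    .sieve_error("tetrasieve_format_error", "calibration table is empty")
  }
  if (any(diff(table$kb) <= 0)) {
    .sieve_error("tetrasieve_format_error",
                 "calibration kb bins must be strictly increasing")
  }
  if (max(table$kb) > 200) {
    .sieve_error("tetrasieve_format_error",
                 "calibration bins are capped at 200 kb")
  }
  if (any(table$sd_intra < 0) || any(table$mean_intra > 1)) {
    .sieve_error("tetrasieve_format_error",
                 "calibration rows out of range (mean <= 1, sd >= 0)")
  }
  if (any(table$n_samples < min_samples)) {
    .sieve_error("tetrasieve_format_error",
                 "calibration rows with fewer than %d samples", min_samples)
  }
  table
}

#' Calibrate length-specific intraspecific PCCD distributions
#'
#' For each genome-size bin `kb`, repeatedly samples two overlapping
#' extracts of `kb` kilobases from the same genome (an intraspecific
#' proxy: mutual overlap drawn uniformly from 70-100%, placed uniformly at
#' random), computes the PCCD between the extracts' tetranucleotide
#' z-vectors, and records the mean and sample SD over `n_pairs_per_bin`
#' draws. Genomes shorter than a bin are skipped for that bin; eligible
#' genomes are cycled per draw.
#'
#' @param genomes List of `sieve_genome` objects (concatenated or
#'   single-sequence).
#' @param bins_kb Integer bins in kb (default 10 to 200 by 10; capped at
#'   200).
#' @param n_pairs_per_bin Number of extract pairs per bin (default 200).
#' @param seed Optional integer seed; fixed seed gives a bit-identical
#'   table.
#' @param min_overlap Lower bound of the mutual-overlap fraction
#'   (default 0.7, matching the >= 70% shared-genome definition of
#'   intraspecies pairs).
#' @param provenance Free-text provenance string stored with the table.
#' @return A calibration table: data.frame with columns `kb`,
#'   `mean_intra`, `sd_intra`, `n_samples` and attribute `provenance`.
#' @export
calibrate <- function(genomes, bins_kb = seq(10, 200, by = 10),
                      n_pairs_per_bin = 200, seed = NULL,
                      min_overlap = 0.7,
                      provenance = "calibrate()") {
  if (n_pairs_per_bin < 2) {
    .sieve_error("tetrasieve_input_error", "n_pairs_per_bin must be >= 2")
  }
  bins_kb <- sort(unique(pmin(as.integer(bins_kb), 200L)))
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  dnas <- lapply(genomes, function(g) {
    if (length(g$seqs) > 1L) g <- bayes_concatenate(g)
    g$seqs[[1]]
  })
  lens <- vapply(dnas, length, integer(1))
  rows <- lapply(bins_kb, function(kb) {
    size <- kb * 1000L
    eligible <- which(lens >= size)
    if (length(eligible) == 0L) {
      .sieve_error("tetrasieve_calibration_missing",
                   "no genome long enough for the %d kb bin", kb)
    }
    pccds <- vapply(seq_len(n_pairs_per_bin), function(j) {
      gi <- eligible[((j - 1L) %% length(eligible)) + 1L]
      dna <- dnas[[gi]]
      L <- lens[gi]
      o <- round(stats::runif(1, min_overlap, 1) * size)
      o <- max(o, 2L * size - L)  # both extracts must fit in the genome
      span <- 2L * size - o
      s1 <- min(floor(stats::runif(1, 0, L - span + 1)), L - span)
      s2 <- s1 + size - o
      pccd(
        zvalues(Biostrings::subseq(dna, s1 + 1L, s1 + size)),
        zvalues(Biostrings::subseq(dna, s2 + 1L, s2 + size))
      )
    }, numeric(1))
    data.frame(kb = kb, mean_intra = mean(pccds),
               sd_intra = stats::sd(pccds), n_samples = n_pairs_per_bin)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- provenance
  validate_calibration(out)
  out
}

#' Save / load a calibration table as TSV
#'
#' The TSV has columns `kb`, `mean_intra`, `sd_intra`, `n_samples`; the
#' provenance string is kept in a `# provenance:` comment line. The
#' round-trip is lossless (values written at full precision).
#'
#' @param table A calibration table.
#' @param path TSV file path.
#' @return `save_calibration()` returns `path` invisibly.
#' @export
save_calibration <- function(table, path) {
  validate_calibration(table)
  con <- file(path, "w")
  on.exit(close(con))
  prov <- attr(table, "provenance") %||% ""
  writeLines(sprintf("# provenance: %s", prov), con)
  utils::write.table(
    data.frame(kb = table$kb,
               mean_intra = sprintf("%.17g", table$mean_intra),
               sd_intra = sprintf("%.17g", table$sd_intra),
               n_samples = table$n_samples),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) {
    .sieve_error("tetrasieve_input_error", "file not found: %s", path)
  }
  lines <- readLines(path)
  prov <- sub("^# provenance: ?", "", grep("^# provenance:", lines, value = TRUE))
  df <- utils::read.delim(text = lines, comment.char = "#")
  df <- validate_calibration(df)
  attr(df, "provenance") <- if (length(prov)) prov[1] else ""
  df
}

#' The packaged default calibration table
#'
#' A calibration table generated by [calibrate()] on packaged synthetic
#' Markov-mixture genomes (see the shipped TSV's provenance line for the
#' exact seed and generator settings). It is a synthetic stand-in for
#' empirical intraspecific PCCD distributions of real genomes: use a table
#' calibrated on your own data when available.
#'
#' @return A calibration table.
#' @export
default_calibration <- function() {
  load_calibration(system.file("extdata", "lsc_synthetic_default.tsv",
                               package = "tetrasieve", mustWork = TRUE))
}

# RNG bookkeeping: run seeded code without disturbing the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
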