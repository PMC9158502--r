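# Fragmenting stage: window rules, ZRF by central-value averaging,
# genome-specific cutoff (GSC), length-specific cutoffs (LSC1/LSC2) and
# the 10-kb re-fragmenting fallback for compositionally heterogeneous
# genomes.

#' Divide a concatenated genome into sliding windows
#'
#' Window rules, with `L` the total (concatenated) genome length:
#' * `L < 40 kb`: no dividing; one window covering the whole genome.
#' * `40 kb <= L <= 800 kb`: window size `l = L/4`, giving exactly 8
#'   windows (7 full plus one final half-length window).
#' * `L > 800 kb`: `l = L/4` (still 8 windows) when the genome's average
#'   retained-sequence size exceeds 200 kb, otherwise `l = 200 kb`.
#'
#' Windows start at multiples of `0.5 l` while the start is below `L`;
#' consecutive windows overlap by `0.5 l`. The final window is truncated
#' at `L` and kept only if its length is at least `0.5 l`.
#'
#' @param g A `sieve_genome` (already concatenated) or, alternatively, a
#'   total length in bp via `L_bp` and `avg_seq_size_bp`.
#' @param L_bp,avg_seq_size_bp Optional scalar overrides used when `g` is
#'   missing (handy for window-arithmetic checks).
#' @param l_bp Optional fixed window size (used for the 10-kb
#'   re-fragmenting); when given, the `L`-dependent rules are bypassed.
#' @return A data.frame with 0-based half-open columns `start`, `end`,
#'   and attribute `l_bp` (the window size used).
#' @export
divide_genome <- function(g = NULL, L_bp = NULL, avg_seq_size_bp = NULL,
                          l_bp = NULL) {
  if (!is.null(g)) {
    stopifnot(inherits(g, "sieve_genome"))
    L_bp <- g$total_length_bp
    avg_seq_size_bp <- g$avg_seq_size_bp
  }
  if (is.null(L_bp) || is.null(avg_seq_size_bp)) {
    .sieve_error("tetrasieve_input_error",
                 "need a genome or both L_bp and avg_seq_size_bp")
  }
  if (L_bp < 10000) {
    .sieve_error("tetrasieve_short_genome",
                 "genome of %d bp is below the 10 kb sieving minimum", L_bp)
  }
  if (is.null(l_bp)) {
    if (L_bp < 40000) {
      out <- data.frame(start = 0, end = L_bp)
      attr(out, "l_bp") <- as.numeric(L_bp)
      return(out)
    }
    l_bp <- if (L_bp <= 800000) {
      L_bp / 4
    } else if (avg_seq_size_bp > 200000) {
      L_bp / 4
    } else {
      200000
    }
  }
  l_bp <- as.numeric(l_bp)
  step <- l_bp / 2
  k <- 0:(ceiling(L_bp / step) - 1)
  k <- k[k * step < L_bp]
  start <- round(k * step)
  end <- pmin(round(k * step + l_bp), L_bp)
  keep <- (end - start) >= (step - 0.5)  # 0.5 absorbs integer rounding
  out <- data.frame(start = start[keep], end = end[keep])
  attr(out, "l_bp") <- l_bp
  out
}

#' Representative-fragment z-values (ZRF)
#'
#' Summarises per-fragment z-vectors into one genome signature by, for each
#' canonical tetranucleotide independently, sorting the fragment z-values
#' and averaging the central three (odd number of fragments, >= 3) or
#' central four (even number, >= 4). Degenerate cases: one fragment
#' returns its vector verbatim; two fragments return their mean (the only
#' consistent reading of the central-four rule).
#'
#' @param zmat A 136 x n matrix of fragment z-vectors (columns =
#'   fragments), or a list of 136-long z-vectors.
#' @return A named numeric vector of length 136.
#' @export
compute_zrf <- function(zmat) {
  if (is.list(zmat)) {
    zmat <- do.call(cbind, zmat)
  }
  if (is.null(dim(zmat)) || ncol(zmat) < 1L) {
    .sieve_error("tetrasieve_input_error", "need at least one fragment z-vector")
  }
  n <- ncol(zmat)
  if (n == 1L) {
    zrf <- zmat[, 1]
  } else if (n == 2L) {
    zrf <- rowMeans(zmat)
  } else {
    idx <- if (n %% 2L == 1L) {
      ((n + 1L) %/% 2L - 1L):((n + 1L) %/% 2L + 1L)
    } else {
      (n %/% 2L - 1L):(n %/% 2L + 2L)
    }
    # sort all rows with a single order() call (row-major grouping)
    sorted <- matrix(zmat[order(row(zmat), zmat)], nrow = nrow(zmat),
                     byrow = TRUE)
    zrf <- rowMeans(sorted[, idx, drop = FALSE])
  }
  names(zrf) <- rownames(zmat) %||% canonical_tetranucleotides()
  zrf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-specific cutoff (GSC)
#'
#' The per-genome PCCD threshold derived from the intragenomic PCCDs of
#' each fragment against the ZRF: `GSC = Mean - SD - 0.01`, where 0.01
#' guards against boundary effects and SD is the sample (n-1) standard
#' deviation (0 for a single fragment). The legacy mode uses the older
#' `Mean - 2 SD` rule instead, retained for comparison.
#'
#' @param pccds Numeric vector of intragenomic PCCDs (>= 1 value).
#' @param mode `"strict"` (Mean - SD - 0.01, default) or `"legacy"`
#'   (Mean - 2 SD).
#' @param boundary_epsilon The boundary-effect constant (default 0.01).
#' @return The cutoff as a scalar.
#' @export
compute_gsc <- function(pccds, mode = c("strict", "legacy"),
                        boundary_epsilon = 0.01) {
  mode <- match.arg(mode)
  if (length(pccds) < 1L) {
    .sieve_error("tetrasieve_input_error", "need at least one PCCD")
  }
  s <- if (length(pccds) == 1L) 0 else stats::sd(pccds)
  m <- mean(pccds)
  if (mode == "strict") m - s - boundary_epsilon else m - 2 * s
}

#' Length-specific cutoffs (LSC1, LSC2)
#'
#' Looks up the empirical intraspecific PCCD distribution for a genome of
#' total length `L_bp` in a calibration table of `(kb, mean_intra,
#' sd_intra)` rows and returns
#' `LSC1 = mean - sd - 0.01` and `LSC2 = mean - 2 sd`.
#' The size in kb is capped at 200 and snapped to the nearest table bin.
#'
#' @param L_bp Total genome length in bp (>= 10,000).
#' @param table A calibration table (see [calibrate()]).
#' @param boundary_epsilon The boundary-effect constant (default 0.01).
#' @return Named list with elements `lsc1`, `lsc2` and `kb` (the bin used).
#' @export
lsc_values <- function(L_bp, table, boundary_epsilon = 0.01) {
  table <- validate_calibration(table)
  kb <- min(round(L_bp / 1000), 200)
  bins <- table$kb
  i <- which.min(abs(bins - kb))
  tol <- if (length(bins) > 1L) max(diff(bins)) else Inf
  if (abs(bins[i] - kb) > tol) {
    .sieve_error("tetrasieve_calibration_missing",
                 "no calibration bin near %d kb (nearest: %d kb)", kb, bins[i])
  }
  list(
    lsc1 = table$mean_intra[i] - table$sd_intra[i] - boundary_epsilon,
    lsc2 = table$mean_intra[i] - 2 * table$sd_intra[i],
    kb = bins[i]
  )
}

# z-vectors for all windows at once: one vectorized counting call per
# k-mer width (numerically identical to zvalues() per fragment, which the
# tests assert).
.fragment_zmatrix <- function(dna, windows) {
  maps <- .tetra_maps()
  v <- Biostrings::Views(dna, start = windows$start + 1L, end = windows$end)
  cnt <- function(k, rc) {
    m <- Biostrings::oligonucleotideFrequency(v, width = k)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    storage.mode(m) <- "double"   # count products overflow integers
    m + m[, rc, drop = FALSE]
  }
  d4 <- cnt(4L, maps$rc4)
  d3 <- cnt(3L, maps$rc3)
  d2 <- cnt(2L, maps$rc2)
  pre <- d3[, maps$i_pre, drop = FALSE]
  suf <- d3[, maps$i_suf, drop = FALSE]
  mid <- d2[, maps$i_mid, drop = FALSE]
  e <- pre * suf / mid
  vv <- e * (1 - pre / mid) * (1 - suf / mid)
  z <- (d4[, maps$i_w, drop = FALSE] - e) / sqrt(vv)
  z[mid == 0 | !(vv > 0) | !is.finite(z)] <- 0
  out <- t(z)
  rownames(out) <- maps$canon
  out
}

#' Build the sieve signature of a genome
#'
#' Runs the full fragmenting stage for one genome: concatenation (if still
#' multi-sequence), window division, per-fragment z-values, ZRF,
#' intragenomic fragment-vs-ZRF PCCDs, and the GSC; then applies the
#' length-specific cutoffs:
#' * if the raw GSC falls below LSC1, the stored GSC is raised to LSC1
#'   (`restricted_by_lsc1 = TRUE`), keeping specificity high;
#' * if the raw GSC is at or below LSC2 the genome's tetranucleotide
#'   composition is too heterogeneous for the standard windows, and the
#'   ZRF (only the ZRF; the GSC keeps its restricted value) is recomputed
#'   from 10-kb windows (`refragmented_10kb = TRUE`).
#'
#' @param g A `sieve_genome` (pre-processed; concatenated if needed).
#' @param table Calibration table for the length-specific cutoffs.
#' @param gsc_mode `"strict"` or `"legacy"`, see [compute_gsc()].
#' @param refragment_l_bp Window size for the re-fragmenting fallback
#'   (default 10,000 bp).
#' @param boundary_epsilon The boundary-effect constant (default 0.01).
#' @return An object of class `sieve_signature`: list with `genome_id`,
#'   `zrf` (136 values), `gsc`, `gsc_raw`, `lsc1`, `lsc2`,
#'   `restricted_by_lsc1`, `refragmented_10kb`, `n_fragments`, `L_bp`.
#' @export
build_signature <- function(g, table, gsc_mode = c("strict", "legacy"),
                            refragment_l_bp = 10000,
                            boundary_epsilon = 0.01) {
  stopifnot(inherits(g, "sieve_genome"))
  gsc_mode <- match.arg(gsc_mode)
  if (length(g$seqs) > 1L) {
    g <- bayes_concatenate(g)
  }
  dna <- g$seqs[[1]]
  windows <- divide_genome(g)
  zmat <- .fragment_zmatrix(dna, windows)
  zrf <- compute_zrf(zmat)
  pccds <- vapply(seq_len(ncol(zmat)), function(i) pccd(zmat[, i], zrf),
                  numeric(1))
  gsc_raw <- compute_gsc(pccds, mode = gsc_mode,
                         boundary_epsilon = boundary_epsilon)
  lsc <- lsc_values(g$total_length_bp, table,
                    boundary_epsilon = boundary_epsilon)
  restricted <- gsc_raw < lsc$lsc1
  gsc <- if (restricted) lsc$lsc1 else gsc_raw
  refragged <- gsc_raw <= lsc$lsc2
  n_frag <- ncol(zmat)
  if (refragged) {
    w10 <- divide_genome(g, l_bp = refragment_l_bp)
    zrf <- compute_zrf(.fragment_zmatrix(dna, w10))
    n_frag <- nrow(w10)
  }
  structure(
    list(
      genome_id = g$id,
      zrf = zrf,
      gsc = gsc,
      gsc_raw = gsc_raw,
      lsc1 = lsc$lsc1,
      lsc2 = lsc$lsc2,
      restricted_by_lsc1 = restricted,
      refragmented_10kb = refragged,
      n_fragments = n_frag,
      L_bp = g$total_length_bp
    ),
    class = "sieve_signature"
  )
}

#' @export
print.sieve_signature <- function(x, ...) {
  cat(sprintf(
    paste0("<sieve_signature> %s: L=%s bp, %d fragment(s), GSC=%.4f",
           " (raw %.4f, LSC1=%.4f, LSC2=%.4f)%s%s\n"),
    x$genome_id, format(x$L_bp, big.mark = ","), x$n_fragments, x$gsc,
    x$gsc_raw, x$lsc1, x$lsc2,
    if (x$restricted_by_lsc1) " [LSC1-restricted]" else "",
    if (x$refragmented_10kb) " [10kb-refragmented]" else ""
  ))
  invisible(x)
}

#' Save / load signature caches
#'
#' Signatures are cached as TSV with one row per genome: id, the 136 ZRF
#' values, gsc, lsc1, lsc2 and the provenance flags.
#'
#' @param sigs A list of `sieve_signature` objects.
#' @param path TSV file path.
#' @return `save_signatures()` returns `path` invisibly;
#'   `load_signatures()` returns a list of `sieve_signature` objects.
#' @export
save_signatures <- function(sigs, path) {
  canon <- canonical_tetranucleotides()
  df <- do.call(rbind, lapply(sigs, function(s) {
    row <- data.frame(
      genome_id = s$genome_id, gsc = s$gsc, gsc_raw = s$gsc_raw,
      lsc1 = s$lsc1, lsc2 = s$lsc2,
      restricted_by_lsc1 = s$restricted_by_lsc1,
      refragmented_10kb = s$refragmented_10kb,
      n_fragments = s$n_fragments, L_bp = s$L_bp
    )
    zdf <- as.data.frame(as.list(stats::setNames(s$zrf, paste0("z_", canon))))
    cbind(row, zdf)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_signatures
#' @param path TSV file path.
#' @export
load_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  canon <- canonical_tetranucleotides()
  zcols <- paste0("z_", canon)
  if (!all(zcols %in% names(df))) {
    .sieve_error("tetrasieve_format_error",
                 "signature cache misses ZRF columns")
  }
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(
        genome_id = as.character(df$genome_id[i]),
        zrf = stats::setNames(as.numeric(df[i, zcols]), canon),
        gsc = df$gsc[i], gsc_raw = df$gsc_raw[i],
        lsc1 = df$lsc1[i], lsc2 = df$lsc2[i],
        restricted_by_lsc1 = as.logical(df$restricted_by_lsc1[i]),
        refragmented_10kb = as.logical(df$refragmented_10kb[i]),
        n_fragments = df$n_fragments[i], L_bp = df$L_bp[i]
      ),
      class = "sieve_signature"
    )
  })
}
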