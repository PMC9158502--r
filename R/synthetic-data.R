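# Synthetic genomes and genome pairs with controlled shared-genome
# fraction (PSG) and completeness, plus benchmark metrics. Used for
# calibration, testing and the simulated sieving benchmark.

# Sample block-structured sequences from 3rd-order Markov models.
# All blocks advance in lock-step (one vectorized transition per
# position), which keeps megabase genomes fast in pure R.
.markov_blocks <- function(block_lens, model_of_block, trans_stack) {
  B <- length(block_lens)
  maxlen <- max(block_lens)
  out <- matrix(1L, nrow = B, ncol = maxlen)
  state <- sample.int(64L, B, replace = TRUE)
  s0 <- state - 1L
  out[, 1] <- s0 %/% 16L + 1L
  out[, 2] <- (s0 %/% 4L) %% 4L + 1L
  out[, 3] <- s0 %% 4L + 1L
  offset <- (model_of_block - 1L) * 64L
  # cumulative transition probabilities, flat-indexed by model and state
  c1 <- trans_stack[, 1]
  c2 <- c1 + trans_stack[, 2]
  c3 <- c2 + trans_stack[, 3]
  if (maxlen >= 4L) {
    for (t in 4:maxlen) {
      i <- offset + state
      u <- stats::runif(B)
      d <- 1L + (u > c1[i]) + (u > c2[i]) + (u > c3[i])
      out[, t] <- d
      state <- (state - 1L) %% 16L * 4L + d
    }
  }
  out
}

#' Simulate a genome from a mixture of 3rd-order Markov models
#'
#' Generates a single-sequence genome laid out in consecutive blocks, each
#' block sampled from one of `n_components` distinct 3rd-order Markov
#' models (tetranucleotide transition probabilities drawn from a
#' symmetric Dirichlet). Components cycle across blocks, so at scales
#' above `block_len_bp` every region carries the same component blend:
#' the genome has a strong, genome-wide tetranucleotide signature (as real
#' bacterial genomes do) while still being compositionally heterogeneous
#' at the block scale. With `n_components = 1` the genome is a plain
#' Markov sequence and its z-values are near-zero noise.
#'
#' @param length_bp Genome length (>= 10,000 bp for sieving).
#' @param n_components Number of component models (>= 1; default 3).
#' @param seed Optional integer seed; the same seed reproduces the
#'   sequence exactly.
#' @param block_len_bp Block length in bp (default 5000).
#' @param alpha Dirichlet concentration of the transition rows
#'   (default 1; smaller values give more strongly separated components).
#' @param id Genome id (default `"sim"`).
#' @return A `sieve_genome` with one sequence.
#' @export
simulate_genome <- function(length_bp, n_components = 3, seed = NULL,
                            block_len_bp = 5000, alpha = 1, id = "sim") {
  if (n_components < 1) {
    .sieve_error("tetrasieve_input_error", "n_components must be >= 1")
  }
  if (length_bp < 10000) {
    .sieve_error("tetrasieve_input_error",
                 "simulated genomes must be >= 10 kb")
  }
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  trans_stack <- matrix(stats::rgamma(n_components * 64L * 4L, shape = alpha),
                        ncol = 4L)
  trans_stack <- trans_stack / rowSums(trans_stack)
  n_blocks <- ceiling(length_bp / block_len_bp)
  lens <- rep(block_len_bp, n_blocks)
  lens[n_blocks] <- length_bp - (n_blocks - 1L) * block_len_bp
  comp <- rep_len(seq_len(n_components), n_blocks)
  out <- .markov_blocks(lens, comp, trans_stack)
  flat <- as.vector(t(out))[seq_len(length_bp)]
  seq <- intToUtf8(c(65L, 67L, 71L, 84L)[flat])  # A C G T
  genome(stats::setNames(seq, id), id = id)
}

#' Extract an intraspecific genome pair with controlled PSG
#'
#' Extracts two substrings of a parent genome whose overlap realizes a
#' target shared-genome percentage: extract lengths are
#' `completeness/100 * L`, the overlap is
#' `o = psg_target * (len1 + len2) / 200` bp, and the overlapping layout
#' is placed uniformly at random in the parent. The realized PSG,
#' computed exactly from the coordinates (overlap counted once in each
#' extract over the summed lengths), is returned and is within 0.5
#' percentage points of the target (integer rounding only).
#'
#' @param g Parent `sieve_genome` (single sequence; concatenated first if
#'   not).
#' @param psg_target_pct Target PSG in `[0, 100]`.
#' @param completeness_q_pct,completeness_r_pct Extract sizes as a
#'   percentage of the parent length, in `(0, 100]`.
#' @param seed Optional integer seed for the placement.
#' @param id_suffixes Suffixes appended to the parent id for the two
#'   extracts (default `c("_q", "_r")`).
#' @return A list with `query` and `ref` (`sieve_genome` extracts),
#'   `realized_psg_pct`, and `coords` (0-based parent offsets: `q_start`,
#'   `q_len`, `r_start`, `r_len`, `overlap_bp`).
#' @export
extract_pair <- function(g, psg_target_pct, completeness_q_pct,
                         completeness_r_pct, seed = NULL,
                         id_suffixes = c("_q", "_r")) {
  stopifnot(inherits(g, "sieve_genome"))
  if (psg_target_pct < 0 || psg_target_pct > 100) {
    .sieve_error("tetrasieve_input_error", "psg_target_pct must be in [0, 100]")
  }
  if (completeness_q_pct <= 0 || completeness_q_pct > 100 ||
      completeness_r_pct <= 0 || completeness_r_pct > 100) {
    .sieve_error("tetrasieve_input_error", "completeness must be in (0, 100]")
  }
  if (length(g$seqs) > 1L) {
    g <- bayes_concatenate(g)
  }
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  dna <- g$seqs[[1]]
  L <- length(dna)
  len1 <- round(completeness_q_pct / 100 * L)
  len2 <- round(completeness_r_pct / 100 * L)
  o <- round(psg_target_pct * (len1 + len2) / 200)
  if (o > min(len1, len2)) {
    .sieve_error("tetrasieve_infeasible_pair",
                 paste0("target PSG %.1f%% needs a %d bp overlap, more than ",
                        "the shorter extract (%d bp)"),
                 psg_target_pct, o, min(len1, len2))
  }
  span <- len1 + len2 - o
  if (span > L) {
    .sieve_error("tetrasieve_infeasible_pair",
                 paste0("extracts with the target overlap span %d bp, more ",
                        "than the parent genome (%d bp); lower completeness ",
                        "or raise the PSG target"), span, L)
  }
  s1 <- min(floor(stats::runif(1, 0, L - span + 1)), L - span)
  s2 <- s1 + len1 - o
  qid <- paste0(g$id, id_suffixes[1])
  rid <- paste0(g$id, id_suffixes[2])
  qset <- Biostrings::DNAStringSet(dna, start = s1 + 1L, end = s1 + len1)
  names(qset) <- qid
  rset <- Biostrings::DNAStringSet(dna, start = s2 + 1L, end = s2 + len2)
  names(rset) <- rid
  q <- genome(qset, id = qid)
  r <- genome(rset, id = rid)
  realized <- 100 * 2 * o / (len1 + len2)
  stopifnot(abs(realized - psg_target_pct) <= 0.5)
  list(
    query = q, ref = r, realized_psg_pct = realized,
    coords = list(q_start = s1, q_len = len1, r_start = s2, r_len = len2,
                  overlap_bp = o)
  )
}

#' Perfect synthetic alignment of an extracted pair
#'
#' Builds the delta-style alignment record describing the (ungapped,
#' error-free) overlap of the two extracts of [extract_pair()], in the
#' same shape as [parse_delta()] output. Evaluating [psg()] on it
#' reproduces the pair's realized PSG exactly, tying the simulator's
#' coordinate arithmetic to the alignment-based definition.
#'
#' @param pair A list as returned by [extract_pair()].
#' @return A one-row alignment data.frame with `ref_lengths` /
#'   `query_lengths` attributes.
#' @export
pair_alignment <- function(pair) {
  co <- pair$coords
  if (co$overlap_bp <= 0) {
    .sieve_error("tetrasieve_input_error", "pair has no overlap to align")
  }
  ov_start <- co$r_start                    # 0-based parent coordinate
  q_start <- ov_start - co$q_start + 1L     # 1-based within query extract
  out <- data.frame(
    ref_id = pair$ref$id, query_id = pair$query$id,
    ref_start = 1, ref_end = co$overlap_bp,
    q_start = q_start, q_end = q_start + co$overlap_bp - 1,
    n_errors = 0, n_sim_errors = 0, n_stop = 0
  )
  out$digits <- list(numeric(0))
  attr(out, "ref_lengths") <- stats::setNames(co$r_len, pair$ref$id)
  attr(out, "query_lengths") <- stats::setNames(co$q_len, pair$query$id)
  out
}

#' Sensitivity / specificity of a sieve run against truth labels
#'
#' @param records Sieve records (the `records` element of a
#'   `sieve_result`); a pair counts as sieved whether it passed the cutoff
#'   or was rescued.
#' @param truth A data.frame with columns `query_id`, `ref_id` and
#'   `label` (`"intraspecific"` or `"interspecific"`); each pair at most
#'   once.
#' @return A list with `sensitivity_pct` (sieved intraspecific / all
#'   intraspecific), `specificity_pct` (unsieved interspecific / all
#'   interspecific), `sieved_fraction_pct`, and the confusion counts.
#' @export
benchmark_metrics <- function(records, truth) {
  stopifnot(all(c("query_id", "ref_id", "label") %in% names(truth)))
  if (!all(truth$label %in% c("intraspecific", "interspecific"))) {
    .sieve_error("tetrasieve_input_error",
                 "labels must be 'intraspecific' or 'interspecific'")
  }
  tkey <- paste(truth$query_id, truth$ref_id, sep = "\r")
  if (anyDuplicated(tkey)) {
    .sieve_error("tetrasieve_input_error", "duplicate pairs in truth labels")
  }
  rkey <- unique(paste(records$query_id, records$ref_id, sep = "\r"))
  if (!all(rkey %in% tkey)) {
    .sieve_error("tetrasieve_input_error",
                 "sieve records contain pairs absent from the truth labels")
  }
  sieved <- tkey %in% rkey
  intra <- truth$label == "intraspecific"
  n_intra <- sum(intra)
  n_inter <- sum(!intra)
  list(
    sensitivity_pct = if (n_intra) 100 * sum(sieved & intra) / n_intra else NA,
    specificity_pct = if (n_inter) 100 * sum(!sieved & !intra) / n_inter else NA,
    sieved_fraction_pct = 100 * mean(sieved),
    n_intra = n_intra, n_inter = n_inter,
    n_intra_sieved = sum(sieved & intra), n_inter_sieved = sum(sieved & !intra)
  )
}

#' Run the full simulated sieving benchmark
#'
#' Generates `n_parents` synthetic parent genomes, forms one intraspecific
#' pair per feasible cell of the PSG x completeness grid (both extracts of
#' a pair share the completeness value; a cell is feasible when
#' `completeness <= 100 / (2 - psg/100)`, i.e. PSG 70% allows 10-70%
#' completeness, PSG 100% allows 10-100%), builds all signatures,
#' and sieves all first extracts (queries) against all second extracts
#' (references). Extracts from different parents form the interspecific
#' pairs. The calibration table is, by default, calibrated with the same
#' generator settings on freshly simulated genomes.
#'
#' @param n_parents Number of parent genomes (default 50).
#' @param genome_length_bp Parent genome length (default 1e6).
#' @param psg_levels Target PSG levels (default `c(70, 80, 90, 100)`).
#' @param completeness_levels Completeness grid in percent (default
#'   `seq(10, 100, 10)`); infeasible cells are skipped.
#' @param n_components,block_len_bp,alpha Generator settings, see
#'   [simulate_genome()].
#' @param table Optional pre-built calibration table; when `NULL`, one is
#'   calibrated from `n_calibration_genomes` fresh simulated genomes with
#'   `n_pairs_per_bin` draws per bin.
#' @param n_calibration_genomes,n_pairs_per_bin Calibration settings.
#' @param n_rescue Rescue size for the sieve (default 100).
#' @param seed Integer seed for all randomness.
#' @return A list with `result` (the `sieve_result`), `pairs` (one row
#'   per intraspecific pair: parent, psg target, completeness, realized
#'   PSG, sieved/rescued flags), `metrics` (sensitivity, specificity,
#'   sieved fraction), and `table` (the calibration table used).
#' @export
simulate_benchmark <- function(n_parents = 50, genome_length_bp = 1e6,
                               psg_levels = c(70, 80, 90, 100),
                               completeness_levels = seq(10, 100, 10),
                               n_components = 3, block_len_bp = 5000,
                               alpha = 1, table = NULL,
                               n_calibration_genomes = 5,
                               n_pairs_per_bin = 100,
                               n_rescue = 100, seed = 1) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.null(table)) {
    cal_genomes <- lapply(seq_len(n_calibration_genomes), function(i) {
      simulate_genome(max(genome_length_bp, 200000), n_components,
                      block_len_bp = block_len_bp, alpha = alpha,
                      id = sprintf("cal%02d", i))
    })
    table <- calibrate(cal_genomes, n_pairs_per_bin = n_pairs_per_bin,
                       provenance = sprintf(
                         "simulate_benchmark(seed=%d) generator settings", seed))
  }
  qsigs <- list()
  rsigs <- list()
  pair_rows <- list()
  for (i in seq_len(n_parents)) {
    parent <- simulate_genome(genome_length_bp, n_components,
                              block_len_bp = block_len_bp, alpha = alpha,
                              id = sprintf("parent%03d", i))
    for (p in psg_levels) {
      for (cc in completeness_levels) {
        if (cc > 100 / (2 - p / 100) + 1e-9) next
        pr <- extract_pair(parent, p, cc, cc,
                           id_suffixes = sprintf("_p%d_c%d_%s", p, cc,
                                                 c("q", "r")))
        qsigs[[length(qsigs) + 1L]] <- build_signature(pr$query, table)
        rsigs[[length(rsigs) + 1L]] <- build_signature(pr$ref, table)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          parent = parent$id, query_id = pr$query$id, ref_id = pr$ref$id,
          psg_target_pct = p, completeness_pct = cc,
          realized_psg_pct = pr$realized_psg_pct
        )
      }
    }
  }
  pairs <- do.call(rbind, pair_rows)
  result <- sieve_all(qsigs, rsigs, n_rescue = n_rescue)
  rkey <- paste(result$records$query_id, result$records$ref_id, sep = "\r")
  ikey <- paste(pairs$query_id, pairs$ref_id, sep = "\r")
  pairs$sieved <- ikey %in% rkey
  pairs$rescued <- ikey %in% rkey[result$records$rescued]
  n_intra <- nrow(pairs)
  n_pairs <- length(qsigs) * length(rsigs)   # ids are disjoint; no self-pairs
  n_inter <- n_pairs - n_intra
  n_inter_sieved <- length(unique(rkey)) - sum(pairs$sieved)
  metrics <- list(
    sensitivity_pct = 100 * sum(pairs$sieved) / n_intra,
    specificity_pct = 100 * (n_inter - n_inter_sieved) / n_inter,
    sieved_fraction_pct = 100 * length(unique(rkey)) / n_pairs,
    n_intra = n_intra, n_inter = n_inter,
    n_intra_sieved = sum(pairs$sieved), n_inter_sieved = n_inter_sieved
  )
  list(result = result, pairs = pairs, metrics = metrics, table = table)
}
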