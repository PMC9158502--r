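# Determining stage: all-vs-all ZRF correlations, the pairwise cutoff
# rule, and the top-N rescue for queries that sieve nothing.

#' Decide whether a single genome pair is sieved
#'
#' The pair cutoff `GSC_p` is the smaller of the two genome-specific
#' cutoffs; the pair is sieved when the PCCD between the two ZRFs is at or
#' above `GSC_p` (the comparison is inclusive). A zero-variance ZRF makes
#' the correlation undefined; such pairs are reported unsieved with
#' `undefined_pccd = TRUE`.
#'
#' @param sig_q,sig_r `sieve_signature` objects for query and reference
#'   (built against the same calibration table).
#' @return A one-row data.frame with columns `query_id`, `ref_id`, `pccd`,
#'   `gsc_p`, `sieved`, `rescued`, `undefined_pccd`.
#' @export
decide_pair <- function(sig_q, sig_r) {
  stopifnot(inherits(sig_q, "sieve_signature"),
            inherits(sig_r, "sieve_signature"))
  gsc_p <- min(sig_q$gsc, sig_r$gsc)
  r <- tryCatch(pccd(sig_q$zrf, sig_r$zrf), error = function(e) NA_real_)
  data.frame(
    query_id = sig_q$genome_id,
    ref_id = sig_r$genome_id,
    pccd = r,
    gsc_p = gsc_p,
    sieved = !is.na(r) && r >= gsc_p,
    rescued = FALSE,
    undefined_pccd = is.na(r)
  )
}

#' Rescue the top-N references for a query that sieved nothing
#'
#' Queries for which no reference passes the pair cutoff would otherwise
#' be lost to downstream species demarcation; the `n` references with the
#' highest PCCD to the query (default 100) are "roughly sieved" instead.
#' If fewer than `n` references exist, all are returned. Ordering is
#' descending by PCCD with ties broken by reference id (lexicographic) so
#' the result is deterministic.
#'
#' @param query A `sieve_signature`.
#' @param refs List of `sieve_signature` objects.
#' @param n Number of references to rescue (default 100).
#' @return A data.frame of rescue records (`rescued = TRUE`), possibly
#'   empty.
#' @export
rescue <- function(query, refs, n = 100) {
  if (length(refs) == 0L || n <= 0) {
    return(.empty_records())
  }
  ids <- vapply(refs, function(s) s$genome_id, character(1))
  rs <- vapply(refs, function(s) {
    tryCatch(pccd(query$zrf, s$zrf), error = function(e) NA_real_)
  }, numeric(1))
  ord <- order(-rs, ids, na.last = TRUE)
  take <- ord[seq_len(min(n, length(refs)))]
  data.frame(
    query_id = query$genome_id,
    ref_id = ids[take],
    pccd = rs[take],
    gsc_p = pmin(query$gsc, vapply(refs[take], function(s) s$gsc, numeric(1))),
    sieved = TRUE,
    rescued = TRUE,
    undefined_pccd = is.na(rs[take])
  )
}

.empty_records <- function() {
  data.frame(
    query_id = character(0), ref_id = character(0), pccd = numeric(0),
    gsc_p = numeric(0), sieved = logical(0), rescued = logical(0),
    undefined_pccd = logical(0)
  )
}

#' Sieve all query x reference pairs
#'
#' Computes all pairwise PCCDs between query and reference ZRFs, applies
#' the pair-cutoff rule, rescues queries with zero passing references, and
#' returns the sieved records together with summary totals. Pairs between
#' identical ids (self-pairs, relevant when queries and references are the
#' same set) are excluded.
#'
#' The implementation computes the full correlation matrix at once (memory
#' is O(queries x references) doubles); the result is identical to
#' evaluating [decide_pair()] sequentially over all non-self pairs.
#'
#' @param queries,refs Lists of `sieve_signature` objects; ids must be
#'   unique within each list.
#' @param n_rescue Rescue size (default 100; 0 disables rescue, in which
#'   case a query may end with zero records and a warning is emitted).
#' @return A list of class `sieve_result` with elements `records` (one row
#'   per sieved or rescued pair) and `summary` (totals: queries,
#'   references, pairs evaluated, pairs sieved, queries rescued).
#' @export
sieve_all <- function(queries, refs, n_rescue = 100) {
  qid <- vapply(queries, function(s) s$genome_id, character(1))
  rid <- vapply(refs, function(s) s$genome_id, character(1))
  if (anyDuplicated(qid) || anyDuplicated(rid)) {
    .sieve_error("tetrasieve_input_error",
                 "duplicate genome ids within a query or reference set")
  }
  qm <- vapply(queries, function(s) as.numeric(s$zrf), numeric(136))
  rm_ <- vapply(refs, function(s) as.numeric(s$zrf), numeric(136))
  qg <- vapply(queries, function(s) s$gsc, numeric(1))
  rg <- vapply(refs, function(s) s$gsc, numeric(1))

  pcc <- suppressWarnings(stats::cor(qm, rm_))  # nq x nr; NA on zero variance
  gscp <- outer(qg, rg, pmin)
  self <- outer(qid, rid, `==`)
  sieved <- !is.na(pcc) & pcc >= gscp & !self

  rec_list <- vector("list", length(queries))
  n_rescued_queries <- 0L
  for (i in seq_along(queries)) {
    hit <- which(sieved[i, ])
    if (length(hit) > 0L) {
      rec_list[[i]] <- data.frame(
        query_id = qid[i], ref_id = rid[hit], pccd = pcc[i, hit],
        gsc_p = gscp[i, hit], sieved = TRUE, rescued = FALSE,
        undefined_pccd = FALSE
      )
    } else if (n_rescue > 0L) {
      cand <- which(!self[i, ])
      if (length(cand) > 0L) {
        ord <- cand[order(-pcc[i, cand], rid[cand], na.last = TRUE)]
        take <- ord[seq_len(min(n_rescue, length(ord)))]
        rec_list[[i]] <- data.frame(
          query_id = qid[i], ref_id = rid[take], pccd = pcc[i, take],
          gsc_p = gscp[i, take], sieved = TRUE, rescued = TRUE,
          undefined_pccd = is.na(pcc[i, take])
        )
        n_rescued_queries <- n_rescued_queries + 1L
      }
    } else {
      warning(sprintf("query '%s' sieved no references and rescue is disabled",
                      qid[i]))
    }
  }
  records <- do.call(rbind, c(list(.empty_records()), rec_list))
  rownames(records) <- NULL
  structure(
    list(
      records = records,
      summary = list(
        n_queries = length(queries),
        n_refs = length(refs),
        pairs_evaluated = sum(!self),
        pairs_sieved = sum(sieved),
        queries_rescued = n_rescued_queries,
        n_records = nrow(records)
      )
    ),
    class = "sieve_result"
  )
}

#' @export
print.sieve_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<sieve_result> %d x %d genomes, %s pairs evaluated, ",
           "%s sieved (%.3f%%), %d queries rescued\n"),
    s$n_queries, s$n_refs,
    format(s$pairs_evaluated, big.mark = ","),
    format(s$pairs_sieved, big.mark = ","),
    100 * s$pairs_sieved / max(s$pairs_evaluated, 1),
    s$queries_rescued
  ))
  invisible(x)
}
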