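# Independent, deliberately naive oracles used to check the package's
# vectorized implementations. Everything here works character by
# character / position by position and shares no code with R/.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# double-stranded k-mer counts by sliding a window over both strands
oracle_count_kmers <- function(s, k) {
  words <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[k:1],
                      1, paste, collapse = ""))
  counts <- stats::setNames(rep(0, length(words)), words)
  for (strand in c(s, oracle_revcomp(s))) {
    chars <- strsplit(strand, "")[[1]]
    if (length(chars) < k) next
    for (i in 1:(length(chars) - k + 1)) {
      w <- paste(chars[i:(i + k - 1)], collapse = "")
      if (w %in% words) counts[w] <- counts[w] + 1
    }
  }
  counts
}

# literal transcription of the z-value formulas, one word at a time
oracle_zvalues <- function(s) {
  n4 <- oracle_count_kmers(s, 4)
  n3 <- oracle_count_kmers(s, 3)
  n2 <- oracle_count_kmers(s, 2)
  canon <- sort(unique(pmin(names(n4), sapply(names(n4), oracle_revcomp))))
  z <- stats::setNames(numeric(length(canon)), canon)
  for (w in canon) {
    pre <- substr(w, 1, 3)
    suf <- substr(w, 2, 4)
    mid <- substr(w, 2, 3)
    if (n2[mid] == 0) next
    e <- n3[pre] * n3[suf] / n2[mid]
    v <- e * (1 - n3[pre] / n2[mid]) * (1 - n3[suf] / n2[mid])
    if (v <= 0) next
    z[w] <- (n4[w] - e) / sqrt(v)
  }
  z
}

# textbook covariance / standard deviation Pearson correlation
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  cov <- sum((a - ma) * (b - mb)) / (n - 1)
  cov / (sqrt(sum((a - ma)^2) / (n - 1)) * sqrt(sum((b - mb)^2) / (n - 1)))
}

# per-tetranucleotide sort-and-average of central fragment z-values
oracle_zrf <- function(zmat) {
  n <- ncol(zmat)
  out <- numeric(nrow(zmat))
  for (i in seq_len(nrow(zmat))) {
    v <- sort(zmat[i, ])
    out[i] <- if (n == 1) {
      v
    } else if (n == 2) {
      mean(v)
    } else if (n %% 2 == 1) {
      mean(v[((n + 1) / 2 - 1):((n + 1) / 2 + 1)])
    } else {
      mean(v[(n / 2 - 1):(n / 2 + 2)])
    }
  }
  out
}

# explicit summation of the reference-based identity formula
oracle_ani <- function(alignments) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(alignments))) {
    stretch <- alignments$ref_end[i] - alignments$ref_start[i] + 1
    neg <- sum(alignments$digits[[i]] < 0)
    num <- num + stretch + neg - alignments$n_errors[i]
    den <- den + stretch + neg
  }
  100 * num / den
}

# position-by-position coverage flags, then a ratio
oracle_psg <- function(alignments, L1, L2) {
  qcov <- logical(L1)
  rcov <- logical(L2)
  for (i in seq_len(nrow(alignments))) {
    qs <- min(alignments$q_start[i], alignments$q_end[i])
    qe <- max(alignments$q_start[i], alignments$q_end[i])
    rs <- min(alignments$ref_start[i], alignments$ref_end[i])
    re <- max(alignments$ref_start[i], alignments$ref_end[i])
    qcov[qs:qe] <- TRUE
    rcov[rs:re] <- TRUE
  }
  100 * (sum(qcov) + sum(rcov)) / (L1 + L2)
}

# per-k-mer summation score of a sequence under an add-one 3rd-order
# Markov model trained on the training sequences (counts summed per
# sequence, no junction windows)
oracle_bayes_score <- function(train, s) {
  n4 <- Reduce(`+`, lapply(train, oracle_count_kmers_onestrand, k = 4))
  chars <- strsplit(s, "")[[1]]
  total <- 0
  nwin <- 0
  for (i in 1:(length(chars) - 3)) {
    w <- paste(chars[i:(i + 3)], collapse = "")
    pre_words <- paste0(substr(w, 1, 3), c("A", "C", "G", "T"))
    total <- total + log((n4[w] + 1) / (sum(n4[pre_words]) + 4))
    nwin <- nwin + 1
  }
  total / nwin
}

oracle_count_kmers_onestrand <- function(s, k) {
  words <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[k:1],
                      1, paste, collapse = ""))
  counts <- stats::setNames(rep(0, length(words)), words)
  chars <- strsplit(s, "")[[1]]
  for (i in 1:(length(chars) - k + 1)) {
    w <- paste(chars[i:(i + k - 1)], collapse = "")
    if (w %in% words) counts[w] <- counts[w] + 1
  }
  counts
}

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# small flat calibration table for tests that only need plumbing
toy_table <- function(mean_intra = 0.9, sd_intra = 0.01,
                      bins = seq(10, 200, 10)) {
  data.frame(kb = bins, mean_intra = mean_intra, sd_intra = sd_intra,
             n_samples = 100)
}

# hand-built signature object for sieve-engine tests
make_sig <- function(id, zrf, gsc, lsc1 = gsc - 0.1, lsc2 = gsc - 0.2) {
  structure(
    list(genome_id = id, zrf = zrf, gsc = gsc, gsc_raw = gsc,
         lsc1 = lsc1, lsc2 = lsc2, restricted_by_lsc1 = FALSE,
         refragmented_10kb = FALSE, n_fragments = 1, L_bp = 100000),
    class = "sieve_signature"
  )
}
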