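test_that("simulate_genome is deterministic and leaves the RNG alone", {
  g1 <- simulate_genome(20000, 2, seed = 601, id = "a")
  g2 <- simulate_genome(20000, 2, seed = 601, id = "a")
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  g3 <- simulate_genome(20000, 2, seed = 602, id = "a")
  expect_false(identical(as.character(g1$seqs), as.character(g3$seqs)))

  set.seed(1); before <- stats::runif(5)
  set.seed(1); invisible(simulate_genome(20000, 2, seed = 603))
  expect_identical(stats::runif(5), before)

  expect_error(simulate_genome(5000, 1), class = "tetrasieve_input_error")
  expect_error(simulate_genome(20000, 0), class = "tetrasieve_input_error")
})

test_that("single-component genomes have tightly clustered fragment PCCDs", {
  # 20 replicates at 1 Mb: intragenomic fragment-vs-ZRF PCCD SD < 0.05
  sds <- vapply(1:20, function(i) {
    g <- simulate_genome(1e6, 1, seed = 700 + i, id = paste0("h", i))
    w <- divide_genome(g)
    zm <- tetrasieve:::.fragment_zmatrix(g$seqs[[1]], w)
    zrf <- compute_zrf(zm)
    stats::sd(vapply(seq_len(ncol(zm)), function(j) pccd(zm[, j], zrf),
                     numeric(1)))
  }, numeric(1))
  expect_true(all(sds < 0.05))
})

test_that("strongly separated components reach the 10-kb re-fragmenting path", {
  tab <- default_calibration()
  hits <- vapply(1:20, function(i) {
    g <- simulate_genome(5e5, 4, seed = 730 + i, block_len_bp = 6e4,
                         alpha = 0.2, id = paste0("c", i))
    build_signature(g, tab)$refragmented_10kb
  }, logical(1))
  expect_gte(sum(hits), 1)
})

test_that("extract_pair realizes the target PSG from coordinates", {
  g <- simulate_genome(100000, 2, seed = 610, id = "parent")

  whole <- extract_pair(g, 100, 100, 100, seed = 1)
  expect_equal(whole$realized_psg_pct, 100)
  expect_identical(as.character(whole$query$seqs[[1]]),
                   as.character(g$seqs[[1]]))
  expect_identical(as.character(whole$ref$seqs[[1]]),
                   as.character(g$seqs[[1]]))

  # PSG 70% is only feasible up to ~76.9% completeness: two full-length
  # extracts of one parent necessarily coincide completely
  expect_error(extract_pair(g, 70, 100, 100, seed = 2),
               class = "tetrasieve_infeasible_pair")
  p70 <- extract_pair(g, 70, 70, 70, seed = 2)
  expect_equal(p70$coords$overlap_bp, 49000)
  expect_equal(p70$realized_psg_pct, 70)

  tight <- extract_pair(g, 90, 10, 10, seed = 3)
  expect_lte(abs(tight$realized_psg_pct - 90), 0.5)
  expect_equal(tight$coords$q_len, 10000)

  # infeasible: low PSG with full completeness cannot fit in the parent
  expect_error(extract_pair(g, 10, 100, 100),
               class = "tetrasieve_infeasible_pair")
  expect_error(extract_pair(g, 150, 50, 50),
               class = "tetrasieve_input_error")
})

test_that("realized PSG equals the alignment-based value exactly", {
  # cross-module consistency: coordinate arithmetic vs interval-union PSG
  g <- simulate_genome(50000, 3, seed = 620, id = "xmod")
  for (p in c(70, 80, 90, 100)) {
    for (cc in c(20, 50, min(100, floor(100 / (2 - p / 100))))) {
      pr <- extract_pair(g, p, cc, cc)
      a <- pair_alignment(pr)
      expect_identical(psg(a, pr$coords$q_len, pr$coords$r_len),
                       pr$realized_psg_pct)
    }
  }
  # and the written delta file round-trips to the same value
  pr <- extract_pair(g, 80, 50, 50, seed = 4)
  f <- withr::local_tempfile(fileext = ".delta")
  write_delta(pair_alignment(pr), f)
  expect_equal(psg(parse_delta(f), pr$coords$q_len, pr$coords$r_len),
               pr$realized_psg_pct)
  expect_equal(ani(parse_delta(f)), 100)  # perfect synthetic alignment
})

test_that("benchmark_metrics computes the confusion ratios", {
  truth <- data.frame(
    query_id = c("a", "b", "c", "d", "x"),
    ref_id = c("a2", "b2", "c2", "d2", "y"),
    label = c(rep("intraspecific", 4), "interspecific")
  )
  recs <- data.frame(query_id = c("a", "b", "c"),
                     ref_id = c("a2", "b2", "c2"))
  m <- benchmark_metrics(recs, truth)
  expect_equal(m$sensitivity_pct, 75)            # 3 of 4 intraspecific
  expect_equal(m$specificity_pct, 100)

  perfect <- benchmark_metrics(truth[1:4, c("query_id", "ref_id")], truth)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)

  # permutation invariance in pair order
  m2 <- benchmark_metrics(recs[3:1, ], truth[sample(5), ])
  expect_equal(m2$sensitivity_pct, m$sensitivity_pct)
  expect_equal(m2$specificity_pct, m$specificity_pct)

  expect_error(benchmark_metrics(data.frame(query_id = "zz", ref_id = "zz"),
                                 truth),
               class = "tetrasieve_input_error")
  expect_error(benchmark_metrics(recs, truth[c(1, 1, 2), ]),
               class = "tetrasieve_input_error")
})

test_that("a small seeded benchmark agrees with the confusion-matrix oracle", {
  bench <- simulate_benchmark(
    n_parents = 20, genome_length_bp = 5e4, psg_levels = 70,
    completeness_levels = 20, n_calibration_genomes = 2,
    n_pairs_per_bin = 20, seed = 630
  )
  # 20 intraspecific pairs, 380 interspecific pairs
  expect_equal(bench$metrics$n_intra, 20)
  expect_equal(bench$metrics$n_inter, 380)

  # independent recount from the records and an exhaustive truth table
  truth <- expand.grid(
    query_id = bench$pairs$query_id, ref_id = bench$pairs$ref_id,
    stringsAsFactors = FALSE
  )
  truth$label <- ifelse(
    sub("_q$", "", truth$query_id) == sub("_r$", "", truth$ref_id),
    "intraspecific", "interspecific"
  )
  m <- benchmark_metrics(bench$result$records, truth)
  expect_equal(m$sensitivity_pct, bench$metrics$sensitivity_pct)
  expect_equal(m$specificity_pct, bench$metrics$specificity_pct)
  expect_equal(m$n_intra_sieved, bench$metrics$n_intra_sieved)
  expect_equal(m$n_inter_sieved, bench$metrics$n_inter_sieved)

  # rerunning with the same seed reproduces the records exactly
  bench2 <- simulate_benchmark(
    n_parents = 20, genome_length_bp = 5e4, psg_levels = 70,
    completeness_levels = 20, n_calibration_genomes = 2,
    n_pairs_per_bin = 20, seed = 630
  )
  expect_identical(bench$result$records, bench2$result$records)
})
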