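test_that("divide_genome reproduces the published window rules", {
  w30 <- divide_genome(L_bp = 30000, avg_seq_size_bp = 30000)
  expect_equal(nrow(w30), 1)
  expect_equal(unlist(w30[1, ], use.names = FALSE), c(0, 30000))

  w400 <- divide_genome(L_bp = 400000, avg_seq_size_bp = 400000)
  expect_equal(attr(w400, "l_bp"), 100000)
  expect_equal(nrow(w400), 8)
  expect_equal(unlist(w400[8, ], use.names = FALSE), c(350000, 400000))

  # > 800 kb with large contigs keeps 8 fragments (l = L/4)
  wbig <- divide_genome(L_bp = 1200000, avg_seq_size_bp = 300000)
  expect_equal(attr(wbig, "l_bp"), 300000)
  expect_equal(nrow(wbig), 8)

  # > 800 kb with small contigs falls back to l = 200 kb
  wfrag <- divide_genome(L_bp = 1200000, avg_seq_size_bp = 50000)
  expect_equal(attr(wfrag, "l_bp"), 200000)
  expect_equal(nrow(wfrag), 12)
  expect_equal(wfrag$end[12] - wfrag$start[12], 100000)  # truncated final

  expect_error(divide_genome(L_bp = 9999, avg_seq_size_bp = 9999),
               class = "tetrasieve_short_genome")
})

test_that("window geometry holds across random lengths", {
  set.seed(21)
  for (L in sample(40000:800000, 50)) {
    w <- divide_genome(L_bp = L, avg_seq_size_bp = L)
    l <- attr(w, "l_bp")
    expect_equal(nrow(w), 8)
    # consecutive windows overlap by 0.5 l (within integer rounding)
    expect_true(all(abs(diff(w$start) - l / 2) <= 1))
    expect_true(all(w$end - w$start >= l / 2 - 1))
    expect_equal(w$start[1], 0)
    expect_equal(w$end[8], L)
  }
  for (L in sample(800001:5000000, 10)) {
    expect_equal(nrow(divide_genome(L_bp = L, avg_seq_size_bp = 250000)), 8)
  }
})

test_that("compute_zrf averages the central fragment z-values", {
  set.seed(22)
  # 8 fragments: the mean of sorted ranks 3-6, per tetranucleotide
  zmat <- matrix(stats::rnorm(136 * 8), nrow = 136,
                 dimnames = list(canonical_tetranucleotides(), NULL))
  zrf <- compute_zrf(zmat)
  expect_equal(as.numeric(zrf), oracle_zrf(zmat))
  expect_equal(as.numeric(zrf),
               unname(apply(zmat, 1, function(v) mean(sort(v)[3:6]))))

  # 7 fragments with values {0..6} per row -> central three -> 3.0
  z7 <- matrix(rep(0:6, each = 136), nrow = 136)
  expect_equal(as.numeric(compute_zrf(z7)), rep(3, 136))

  one <- matrix(stats::rnorm(136), ncol = 1)
  expect_equal(as.numeric(compute_zrf(one)), as.numeric(one))
  two <- matrix(stats::rnorm(272), ncol = 2)
  expect_equal(as.numeric(compute_zrf(two)), rowMeans(two))

  # odd counts and range containment, against the loop oracle
  for (n in c(3, 5, 9, 12)) {
    m <- matrix(stats::rnorm(136 * n), nrow = 136)
    got <- as.numeric(compute_zrf(m))
    expect_equal(got, oracle_zrf(m))
    expect_true(all(got >= apply(m, 1, min) & got <= apply(m, 1, max)))
  }
  expect_error(compute_zrf(list()), class = "tetrasieve_input_error")
})

test_that("compute_gsc implements both cutoff rules", {
  expect_equal(compute_gsc(c(0.95, 0.95, 0.95)), 0.94)
  expect_equal(compute_gsc(c(0.98, 0.96)),
               mean(c(0.98, 0.96)) - stats::sd(c(0.98, 0.96)) - 0.01,
               tolerance = 1e-12)
  expect_equal(compute_gsc(c(0.98, 0.96)), 0.9458578644, tolerance = 1e-9)
  expect_equal(compute_gsc(c(0.98, 0.96), mode = "legacy"),
               0.9417157288, tolerance = 1e-9)
  expect_equal(compute_gsc(0.97), 0.96)  # single fragment: SD = 0
  expect_error(compute_gsc(numeric(0)), class = "tetrasieve_input_error")
})

test_that("lsc_values caps at 200 kb and snaps to the nearest bin", {
  tab <- toy_table(mean_intra = 0.97, sd_intra = 0.01, bins = c(100, 200))
  got <- lsc_values(100000, tab)
  expect_equal(got$lsc1, 0.95)
  expect_equal(got$lsc2, 0.95)
  expect_equal(lsc_values(5e6, tab)$kb, 200)       # capped
  expect_equal(lsc_values(120000, tab)$kb, 100)    # nearest bin
  expect_equal(lsc_values(160000, tab)$kb, 200)
})

test_that("build_signature pipeline, flags and invariants", {
  set.seed(23)
  # homogeneous blend: no restriction, no re-fragmenting under a
  # permissive table
  g <- simulate_genome(3e5, n_components = 3, seed = 301, id = "homog")
  lax <- toy_table(mean_intra = 0.8, sd_intra = 0.05)
  s <- build_signature(g, lax)
  expect_s3_class(s, "sieve_signature")
  expect_false(s$restricted_by_lsc1)
  expect_false(s$refragmented_10kb)
  expect_equal(s$n_fragments, 8)
  expect_equal(s$gsc, s$gsc_raw)

  # a strict table floors the GSC at LSC1 and triggers 10-kb windows
  strict <- toy_table(mean_intra = 0.9999, sd_intra = 1e-5)
  s2 <- build_signature(g, strict)
  expect_true(s2$restricted_by_lsc1)
  expect_true(s2$refragmented_10kb)
  expect_equal(s2$gsc, 0.9999 - 1e-5 - 0.01)       # forced to LSC1
  expect_gte(s2$gsc, s2$lsc1)                       # post-restriction invariant
  expect_equal(s2$n_fragments, nrow(divide_genome(g, l_bp = 10000)))
  # re-fragmenting updates the ZRF, not the GSC
  expect_false(isTRUE(all.equal(s2$zrf, s$zrf)))
  expect_equal(s2$gsc_raw, s$gsc_raw)

  # chimeric genome with large, strongly separated blocks crosses LSC2
  chi <- simulate_genome(4e5, n_components = 2, seed = 302,
                         block_len_bp = 1e5, alpha = 0.2, id = "chimera")
  tab <- toy_table(mean_intra = 0.99, sd_intra = 0.002)
  s3 <- build_signature(chi, tab)
  expect_true(s3$refragmented_10kb)
  expect_lte(s3$gsc_raw, s3$lsc2)
})

test_that("ZRF is strand-symmetric for single-window genomes", {
  # below 40 kb the whole genome is the single representative fragment,
  # so exact strand symmetry of z-values carries over to the ZRF
  set.seed(24)
  s <- random_seq(30000)
  tab <- toy_table()
  sig_f <- build_signature(genome(c(x = s), id = "f"), tab)
  sig_r <- build_signature(genome(c(x = oracle_revcomp(s)), id = "r"), tab)
  expect_identical(as.numeric(sig_f$zrf), as.numeric(sig_r$zrf))
  expect_identical(sig_f$gsc, sig_r$gsc)
})

test_that("signature caches round-trip through TSV", {
  set.seed(25)
  tab <- toy_table()
  sigs <- lapply(1:2, function(i) {
    build_signature(simulate_genome(5e4, 2, seed = 400 + i,
                                    id = paste0("g", i)), tab)
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  save_signatures(sigs, f)
  back <- load_signatures(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$genome_id, sigs[[1]]$genome_id)
  expect_equal(back[[2]]$zrf, sigs[[2]]$zrf, tolerance = 1e-6)
  expect_equal(back[[1]]$gsc, sigs[[1]]$gsc, tolerance = 1e-9)
  expect_identical(back[[1]]$refragmented_10kb, sigs[[1]]$refragmented_10kb)
})
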