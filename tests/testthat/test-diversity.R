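test_that("nucleotide diversity matches direct pair counting", {
  # all identical
  expect_equal(nucleotide_diversity(matrix(0L, 4, 3)), 0)
  # n=4, alleles A,A,T,T at one called site: 4 of 6 pairs differ
  expect_equal(nucleotide_diversity(matrix(c(0L, 0L, 1L, 1L), 4, 1)), 4 / 6)
  # n=2 differing at 1 of 100 called sites
  expect_equal(nucleotide_diversity(matrix(c(0L, 1L), 2, 1), n_called = 100),
               0.01)
  expect_error(nucleotide_diversity(matrix(0L, 2, 0), n_called = 0), "zero")
  # multiallelic general form agrees with the oracle
  set.seed(3)
  m <- random_calls(6, 20, k_alleles = 3L)
  expect_equal(nucleotide_diversity(m), oracle_pi(m), tolerance = 1e-12)
})

test_that("Tajima's D sign follows the frequency spectrum and S=0 is undefined", {
  expect_true(is.na(tajimas_d(matrix(0L, 4, 5))))
  singletons <- rbind(c(1L, 1L, 1L), matrix(0L, 3, 3))   # 3 singleton SNPs
  expect_lt(tajimas_d(singletons), 0)
  balanced <- rbind(matrix(1L, 2, 3), matrix(0L, 2, 3))  # 3 SNPs split 2/2
  expect_gt(tajimas_d(balanced), 0)
  expect_equal(tajimas_d(singletons), oracle_tajimas_d(singletons),
               tolerance = 1e-12)
})

test_that("pi is invariant under sample reordering and allele relabeling", {
  set.seed(11)
  for (k in 1:10) {
    m <- random_calls(5, 15, k_alleles = 3L)
    expect_equal(nucleotide_diversity(m[sample(5), ]),
                 nucleotide_diversity(m))
    relab <- matrix(c(2L, 0L, 1L)[m + 1L], nrow(m), ncol(m))
    expect_equal(nucleotide_diversity(relab), nucleotide_diversity(m))
  }
})

test_that("window scans tile chromosomes and localize diversity", {
  # 100 kb at 20 kb / 4 kb: 21 windows starting 0, 4k, ..., 80k
  set.seed(5)
  pos <- sort(sample(0:99999, 300))
  calls <- random_calls(8, 300)
  am <- toy_analysis_matrix(calls, pos, L = 100000L)
  w <- window_scan(am, 20000L, 4000L)
  expect_equal(nrow(w), 21L)
  expect_equal(w$start, seq(0L, 80000L, by = 4000L))
  expect_equal(unique(w$end - w$start), 20000L)

  # non-overlapping windows partition the SNPs
  w2 <- window_scan(am, 20000L, 20000L)
  expect_equal(sum(w2$n_snps), ncol(calls))
  expect_equal(sum(w2$n_called), 100000)

  # an injected monomorphic block zeroes the windows inside it
  calls2 <- calls
  calls2[, pos >= 40000 & pos < 70000] <- 0L
  am2 <- toy_analysis_matrix(calls2, pos, L = 100000L)
  w3 <- window_scan(am2, 20000L, 4000L)
  inside <- w3$start >= 40000 & w3$end <= 70000
  expect_true(all(w3$pi[inside] == 0))
  expect_true(all(w3$pi[!inside] > 0))
})

test_that("the folded spectrum bins by minor-allele count and collapses groups", {
  # all singletons
  calls <- cbind(diag(1L, 6, 3), matrix(0L, 6, 0))
  am <- toy_analysis_matrix(calls, pos = c(10L, 20L, 30L), L = 1000L)
  sp <- minor_allele_spectrum(am)
  expect_equal(unname(sp$counts), c(3L, 0L, 0L))

  # a 5/27 split lands in bin 5
  g <- c(rep(1L, 5), rep(0L, 27))
  am2 <- toy_analysis_matrix(matrix(g, 32, 1), pos = 10L, L = 1000L)
  sp2 <- minor_allele_spectrum(am2)
  expect_equal(unname(sp2$counts[5L]), 1L)
  expect_equal(sum(sp2$counts), 1L)

  # collapsing a clade removes its private variation
  clade <- 1:5
  calls3 <- cbind(matrix(c(rep(1L, 5), rep(0L, 27)), 32, 1),  # clade-fixed
                  matrix(c(1L, rep(0L, 31)), 32, 1),          # clade-private
                  matrix(c(rep(0L, 10), 1L, 1L, rep(0L, 20)), 32, 1))
  am3 <- toy_analysis_matrix(calls3, pos = c(10L, 20L, 30L), L = 1000L)
  sp3 <- minor_allele_spectrum(am3, collapse_group = clade)
  expect_equal(sp3$n, 28L)
  expect_equal(sum(sp3$counts), 2L)    # clade-private site dropped
  expect_equal(unname(sp3$counts[1L]), 1L)  # clade-fixed becomes a singleton
  expect_equal(unname(sp3$counts[2L]), 1L)
})

test_that("between-group divergence counts cross-group mismatches per site", {
  # one fixed difference between groups over 100 called sites
  calls <- matrix(c(rep(1L, 4), rep(0L, 4)), 8, 1)
  am <- toy_analysis_matrix(calls, pos = 50L, L = 100L)
  w <- group_divergence(am, 1:4, 5:8, size = 100L, step = 100L)
  expect_equal(w$dxy, 0.01)
  expect_equal(w$pi_b, 0)

  # equal groups on a polymorphic site: dxy reflects the cross-pair fraction
  calls2 <- matrix(c(0L, 1L, 0L, 1L), 4, 1)
  am2 <- toy_analysis_matrix(calls2, pos = 0L, L = 1L)
  w2 <- group_divergence(am2, c(1L, 3L), c(2L, 4L), size = 1L, step = 1L)
  expect_equal(w2$dxy, 1)    # every cross pair differs
  expect_error(group_divergence(am2, 1:2, 2:3, 10L, 10L), "disjoint")
  expect_error(group_divergence(am2, integer(0), 3:4, 10L, 10L), "empty")
})

test_that("an injected divergent segment dominates the fine-scale dxy scan", {
  set.seed(21)
  cfg <- sim_config(n = 16L, chrom_lengths = c(chr1 = 50000L), theta = 0.003,
                    seed = 77L)
  sim <- simulate_population(cfg)
  sim$matrix <- inject_divergent_segment(sim$matrix, clade = 1:4,
                                         interval = list("chr1", 30000L, 31000L),
                                         divergence = 0.05,
                                         reference = sim$reference, seed = 78L)
  am <- as_analysis_matrix(sim)
  w <- group_divergence(am, 1:4, 5:16, size = 200L, step = 40L)
  top <- w[which.max(w$dxy), ]
  expect_lt(top$start, 31000)
  expect_gt(top$end, 30000)
  expect_gt(top$dxy, 0.04)
})
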