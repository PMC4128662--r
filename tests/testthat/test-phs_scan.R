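linear_map <- function(L, cm_per_bp = 1e-4, chrom = "chr1") {
  mk <- data.frame(chrom = chrom,
                   bp = seq(0L, L, length.out = 6L),
                   cM = cm_per_bp * seq(0L, L, length.out = 6L))
  fit_genetic_map(mk)
}

test_that("genetic map fitting reproduces linear and interpolating cases", {
  # markers on an exact line
  mk <- data.frame(chrom = "chr1", bp = c(0, 2e4, 5e4, 7e4, 9e4, 1e5),
                   cM = 2e-4 * c(0, 2e4, 5e4, 7e4, 9e4, 1e5))
  map <- fit_genetic_map(mk)
  expect_lt(max(abs(map_position(map, "chr1", mk$bp) - mk$cM)), 1e-9)

  # exactly 5 markers: the quartic interpolates them
  mk5 <- data.frame(chrom = "chr1", bp = c(0, 1e4, 3e4, 6e4, 1e5),
                    cM = c(0, 2, 7, 13, 20))
  map5 <- fit_genetic_map(mk5)
  expect_false(map5$chr1$repaired)
  expect_lt(max(abs(map_position(map5, "chr1", mk5$bp) - mk5$cM)), 1e-6)

  # clamping outside the marker range
  expect_equal(map_position(map, "chr1", -5000), map_position(map, "chr1", 0))
  expect_equal(map_position(map, "chr1", 2e5), map_position(map, "chr1", 1e5))

  # a non-monotone fit is repaired to its running maximum
  set.seed(2)
  mkbad <- data.frame(chrom = "chr1", bp = seq(0, 1e5, length.out = 12),
                      cM = c(0, 8, 2, 9, 3, 10, 4, 12, 5, 14, 15, 16))
  mapbad <- fit_genetic_map(mkbad)
  g <- map_position(mapbad, "chr1", seq(0, 1e5, by = 500))
  expect_true(all(diff(g) >= -1e-9))

  expect_error(fit_genetic_map(data.frame(chrom = "c", bp = 1:4, cM = 1:4)),
               "at least 5")
})

test_that("identity tracts follow the boundary and missing-cluster conventions", {
  calls <- rbind(a = c(0L, 0L, 1L, 0L),
                 b = c(0L, 1L, 0L, 0L))
  am <- toy_analysis_matrix(calls, pos = c(50L, 100L, 200L, 300L), L = 1000L,
                            samples = c("a", "b"))
  map <- linear_map(1000L)
  tr <- pairwise_identity_tracts(am, c("a", "b"), map)
  # discordances at 100 and 200: tracts (0,100), (100,200), (200,1000)
  expect_equal(tr$start, c(0, 100, 200))
  expect_equal(tr$end, c(100, 200, 1000))
  expect_equal(tr$genetic_length,
               map_position(map, "chr1", tr$end) -
                 map_position(map, "chr1", tr$start))

  # an identical pair spans the chromosome in one tract
  am2 <- toy_analysis_matrix(rbind(c(0L, 1L), c(0L, 1L)),
                             pos = c(10L, 20L), L = 1000L,
                             samples = c("a", "b"))
  tr2 <- pairwise_identity_tracts(am2, 1:2, linear_map(1000L))
  expect_equal(nrow(tr2), 1L)
  expect_equal(c(tr2$start, tr2$end), c(0, 1000))

  # a >= 30 kb stretch with no called sites terminates tracts at its edges
  am3 <- toy_analysis_matrix(rbind(c(0L, 1L), c(0L, 1L)),
                             pos = c(1000L, 40000L), L = 50000L,
                             samples = c("a", "b"))
  am3$callable <- list(chr1 = data.frame(start = c(0L, 38000L),
                                         end = c(3000L, 50000L)))
  tr3 <- pairwise_identity_tracts(am3, 1:2, linear_map(50000L))
  expect_equal(tr3$start, c(0, 38000))
  expect_equal(tr3$end, c(2999, 50000))
})

test_that("tract moments use the population SD and flag degenerate pairs", {
  m <- pair_tract_moments(c(1, 3))
  expect_equal(c(m$mean, m$sd), c(2, 1))
  expect_false(m$flagged)
  expect_true(pair_tract_moments(c(5))$flagged)
  expect_true(pair_tract_moments(c(2, 2, 2))$flagged)   # clone pair
})

test_that("the PHS statistic matches hand arithmetic on a 4-sample case", {
  # samples a,b carry the allele and share a long identical haplotype;
  # c,d break up everywhere
  calls <- rbind(a = c(1L, 1L, 1L, 1L, 1L, 0L),
                 b = c(0L, 1L, 1L, 1L, 0L, 1L),
                 c = c(1L, 0L, 1L, 0L, 1L, 1L),
                 d = c(0L, 1L, 1L, 0L, 0L, 0L))
  pos <- c(100L, 200L, 300L, 400L, 500L, 600L)
  am <- toy_analysis_matrix(calls, pos, L = 1000L)
  map <- linear_map(1000L, cm_per_bp = 0.01)
  x <- 300L
  phs <- phs_statistic("chr1", x, allele = 1L, am = am, map = map)
  expect_equal(phs, oracle_phs(am, map, "chr1", x, 1L), tolerance = 1e-10)
  # carriers of allele 1 at 300 are all samples: carrier mean equals the
  # all-pair mean and PHS collapses to zero
  expect_equal(phs, 0)

  # allele shared by the coherent pair only
  phs_ab <- phs_statistic("chr1", 400L, allele = 1L, am = am, map = map)
  expect_equal(phs_ab, oracle_phs(am, map, "chr1", 400L, 1L),
               tolerance = 1e-10)
  expect_gt(phs_ab, 0)
})

test_that("PHS is invariant to constant shifts of the genetic map", {
  set.seed(17)
  cfg <- sim_config(n = 6L, chrom_lengths = c(chr1 = 20000L), theta = 0.004,
                    seed = 19L)
  sim <- simulate_population(cfg)
  am <- as_analysis_matrix(sim)
  mk <- data.frame(chrom = "chr1", bp = seq(0, 20000, length.out = 8),
                   cM = 1e-3 * seq(0, 20000, length.out = 8))
  map1 <- fit_genetic_map(mk)
  mk$cM <- mk$cM + 50
  map2 <- fit_genetic_map(mk)
  s1 <- phs_scan(am, map1)
  s2 <- phs_scan(am, map2)
  expect_equal(s1$phs, s2$phs, tolerance = 1e-8)
})

test_that("the scan equals naive per-site recomputation on small instances", {
  set.seed(23)
  for (rep in 1:3) {
    cfg <- sim_config(n = 6L, chrom_lengths = c(chr1 = 30000L), theta = 5e-4,
                      seed = 100L + rep)
    sim <- simulate_population(cfg)
    am <- as_analysis_matrix(sim)
    S <- nrow(am$sites)
    if (S < 2L || S > 50L) next
    map <- linear_map(30000L, cm_per_bp = 5e-3)
    sc <- phs_scan(am, map)
    pick <- sample(nrow(sc), min(10L, nrow(sc)))
    for (k in pick) {
      expect_equal(sc$phs[k],
                   oracle_phs(am, map, sc$chrom[k], sc$pos[k], sc$allele[k]),
                   tolerance = 1e-10)
    }
    # complement alleles at biallelic sites are both finite
    expect_true(all(is.finite(sc$phs)))
  }
})

test_that("candidate selection is frequency-conditioned and monotone in the fraction", {
  set.seed(29)
  cfg <- sim_config(n = 12L, chrom_lengths = c(chr1 = 60000L), theta = 0.005,
                    seed = 55L)
  sim <- simulate_population(cfg)
  am <- as_analysis_matrix(sim)
  map <- linear_map(60000L, cm_per_bp = 2e-3)
  s1 <- phs_scan(am, map, top_fraction = 0.001)
  s2 <- phs_scan(am, map, top_fraction = 0.01)
  expect_gte(sum(s2$candidate), sum(s1$candidate))
  # within every carrier-count class the flagged records are the top ones
  for (na in unique(s1$n_carriers)) {
    k <- s1$n_carriers == na
    if (sum(k) < 2L) next
    flagged <- s1$phs[k][s1$candidate[k]]
    expect_true(all(flagged >= max(s1$phs[k][!s1$candidate[k]])))
  }
})
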