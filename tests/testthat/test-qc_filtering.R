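`%+%` <- function(a, b) paste0(a, b)

mkread <- function(seq, qual) list(seq = seq, qual = as.integer(qual))
mkpair <- function(r1, r2 = NULL) {
  if (is.null(r2)) r2 <- mkread(strrep("GATC", 15), rep(35L, 60))
  list(r1, r2)
}

test_that("read filtering trims low-quality ends and applies length floor", {
  good <- mkread(strrep("A", 30) %+% strrep("C", 30), rep(35L, 60))
  out <- filter_reads(list(mkpair(good)))
  expect_length(out, 1L)
  expect_equal(out[[1L]][[1L]]$seq, good$seq)

  # first 5 bases below the 10-run threshold are trimmed
  r <- mkread(paste0(strrep("T", 5), strrep("A", 50), strrep("C", 50)),
              c(rep(10L, 5), rep(35L, 100)))
  out <- filter_reads(list(mkpair(r)))
  expect_equal(nchar(out[[1L]][[1L]]$seq), 100L)
  expect_equal(substr(out[[1L]][[1L]]$seq, 1L, 1L), "A")

  # a read trimmed below 45 bp removes the whole pair
  short <- mkread(paste0(strrep("A", 30), strrep("C", 14)),
                  c(rep(35L, 44), rep(2L, 0)))
  expect_length(filter_reads(list(mkpair(short))), 0L)
})

test_that("read filtering drops composition failures and dead mates", {
  nnn <- mkread(paste0(strrep("A", 20), "NNN", strrep("C", 37)), rep(35L, 60))
  expect_length(filter_reads(list(mkpair(nnn))), 0L)

  mono <- mkread(strrep("A", 60), rep(35L, 60))
  expect_length(filter_reads(list(mkpair(mono))), 0L)

  # one read the reverse complement of its mate
  fw <- mkread(paste0(strrep("A", 30), strrep("C", 30)), rep(35L, 60))
  rc <- mkread(paste0(strrep("G", 30), strrep("T", 30)), rep(35L, 60))
  expect_length(filter_reads(list(list(fw, rc))), 0L)

  # 3' region rule: from position 150 onward >= 10% of bases below 20
  r <- mkread(strrep("AC", 100), c(rep(35L, 149), rep(10L, 51)))
  out <- filter_reads(list(mkpair(r)))
  expect_equal(nchar(out[[1L]][[1L]]$seq), 149L)

  # whole-read low-quality fraction: scattered low bases survive the end
  # trimming but trip the 10% rule, removing the read (and pair)
  q <- rep(35L, 100)
  q[seq(12L, 92L, by = 8L)] <- 10L
  r <- mkread(strrep("AC", 50), q)
  expect_length(filter_reads(list(mkpair(r))), 0L)

  # adapter trimming cuts from the match to the read end
  r <- mkread(paste0(strrep("AC", 30), "GATCGGAAGAGC", strrep("T", 20)),
              rep(35L, 92))
  out <- filter_reads(list(mkpair(r)), adapters = "GATCGGAAGAGC")
  expect_equal(out[[1L]][[1L]]$seq, strrep("AC", 30))
})

test_that("call filtering masks low quality, bad depth and heterozygotes", {
  sites <- data.frame(chrom = "chr1", pos = 0:3, ref = "A", alt = "T",
                      qual = c(29, 30, 50, 50))
  calls <- matrix(1L, 2, 4, dimnames = list(c("a", "b"), NULL))
  depth <- matrix(c(20L, 20L, 10L, 20L, 9L, 20L, 20L, 20L), 2, 4)
  het <- matrix(FALSE, 2, 4); het[1L, 4L] <- TRUE
  gm <- genotype_matrix(c("a", "b"), sites, calls, depth = depth, het = het)
  out <- filter_calls(gm, min_qual = 30, min_depth = 10)
  expect_true(all(is.na(out$calls[, 1L])))      # qual 29
  expect_true(is.na(out$calls[1L, 3L]))         # depth 9
  expect_true(is.na(out$calls[1L, 4L]))         # heterozygous
  expect_identical(unname(out$calls[2L, 2L]), 1L)  # qual 30 / depth 10 kept

  # per-sample depth cap: literal 3*SD rule vs mean + 3*SD
  sites2 <- data.frame(chrom = "chr1", pos = 0:9, ref = "A", alt = "T",
                       qual = 99)
  d <- matrix(10L, 2, 10); d[1L, 10L] <- 200L
  gm2 <- genotype_matrix(c("a", "b"), sites2,
                         matrix(0L, 2, 10), depth = d)
  lit <- filter_calls(gm2, depth_rule = "literal_3sd")
  expect_true(is.na(lit$calls[1L, 10L]))
  expect_true(all(is.na(lit$calls[2L, ])))  # SD 0 -> cap 0 under literal rule
  rel <- filter_calls(gm2, depth_rule = "mean_plus_3sd")
  expect_false(anyNA(rel$calls[2L, ]))
})

test_that("repeat and indel masking matches hand-computed intervals", {
  # non-repetitive CCGT background; motifs at known offsets:
  # A x10 at [100,110), AT x6 at [200,212), AT x5 at [300,310),
  # GCA x7 at [402,423), indel anchor at 450
  bg <- function(k) substr(strrep("CCGT", ceiling(k / 4)), 1L, k)
  s <- paste0(bg(100), strrep("A", 10), bg(90), strrep("AT", 6), bg(88),
              strrep("AT", 5), bg(90), "TT", strrep("GCA", 7), "TT", bg(75))
  ref <- reference_genome(c(chr1 = s))
  mask <- build_site_mask(ref, indel_positions = data.frame(chrom = "chr1",
                                                            pos = 450L))
  hp <- mask[mask$reason == "homopolymer", ]
  expect_equal(c(hp$start, hp$end), c(90L, 120L))

  di <- mask[mask$reason == "dimer_repeat", ]
  expect_equal(c(di$start, di$end), c(190L, 222L))  # AT x5 is NOT masked

  tri <- mask[mask$reason == "trimer_repeat", ]
  expect_equal(c(tri$start, tri$end), c(392L, 433L))

  ind <- mask[mask$reason == "indel_flank", ]
  expect_equal(c(ind$start, ind$end), c(440L, 461L))
})

test_that("feature masks are taken from the annotation and unions are idempotent", {
  ref <- reference_genome(c(chr1 = strrep("ACGT", 100)))
  ann <- data.frame(type = c("transposable_element", "centromere", "gene"),
                    chrom = "chr1", start = c(10L, 100L, 300L),
                    end = c(40L, 150L, 350L), strand = "+",
                    id = c("te1", "cen1", "g1"), parent = NA_character_)
  mask <- build_site_mask(ref, annotation = ann)
  expect_setequal(mask$reason, c("transposable_element", "centromere"))
  u1 <- mask_union(mask)
  u2 <- mask_union(rbind(mask, mask))
  expect_equal(u1, u2)
})

test_that("mask application keeps complete unmasked sites and the accounting adds up", {
  set.seed(1)
  ref <- reference_genome(c(chr1 = strrep("ACGT", 500)))
  pos <- seq(10L, 1900L, by = 200L)          # 10 sites
  calls <- matrix(sample(0:1, 4 * 10, replace = TRUE), 4, 10)
  calls[, 1L] <- c(0L, 1L, 0L, 1L)
  calls[2L, 5L] <- NA                        # one site incomplete
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                      qual = 99)
  gm <- genotype_matrix(letters[1:4], sites, calls)
  am <- apply_mask_and_complete(gm, NULL, ref)
  expect_equal(am$n_retained_sites, 9L)
  expect_equal(called_sites(am), 9)
  expect_equal(am$n_input_sites - am$n_retained_sites, 1L)

  # a masked position is dropped regardless of its calls
  mask <- structure(data.frame(chrom = "chr1", start = 0L, end = 20L,
                               reason = "custom"),
                    class = c("site_mask", "data.frame"))
  am2 <- apply_mask_and_complete(gm, mask, ref)
  expect_false(any(am2$sites$pos == 10L))

  # no masking, no missing: identity on sites
  calls[2L, 5L] <- 0L
  gm3 <- genotype_matrix(letters[1:4], sites, calls)
  am3 <- apply_mask_and_complete(gm3, NULL, ref)
  expect_equal(am3$sites$pos, pos[apply(calls, 2, function(v) length(unique(v)) > 1)])
  expect_equal(am3$n_retained_sites, 10L)
})

test_that("filtered reads are never shorter than the floor", {
  set.seed(42)
  pairs <- replicate(25, {
    len <- sample(40:120, 1L)
    mkpair(mkread(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""),
                  sample(c(5L, 20L, 35L, 40L), len, replace = TRUE,
                         prob = c(.1, .1, .6, .2))))
  }, simplify = FALSE)
  out <- filter_reads(pairs)
  lens <- unlist(lapply(out, function(p) vapply(p, function(r) nchar(r$seq), 0L)))
  if (length(lens)) expect_true(all(lens >= 45L))
  expect_true(length(out) <= length(pairs))
})
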