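test_that("codon site counts match enumeration and sum to 3 for all sense codons", {
  expect_equal(codon_site_counts("ATG"), c(syn = 0, nonsyn = 3))
  expect_equal(codon_site_counts("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  expect_gt(codon_site_counts("CGG")[["syn"]], 1)   # 4-fold 3rd + CGG<->AGG
  for (cd in oracle_sense_codons()) {
    sc <- codon_site_counts(cd)
    expect_equal(sum(sc), 3)
    expect_equal(unname(sc), unname(oracle_ng_sites(cd)), tolerance = 1e-12)
  }
  expect_error(codon_site_counts("TAA"), "stop")
  expect_error(codon_site_counts("ANT"), "codon")
})

test_that("codon pair differences average pathways and are symmetric", {
  d <- codon_pair_differences("TTT", "TTC")
  expect_equal(c(d$syn_diffs, d$nonsyn_diffs), c(1, 0))
  d <- codon_pair_differences("TTT", "TTA")
  expect_equal(c(d$syn_diffs, d$nonsyn_diffs), c(0, 1))
  d <- codon_pair_differences("TTT", "GTA")
  expect_equal(d$syn_diffs + d$nonsyn_diffs, 2)
  expect_equal(d$n_pathways, 2L)

  set.seed(7)
  sense <- oracle_sense_codons()
  for (k in 1:60) {
    a <- sample(sense, 1L); b <- sample(sense, 1L)
    ab <- codon_pair_differences(a, b)
    ba <- codon_pair_differences(b, a)
    expect_equal(ab$syn_diffs, ba$syn_diffs, tolerance = 1e-12)
    orc <- oracle_ng_pathways(a, b)
    expect_equal(ab$syn_diffs, unname(orc["syn"]), tolerance = 1e-12)
    expect_equal(ab$nonsyn_diffs, unname(orc["nonsyn"]), tolerance = 1e-12)
  }
})

test_that("branchpoint search prefers leftmost exact matches over mismatches", {
  # exact CTAAC at position 10
  expect_equal(find_branchpoint(paste0("GTAAGTACT", "CTAAC", "TTTAG")), 10L)
  # one-mismatch CTGAC accepted when no exact match exists
  expect_equal(find_branchpoint(paste0("GTAAGTACT", "CTGAC", "TTTAG")), 10L)
  # an exact match further right beats an earlier one-mismatch match
  expect_equal(find_branchpoint(paste0("GTAAGTACT", "CTGAC", "CTAAC", "AG")), 15L)
  # matches before position 8 are ignored
  expect_equal(find_branchpoint(paste0("GCTAACG", "TTCTAACTTAG")), 10L)
  expect_true(is.na(find_branchpoint("GTAAGTGGGGGGGGTTTTAG")))
})

# A hand-built two-gene reference: one plus-strand gene with 5'UTR, CDS,
# intron, CDS, 3'UTR; flanked by intergenic sequence and an ncRNA.
build_toy_locus <- function(n = 4L) {
  u5 <- "CCGTCCGTCC"                                   # [20,30)
  cds1 <- "ATGTTTCCGGGT"                               # [30,42)  4 codons
  intron <- paste0("GTAAGTACGAC", "CTAAC", "GGCATTAG") # [42,66)  len 24
  cds2 <- "CGGAAATAA"                                  # [66,75)  3 codons
  u3 <- "CCGTCCGTCCGT"                                 # [75,87)
  nc <- strrep("GACT", 15)                             # ncRNA [100,160)
  s <- paste0(strrep("CCGT", 5), u5, cds1, intron, cds2, u3,
              substr(strrep("TGCA", 4), 1, 13), nc, strrep("CCGT", 10))
  ref <- reference_genome(c(chr1 = s))
  ann <- data.frame(
    type = c("gene", "five_prime_UTR", "CDS", "intron", "CDS",
             "three_prime_UTR", "ncRNA"),
    chrom = "chr1",
    start = c(20L, 20L, 30L, 42L, 66L, 75L, 100L),
    end = c(87L, 30L, 42L, 66L, 75L, 87L, 160L),
    strand = "+",
    id = c("g1", "g1.u5", "g1.c1", "g1.i1", "g1.c2", "g1.u3", "nc1"),
    parent = c(NA, "g1", "g1", "g1", "g1", "g1", NA),
    stringsAsFactors = FALSE)
  class(ann) <- c("annotation_set", "data.frame")
  list(ref = ref, ann = ann)
}

test_that("site classification paints classes with the documented precedence", {
  toy <- build_toy_locus()
  calls <- matrix(c(0L, 0L, 1L, 1L), 4L, 1L)
  am <- toy_analysis_matrix(calls, pos = 33L, L = 200L)
  cm <- classify_sites(toy$ann, toy$ref, am, min_called_bp = 5L)
  codes <- cm$codes$chr1
  expect_equal(unname(codes[21L]), unname(CLASS_CODES[["five_prime_UTR"]]))
  expect_equal(unname(codes[31L]), unname(CLASS_CODES[["CDS"]]))
  expect_equal(unname(codes[80L]), unname(CLASS_CODES[["three_prime_UTR"]]))
  expect_equal(unname(codes[120L]), unname(CLASS_CODES[["ncRNA"]]))
  expect_equal(unname(codes[5L]), unname(CLASS_CODES[["intergenic"]]))
  # intron usable window: positions 8..(branchpoint start - 1) of the
  # intron, i.e. 1-based genomic 50..53 for a motif at intron position 12
  expect_equal(unname(codes[50:53]),
               rep(unname(CLASS_CODES[["intron"]]), 4L))
  expect_equal(unname(codes[49L]), unname(CLASS_CODES[["excluded"]]))
  expect_equal(unname(codes[54L]), unname(CLASS_CODES[["excluded"]]))
  # stop codon at CDS end is not a countable CDS site
  expect_equal(unname(codes[73L]), unname(CLASS_CODES[["excluded"]]))
})

test_that("short elements are excluded by the called-length filter", {
  toy <- build_toy_locus()
  calls <- matrix(c(0L, 0L, 1L, 1L), 4L, 1L)
  am <- toy_analysis_matrix(calls, pos = 33L, L = 200L)
  # default 50 bp floor: the 10 bp 5'UTR and 12 bp 3'UTR drop out
  cm <- classify_sites(toy$ann, toy$ref, am)
  expect_equal(unname(cm$codes$chr1[21L]), unname(CLASS_CODES[["excluded"]]))
  expect_equal(unname(cm$codes$chr1[80L]), unname(CLASS_CODES[["excluded"]]))
  # the 60 bp ncRNA survives
  expect_equal(unname(cm$codes$chr1[120L]), unname(CLASS_CODES[["ncRNA"]]))
})

test_that("a CDS with length not divisible by 3 is excluded with a warning", {
  toy <- build_toy_locus()
  ann <- toy$ann
  ann$end[ann$id == "g1.c2"] <- 74L   # 8 bp second exon
  calls <- matrix(c(0L, 0L, 1L, 1L), 4L, 1L)
  am <- toy_analysis_matrix(calls, pos = 33L, L = 200L)
  expect_warning(cm <- classify_sites(ann, toy$ref, am, min_called_bp = 5L),
                 "divisible by 3")
  expect_false(cm$genes[["g1"]]$ok)
})

test_that("gene-level diversity matches the single-codon oracle", {
  toy <- build_toy_locus()
  # one SNP at pos 35 (codon TTT, 3rd position): T->C is synonymous
  calls <- matrix(c(0L, 0L, 1L, 1L), 4L, 1L)
  am <- toy_analysis_matrix(calls, pos = 35L, L = 200L)
  am$sites$ref <- "T"; am$sites$alt <- "C"
  cm <- classify_sites(toy$ann, toy$ref, am, min_called_bp = 5L)
  gd <- gene_diversity("g1", am, cm, min_syn_sites = 200)
  # 6 callable codons (stop excluded); all samples share site counts except
  # none vary in counts here (TTT and TTC both have 1/3 syn at pos 3)
  expect_equal(gd$pi_n, 0)
  # pairwise syn differences: 4 of 6 pairs differ by one synonymous change
  expect_equal(gd$pi_s * gd$syn_sites, 4 / 6)
  expect_equal(gd$ratio, 0)
  expect_false(gd$eligible)
  expect_equal(site_classes(cm, am), "synonymous")
})

test_that("class assignment is exhaustive and exclusive over callable sites", {
  td <- withr::local_tempdir()
  fx <- generate_fixture(td, "neutral", seed = 9, chrom_length = 30000L,
                         all_sites = FALSE)
  ref <- read_reference(fx$paths$fasta)
  gm <- read_variants(fx$paths$snps, ref)
  ann <- read_annotation(fx$paths$gff)
  mask <- build_site_mask(ref, annotation = ann)
  am <- apply_mask_and_complete(gm, mask, ref,
                                callable = read_callable_bed(fx$paths$callable))
  cm <- classify_sites(ann, ref, am)
  cls <- site_classes(cm, am)
  known <- c("synonymous", "nonsynonymous", "CDS_mixed", "intron",
             "five_prime_UTR", "three_prime_UTR", "ncRNA", "intergenic",
             "excluded")
  expect_true(all(cls %in% known))
  expect_length(cls, nrow(am$sites))
  # generated introns carry a branchpoint motif by construction
  for (r in which(ann$type == "intron")) {
    seqtx <- substr(ref$seq[[ann$chrom[r]]], ann$start[r] + 1L, ann$end[r])
    if (ann$strand[r] == "-") {
      seqtx <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqtx)))
    }
    expect_false(is.na(find_branchpoint(seqtx)))
  }
})
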