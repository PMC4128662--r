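# Fixture generation: annotated references, marker tables and on-disk
# file sets (FASTA/VCF/BED/GFF3/TSV/JSON) with known truth.

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

rand_sense_codons <- function(k) {
  sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*" &
                                       names(GENETIC_CODE_TABLE) != "ATG"]
  paste(sample(sense, k, replace = TRUE), collapse = "")
}

#' Generate a feature annotation onto a reference
#'
#' Writes non-overlapping gene cassettes (5'UTR, two CDS exons flanking an
#' intron carrying a CTAAC branchpoint motif at a position of at least 12,
#' 3'UTR; start and stop codons; no internal stops), ncRNAs, pseudogenes,
#' transposable elements, repeat tracts matching the masking rules, and one
#' centromere plus telomeres per chromosome. The corresponding sequence is
#' written into the reference, which is returned alongside the annotation.
#'
#' @param reference reference_genome to annotate (sequence is edited)
#' @param seed RNG seed
#' @param gene_every approximate spacing of gene cassettes in bp
#' @return list: annotation (annotation_set), reference (edited)
#' @export
generate_annotation <- function(reference, seed = 1L, gene_every = 8000L) {
  set.seed(seed)
  feats <- list()
  gene_no <- 0L
  for (ch in reference$names) {
    L <- reference$lengths[[ch]]
    if (L < 20000L) stop("chromosome too short for annotation: ", ch)
    x <- strsplit(reference$seq[[ch]], "")[[1L]]
    tel <- min(2000L, L %/% 20L)
    cen_half <- min(2500L, L %/% 40L)
    cen <- c(L %/% 2L - cen_half, L %/% 2L + cen_half)
    feats[[length(feats) + 1L]] <- data.frame(
      type = c("telomere", "telomere", "centromere"), chrom = ch,
      start = c(0L, L - tel, cen[1L]), end = c(tel, L, cen[2L]),
      strand = "+", id = paste0(ch, c(":telL", ":telR", ":cen")),
      parent = NA_character_, stringsAsFactors = FALSE)
    at <- tel + 500L
    slot <- 0L
    while (at + 3000L < L - tel) {
      # skip the centromere
      if (at + 3000L >= cen[1L] && at <= cen[2L]) { at <- cen[2L] + 500L; next }
      slot <- slot + 1L
      kind <- slot %% 6L
      if (kind %in% c(1L, 2L, 4L, 5L)) {
        gene_no <- gene_no + 1L
        gid <- sprintf("gene%03d", gene_no)
        strand <- if (kind %in% c(1L, 4L)) "+" else "-"
        u5 <- 90L + 3L * (slot %% 10L)
        e1 <- 150L + 9L * (slot %% 7L)
        e2 <- 300L + 9L * (slot %% 5L)
        inlen <- 80L + (slot %% 4L) * 10L
        u3 <- 120L
        cds1 <- if (strand == "+") paste0("ATG", rand_sense_codons((e1 - 3L) / 3L))
                else rand_sense_codons(e1 / 3L)
        cds2 <- if (strand == "+") paste0(rand_sense_codons((e2 - 6L) / 3L + 1L), "TAA")
                else rand_sense_codons(e2 / 3L)
        if (strand == "-") {
          cds1 <- paste0("ATG", substr(cds1, 4L, e1))
          cds2 <- paste0(substr(cds2, 1L, e2 - 3L), "TAA")
        }
        motif_at <- 12L + 3L * (slot %% 8L)       # 1-based, >= 12
        intron <- rand_seq(inlen)
        substr(intron, 1L, 2L) <- "GT"
        substr(intron, inlen - 1L, inlen) <- "AG"
        substr(intron, motif_at, motif_at + 4L) <- "CTAAC"
        cassette <- paste0(rand_seq(u5), cds1, intron, cds2, rand_seq(u3))
        clen <- nchar(cassette)
        if (strand == "-") cassette <- reverse_complement(cassette)
        x[(at + 1L):(at + clen)] <- strsplit(cassette, "")[[1L]]
        # genomic intervals, left to right
        lens <- c(u5, e1, inlen, e2, u3)
        types <- c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR")
        if (strand == "-") { lens <- rev(lens); types <- rev(types) }
        ends <- at + cumsum(lens)
        starts <- ends - lens
        feats[[length(feats) + 1L]] <- data.frame(
          type = c("gene", types), chrom = ch,
          start = c(at, starts), end = c(at + clen, ends),
          strand = strand,
          id = c(gid, paste0(gid, ".", seq_along(types))),
          parent = c(NA_character_, rep(gid, length(types))),
          stringsAsFactors = FALSE)
        at <- at + clen + (gene_every - clen)
      } else if (kind == 3L) {
        # a noncoding block: ncRNA + pseudogene + TE + repeat tracts
        nc <- 200L; ps <- 300L; te <- 400L
        s0 <- at
        feats[[length(feats) + 1L]] <- data.frame(
          type = c("ncRNA", "pseudogene", "transposable_element"),
          chrom = ch,
          start = c(s0, s0 + nc + 200L, s0 + nc + ps + 400L),
          end = c(s0 + nc, s0 + nc + 200L + ps, s0 + nc + ps + 400L + te),
          strand = "+",
          id = sprintf("%s:nc%d", ch, slot), parent = NA_character_,
          stringsAsFactors = FALSE)
        rep_at <- s0 + nc + ps + te + 600L
        x[(rep_at + 1L):(rep_at + 12L)] <- "A"
        x[(rep_at + 101L):(rep_at + 114L)] <-
          strsplit(strrep("AT", 7L), "")[[1L]]
        at <- at + gene_every
      } else {
        at <- at + gene_every %/% 2L   # plain intergenic stretch
      }
    }
    reference$seq[[ch]] <- paste(x, collapse = "")
  }
  ann <- do.call(rbind, feats)
  rownames(ann) <- NULL
  class(ann) <- c("annotation_set", "data.frame")
  list(annotation = ann, reference = reference)
}

#' Generate a marker table from a smooth monotone quartic truth map
#'
#' The truth map is cM(x) = 80u + 40u^2 - 30u^3 + 10u^4 with u = x/L
#' (about 100 cM per chromosome, strictly increasing); markers are placed
#' at sorted uniform positions with small Gaussian cM noise.
#'
#' @param reference reference_genome
#' @param markers_per_chrom markers per chromosome (default 25)
#' @param noise_sd marker cM noise SD (default 0.5)
#' @param seed RNG seed
#' @return list: markers (data.frame chrom, bp, cM), truth_cM (function
#'   (chrom, bp) -> cM)
#' @export
generate_marker_table <- function(reference, markers_per_chrom = 25L,
                                  noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  truth <- function(chrom, bp) {
    u <- bp / reference$lengths[[chrom]]
    80 * u + 40 * u^2 - 30 * u^3 + 10 * u^4
  }
  rows <- lapply(reference$names, function(ch) {
    L <- reference$lengths[[ch]]
    bp <- sort(c(0L, L, sample.int(L - 1L, markers_per_chrom - 2L)))
    cM <- pmax(0, truth(ch, bp) + stats::rnorm(length(bp), 0, noise_sd))
    data.frame(chrom = ch, bp = bp, cM = cM, stringsAsFactors = FALSE)
  })
  list(markers = do.call(rbind, rows), truth_cM = truth)
}

#' Write a genotype matrix as VCF
#'
#' @param gm genotype_matrix
#' @param path output path
#' @param reference reference_genome (contig headers; reference bases for
#'   monomorphic records)
#' @param all_sites also emit a monomorphic record (ALT ".") for every
#'   position without a variant record
#' @param dp constant per-call depth written to FORMAT/DP
#' @export
write_vcf <- function(gm, path, reference, all_sites = FALSE, dp = 50L) {
  n <- length(gm$samples)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", reference$names,
                      reference$lengths),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- character(0)
  for (ch in reference$names) {
    i_ch <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[i_ch]
    if (all_sites) {
      L <- reference$lengths[[ch]]
      refbases <- strsplit(reference$seq[[ch]], "")[[1L]]
      allpos <- 0:(L - 1L)
      ref <- refbases[allpos + 1L]
      alt <- rep(".", L)
      qual <- rep("99", L)
      gtcols <- matrix(sprintf("0:%d", dp), L, n)
      j <- match(pos, allpos)
    } else {
      allpos <- pos
      ref <- gm$sites$ref[i_ch]
      alt <- gm$sites$alt[i_ch]
      qual <- format(gm$sites$qual[i_ch], trim = TRUE)
      gtcols <- matrix("", length(pos), n)
      j <- seq_along(pos)
    }
    if (length(j)) {
      ref[j] <- gm$sites$ref[i_ch]
      alt[j] <- ifelse(gm$sites$alt[i_ch] == "", ".", gm$sites$alt[i_ch])
      qual[j] <- format(gm$sites$qual[i_ch], trim = TRUE)
      for (s in seq_len(n))
        gtcols[j, s] <- sprintf("%d:%d", gm$calls[s, i_ch], dp)
    }
    cols <- c(list(ch, allpos + 1L, ".", ref, alt, qual, ".", ".", "GT:DP"),
              lapply(seq_len(n), function(s) gtcols[, s]))
    body <- c(body, do.call(paste, c(cols, sep = "\t")))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an annotation set as GFF3
#' @param ann annotation_set
#' @param path output path
#' @export
write_annotation <- function(ann, path) {
  attrs <- ifelse(is.na(ann$parent), paste0("ID=", ann$id),
                  paste0("ID=", ann$id, ";Parent=", ann$parent))
  lines <- paste(ann$chrom, "haploscan", ann$type, ann$start + 1L, ann$end,
                 ".", ann$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Generate a complete on-disk fixture with known truth
#'
#' Scenarios: \code{neutral} (one chromosome, neutral coalescent),
#' \code{sweep} (adds a partial-sweep haplotype block shared by 8 of 32
#' samples), \code{divergent_clade} (a 5-sample clade plus a 5\%-divergent
#' 1-kb segment), and \code{full} (three chromosomes combining the clade,
#' one sweep and one divergent segment). Writes FASTA, SNP-only VCF,
#' all-sites VCF, callable BED, GFF3, marker TSV and a truth JSON.
#'
#' @param out_dir output directory
#' @param scenario one of neutral, sweep, divergent_clade, full
#' @param seed RNG seed (all randomness derives from it)
#' @param n sample size (default 32)
#' @param chrom_length per-chromosome length in bp (default 100000)
#' @param theta per-site mutation rate (default 0.003)
#' @param rho per-site recombination rate (default theta/100)
#' @param all_sites write the all-sites VCF (default TRUE)
#' @return invisible list: paths, truth, plus the in-memory simulation
#' @export
generate_fixture <- function(out_dir,
                             scenario = c("neutral", "sweep",
                                          "divergent_clade", "full"),
                             seed = 1L, n = 32L, chrom_length = 100000L,
                             theta = 0.003, rho = theta / 100,
                             all_sites = TRUE) {
  scenario <- match.arg(scenario)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  nchrom <- if (scenario == "full") 3L else 1L
  lens <- stats::setNames(rep(as.integer(chrom_length), nchrom),
                          paste0("chr", seq_len(nchrom)))
  clade <- if (scenario %in% c("divergent_clade", "full"))
    c(15L, 16L, 17L, 18L, 30L)
  ref0 <- reference_genome(vapply(lens, rand_seq, character(1L)))
  ga <- generate_annotation(ref0, seed = seed + 1L)
  cfg <- sim_config(n = n, chrom_lengths = lens, theta = theta, rho = rho,
                    clade = clade, seed = seed + 2L)
  sim <- simulate_population(cfg, reference = ga$reference)
  truth <- sim$truth
  if (scenario %in% c("sweep", "full")) {
    ch <- if (scenario == "full") "chr2" else "chr1"
    L <- lens[[ch]]
    iv <- list(ch, as.integer(0.4 * L), as.integer(0.4 * L) +
                 min(50000L, L %/% 2L))
    sim$matrix <- inject_partial_sweep(sim$matrix, carriers = 1:8,
                                       interval = iv)
    truth$sweep <- attr(sim$matrix, "sweep")
  }
  if (scenario %in% c("divergent_clade", "full")) {
    ch <- if (scenario == "full") "chr3" else "chr1"
    L <- lens[[ch]]
    iv <- list(ch, as.integer(0.7 * L), as.integer(0.7 * L) + 1000L)
    sim$matrix <- inject_divergent_segment(sim$matrix, clade = clade,
                                           interval = iv, divergence = 0.05,
                                           reference = sim$reference,
                                           seed = seed + 3L)
    truth$divergent <- attr(sim$matrix, "divergent")
  }
  mk <- generate_marker_table(sim$reference, seed = seed + 4L)
  paths <- list(
    fasta = file.path(out_dir, "reference.fa"),
    snps = file.path(out_dir, "snps.vcf"),
    all_sites = if (all_sites) file.path(out_dir, "all_sites.vcf"),
    callable = file.path(out_dir, "callable.bed"),
    gff = file.path(out_dir, "annotation.gff3"),
    markers = file.path(out_dir, "markers.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_reference(sim$reference, paths$fasta)
  write_vcf(sim$matrix, paths$snps, sim$reference, all_sites = FALSE)
  if (all_sites)
    write_vcf(sim$matrix, paths$all_sites, sim$reference, all_sites = TRUE)
  writeLines(paste(names(lens), 0L, lens, sep = "\t"), paths$callable)
  write_annotation(ga$annotation, paths$gff)
  utils::write.table(mk$markers, paths$markers, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth$clade <- clade
  truth$scenario <- scenario
  truth$seed <- seed
  truth$theta <- theta
  truth$rho <- rho
  jsonlite::write_json(truth[names(truth) != "blocks"], paths$truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(paths = paths, truth = truth, sim = sim,
                 annotation = ga$annotation, markers = mk$markers))
}
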