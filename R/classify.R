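# Functional classification of called sites and Nei-Gojobori gene summaries.
#
# Precedence of classes (high to low): CDS > UTR > intron > ncRNA >
# intergenic. tRNA/rRNA/snoRNA, pseudogenes, repeats and masked feature
# footprints are excluded outright; annotated elements with >= 1/3 missing
# sites or < 50 bp of called sequence are excluded; intron sites are
# restricted to positions 8 through the base before the leftmost CTAAC
# branchpoint motif (one mismatch allowed; exact matches preferred), and
# introns lacking a motif are excluded.

CLASS_CODES <- c(uncalled = 0L, intergenic = 1L, excluded = 2L, ncRNA = 3L,
                 intron = 4L, five_prime_UTR = 5L, three_prime_UTR = 6L,
                 CDS = 7L)

codon_site_fractions <- function(codon) {
  # per-position synonymous fraction of the 3 single-base changes
  aa <- translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  vapply(1:3, function(pos) {
    syn <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (translate_codon(mut) == aa) syn <- syn + 1L
    }
    syn / 3
  }, 0)
}

# lazy per-codon cache of per-position synonymous fractions; NULL for
# stop codons and non-codons
codon_fracs_lookup <- function(codon) {
  hit <- .ng_env$fracs[[codon]]
  if (is.null(hit)) {
    if (!codon %in% names(GENETIC_CODE_TABLE) || is_stop_codon(codon))
      return(NULL)
    hit <- codon_site_fractions(codon)
    .ng_env$fracs[[codon]] <- hit
  }
  hit
}

#' Locate the intron branchpoint motif
#'
#' Leftmost exact CTAAC match starting at or after 1-based position
#' \code{min_pos}; if none, the leftmost single-mismatch match. Exact matches
#' win over mismatch matches wherever both exist.
#'
#' @param seq intron sequence in transcription orientation
#' @param min_pos earliest allowed 1-based motif start (default 8)
#' @return 1-based motif start, or NA when no match exists
#' @export
find_branchpoint <- function(seq, min_pos = 8L) {
  motif <- "CTAAC"
  L <- nchar(seq)
  if (L < min_pos + 4L) return(NA_integer_)
  x <- strsplit(seq, "")[[1L]]
  m <- strsplit(motif, "")[[1L]]
  starts <- min_pos:(L - 4L)
  mism <- vapply(starts, function(s) sum(x[s:(s + 4L)] != m), 0L)
  exact <- starts[mism == 0L]
  if (length(exact)) return(exact[1L])
  near <- starts[mism == 1L]
  if (length(near)) return(near[1L])
  NA_integer_
}

#' Classify called sites by functional class
#'
#' Assigns every called position one class and, for CDS positions, the
#' fractional synonymous site count of the reference codon. See the file
#' header for the precedence and exclusion rules.
#'
#' @param annotation annotation_set
#' @param reference reference_genome
#' @param am analysis_matrix (supplies the callable track)
#' @param strict_intergenic_flank additionally exclude this many bp of
#'   intergenic sequence up/downstream of annotated UTR boundaries
#'   (default 0; 500 reproduces the robustness check)
#' @param min_called_bp element filter: minimum called bp (default 50)
#' @param max_missing_frac element filter: maximum missing fraction
#'   (default 1/3)
#' @return object of class \code{site_class_map}
#' @export
classify_sites <- function(annotation, reference, am,
                           strict_intergenic_flank = 0L,
                           min_called_bp = 50L, max_missing_frac = 1 / 3) {
  chroms <- reference$names
  callable01 <- lapply(chroms, function(ch) {
    v <- logical(reference$lengths[[ch]])
    iv <- am$callable[[ch]]
    if (!is.null(iv))
      for (r in seq_len(nrow(iv)))
        if (iv$end[r] > iv$start[r]) v[(iv$start[r] + 1L):iv$end[r]] <- TRUE
    v
  })
  names(callable01) <- chroms
  codes <- lapply(chroms, function(ch) {
    v <- integer(reference$lengths[[ch]])
    v[callable01[[ch]]] <- CLASS_CODES[["intergenic"]]
    v
  })
  names(codes) <- chroms
  syn_frac <- lapply(chroms, function(ch)
    rep(NA_real_, reference$lengths[[ch]]))
  names(syn_frac) <- chroms

  paint <- function(ch, start, end, value) {
    if (end > start) codes[[ch]][(start + 1L):end] <<- value
  }
  element_ok <- function(ch, ivs) {
    # ivs: data.frame(start, end); filter over the element's total footprint
    len <- sum(ivs$end - ivs$start)
    called <- sum(unlist(Map(function(s, e)
      if (e > s) sum(callable01[[ch]][(s + 1L):e]) else 0L, ivs$start, ivs$end)))
    called >= min_called_bp && (len - called) < max_missing_frac * len
  }

  EXC <- CLASS_CODES[["excluded"]]
  # excluded footprints: pseudogene, repeats, small RNAs, masked features
  exc_types <- c("pseudogene", "repeat", "transposable_element",
                 "tRNA", "rRNA", "snoRNA", "centromere", "telomere")
  for (r in which(annotation$type %in% exc_types))
    paint(annotation$chrom[r], annotation$start[r], annotation$end[r], EXC)

  # ncRNA
  for (r in which(annotation$type == "ncRNA")) {
    ch <- annotation$chrom[r]
    iv <- data.frame(start = annotation$start[r], end = annotation$end[r])
    paint(ch, iv$start, iv$end,
          if (element_ok(ch, iv)) CLASS_CODES[["ncRNA"]] else EXC)
  }

  # introns: exclude footprint, then paint the usable pre-branchpoint window
  for (r in which(annotation$type == "intron")) {
    ch <- annotation$chrom[r]
    s <- annotation$start[r]; e <- annotation$end[r]
    paint(ch, s, e, EXC)
    iv <- data.frame(start = s, end = e)
    if (!element_ok(ch, iv)) next
    seq_tx <- substr(reference$seq[[ch]], s + 1L, e)
    if (annotation$strand[r] == "-") seq_tx <- reverse_complement(seq_tx)
    bp <- find_branchpoint(seq_tx)
    if (is.na(bp) || bp <= 8L) next
    if (annotation$strand[r] == "+") paint(ch, s + 7L, s + bp - 1L,
                                           CLASS_CODES[["intron"]])
    else paint(ch, e - bp + 1L, e - 7L, CLASS_CODES[["intron"]])
  }

  # UTRs
  for (type in c("five_prime_UTR", "three_prime_UTR")) {
    for (r in which(annotation$type == type)) {
      ch <- annotation$chrom[r]
      iv <- data.frame(start = annotation$start[r], end = annotation$end[r])
      paint(ch, iv$start, iv$end,
            if (element_ok(ch, iv)) CLASS_CODES[[type]] else EXC)
    }
  }

  # CDS, grouped by gene (Parent attribute)
  cds <- annotation[annotation$type == "CDS", , drop = FALSE]
  cds$gene <- ifelse(is.na(cds$parent), cds$id, cds$parent)
  genes <- list()
  for (gid in unique(cds$gene)) {
    gc <- cds[cds$gene == gid, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    ch <- gc$chrom[1L]
    strand <- gc$strand[1L]
    total_len <- sum(gc$end - gc$start)
    info <- list(chrom = ch, strand = strand,
                 cds = data.frame(start = gc$start, end = gc$end),
                 start = min(gc$start), end = max(gc$end), ok = FALSE)
    if (total_len %% 3L != 0L) {
      warning("CDS length of ", gid, " not divisible by 3; gene excluded")
      for (r in seq_len(nrow(gc))) paint(ch, gc$start[r], gc$end[r], EXC)
    } else if (!element_ok(ch, info$cds)) {
      for (r in seq_len(nrow(gc))) paint(ch, gc$start[r], gc$end[r], EXC)
    } else {
      info$ok <- TRUE
      # footprint defaults to excluded; callable sense codons overwrite it,
      # so stop codons and incompletely-called codons never keep a
      # lower-precedence label
      for (r in seq_len(nrow(gc))) paint(ch, gc$start[r], gc$end[r], EXC)
      # genomic positions in transcription order
      gpos <- unlist(Map(function(s, e) s:(e - 1L), gc$start, gc$end))
      if (strand == "-") gpos <- rev(gpos)
      bases <- strsplit(reference$seq[[ch]], "")[[1L]][gpos + 1L]
      if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
      ncod <- length(gpos) %/% 3L
      for (cdx in seq_len(ncod)) {
        idx <- (3L * (cdx - 1L) + 1L):(3L * cdx)
        codon <- paste(bases[idx], collapse = "")
        p3 <- gpos[idx]
        if (!all(callable01[[ch]][p3 + 1L])) next
        fr <- codon_fracs_lookup(codon)
        if (is.null(fr)) next  # stop or ambiguous codon: leave unpainted
        codes[[ch]][p3 + 1L] <- CLASS_CODES[["CDS"]]
        syn_frac[[ch]][p3 + 1L] <- fr
      }
      info$gpos <- gpos
      info$bases <- bases
    }
    genes[[gid]] <- info
  }

  if (strict_intergenic_flank > 0L) {
    utr <- annotation[annotation$type %in% c("five_prime_UTR",
                                             "three_prime_UTR"), , drop = FALSE]
    for (r in seq_len(nrow(utr))) {
      ch <- utr$chrom[r]
      L <- reference$lengths[[ch]]
      for (iv in list(c(max(0L, utr$start[r] - strict_intergenic_flank),
                        utr$start[r]),
                      c(utr$end[r], min(L, utr$end[r] + strict_intergenic_flank)))) {
        if (iv[2L] > iv[1L]) {
          seg <- (iv[1L] + 1L):iv[2L]
          hit <- codes[[ch]][seg] == CLASS_CODES[["intergenic"]]
          codes[[ch]][seg][hit] <- EXC
        }
      }
    }
  }

  structure(list(codes = codes, syn_frac = syn_frac, genes = genes,
                 reference = reference, callable01 = callable01),
            class = "site_class_map")
}

#' @export
print.site_class_map <- function(x, ...) {
  tab <- table(factor(unlist(lapply(x$codes, function(v) v[v > 0L])),
                      levels = CLASS_CODES, labels = names(CLASS_CODES)))
  cat("site_class_map over", length(x$codes), "chromosome(s);",
      length(x$genes), "gene(s)\n")
  print(tab)
  invisible(x)
}

#' Class labels for the SNP sites of an analysis matrix
#'
#' CDS SNPs are labelled synonymous when every observed non-reference base
#' at the site is a synonymous change of the reference codon, nonsynonymous
#' when none is, and CDS_mixed otherwise.
#'
#' @param class_map site_class_map
#' @param am analysis_matrix
#' @return character vector over the SNP sites of \code{am}
#' @export
site_classes <- function(class_map, am) {
  lab <- names(CLASS_CODES)
  out <- character(n_sites(am))
  for (i in seq_len(n_sites(am))) {
    ch <- am$sites$chrom[i]; p <- am$sites$pos[i]
    code <- class_map$codes[[ch]][p + 1L]
    if (code != CLASS_CODES[["CDS"]]) { out[i] <- lab[code + 1L]; next }
    out[i] <- classify_cds_snp(class_map, ch, p, site_alleles(am, i),
                               unique(am$calls[, i]))
  }
  out
}

classify_cds_snp <- function(class_map, ch, p, alleles, observed_idx) {
  # find the gene codon containing position p
  for (g in class_map$genes) {
    if (!isTRUE(g$ok) || g$chrom != ch) next
    j <- match(p, g$gpos)
    if (is.na(j)) next
    cdx <- (j - 1L) %/% 3L
    idx <- (3L * cdx + 1L):(3L * cdx + 3L)
    codon <- paste(g$bases[idx], collapse = "")
    within <- j - 3L * cdx
    minus <- g$strand == "-"
    obs <- alleles[observed_idx + 1L]
    refb <- alleles[1L]
    altb <- setdiff(obs, refb)
    if (length(altb) == 0L) return("CDS_mixed")
    syn <- vapply(altb, function(b) {
      if (minus) b <- chartr("ACGT", "TGCA", b)
      mut <- codon
      substr(mut, within, within) <- b
      if (!mut %in% names(GENETIC_CODE_TABLE)) return(NA)
      translate_codon(mut) == translate_codon(codon)
    }, NA)
    if (all(syn %in% TRUE)) return("synonymous")
    if (all(syn %in% FALSE)) return("nonsynonymous")
    return("CDS_mixed")
  }
  "CDS_mixed"
}

# Gene-level codon alignment summary used by gene_diversity and
# class_diversity. Returns NULL when the gene failed the element filters.
gene_codon_summary <- function(gene_id, am, class_map) {
  g <- class_map$genes[[gene_id]]
  if (is.null(g) || !isTRUE(g$ok)) return(NULL)
  ch <- g$chrom
  n <- length(am$samples)
  npairs <- n * (n - 1) / 2
  gpos <- g$gpos
  bases <- g$bases
  minus <- g$strand == "-"
  ncod <- length(gpos) %/% 3L
  callable <- class_map$callable01[[ch]]
  # SNPs inside the gene's CDS
  i_gene <- which(am$sites$chrom == ch & am$sites$pos %in% gpos)
  j_tx <- match(am$sites$pos[i_gene], gpos)  # transcription-order index
  snp_codon <- (j_tx - 1L) %/% 3L + 1L
  syn_sites <- 0; nonsyn_sites <- 0; syn_diffs <- 0; nonsyn_diffs <- 0
  cds_snp_idx <- integer(0)
  for (cdx in seq_len(ncod)) {
    idx <- (3L * (cdx - 1L) + 1L):(3L * cdx)
    p3 <- gpos[idx]
    if (!all(callable[p3 + 1L])) next
    ref_codon <- paste(bases[idx], collapse = "")
    if (is.null(codon_sites_lookup(ref_codon))) next
    hits <- which(snp_codon == cdx)
    if (length(hits) == 0L) {
      sc <- codon_sites_lookup(ref_codon)
      syn_sites <- syn_sites + sc[["syn"]]
      nonsyn_sites <- nonsyn_sites + sc[["nonsyn"]]
      next
    }
    # sample codons at this codon
    codchars <- matrix(rep(strsplit(ref_codon, "")[[1L]], each = n), nrow = n)
    for (h in hits) {
      site_i <- i_gene[h]
      alle <- site_alleles(am, site_i)
      b <- alle[am$calls[, site_i] + 1L]
      if (minus) b <- chartr("ACGT", "TGCA", b)
      codchars[, j_tx[h] - 3L * (cdx - 1L)] <- b
    }
    codons <- apply(codchars, 1L, paste, collapse = "")
    scl <- lapply(codons, codon_sites_lookup)
    if (any(vapply(scl, is.null, TRUE))) next  # stop/ambiguous codon observed
    cds_snp_idx <- c(cds_snp_idx, i_gene[hits])
    scs <- vapply(scl, identity, c(syn = 0, nonsyn = 0))
    syn_sites <- syn_sites + mean(scs["syn", ])
    nonsyn_sites <- nonsyn_sites + mean(scs["nonsyn", ])
    tab <- table(codons)
    u <- names(tab)
    if (length(u) > 1L) {
      for (a in seq_len(length(u) - 1L)) for (b in (a + 1L):length(u)) {
        pd <- codon_pair_differences(u[a], u[b])
        w <- as.numeric(tab[a]) * as.numeric(tab[b]) / npairs
        syn_diffs <- syn_diffs + w * pd$syn_diffs
        nonsyn_diffs <- nonsyn_diffs + w * pd$nonsyn_diffs
      }
    }
  }
  list(chrom = ch, start = g$start, end = g$end, syn_sites = syn_sites,
       nonsyn_sites = nonsyn_sites, syn_diffs = syn_diffs,
       nonsyn_diffs = nonsyn_diffs, cds_snp_idx = cds_snp_idx)
}

#' Per-class diversity summary
#'
#' A per-class table of called sites, SNP counts and nucleotide diversity:
#' synonymous and nonsynonymous values come from the Nei-Gojobori gene
#' machinery (fractional site counts, pathway-averaged differences), the
#' noncoding classes pool all called sites of the class.
#'
#' @param am analysis_matrix
#' @param class_map site_class_map
#' @return data.frame: class, sites, snps, pi, pi_pct
#' @export
class_diversity <- function(am, class_map) {
  snp_class <- site_classes(class_map, am)
  ps <- pi_per_site(am$calls)
  code_at <- vapply(seq_len(n_sites(am)), function(i)
    class_map$codes[[am$sites$chrom[i]]][am$sites$pos[i] + 1L], 0L)
  rows <- list()
  rows[["all"]] <- data.frame(class = "all", sites = called_sites(am),
                              snps = n_sites(am),
                              pi = sum(ps) / called_sites(am))
  # Nei-Gojobori classes
  syn_sites <- 0; nonsyn_sites <- 0; syn_diffs <- 0; nonsyn_diffs <- 0
  for (gid in names(class_map$genes)) {
    gs <- gene_codon_summary(gid, am, class_map)
    if (is.null(gs)) next
    syn_sites <- syn_sites + gs$syn_sites
    nonsyn_sites <- nonsyn_sites + gs$nonsyn_sites
    syn_diffs <- syn_diffs + gs$syn_diffs
    nonsyn_diffs <- nonsyn_diffs + gs$nonsyn_diffs
  }
  rows[["synonymous"]] <- data.frame(
    class = "synonymous", sites = syn_sites,
    snps = sum(snp_class == "synonymous"),
    pi = if (syn_sites > 0) syn_diffs / syn_sites else NA_real_)
  rows[["nonsynonymous"]] <- data.frame(
    class = "nonsynonymous", sites = nonsyn_sites,
    snps = sum(snp_class == "nonsynonymous"),
    pi = if (nonsyn_sites > 0) nonsyn_diffs / nonsyn_sites else NA_real_)
  for (cl in c("intron", "five_prime_UTR", "three_prime_UTR", "ncRNA",
               "intergenic")) {
    code <- CLASS_CODES[[cl]]
    nsite <- sum(vapply(names(class_map$codes), function(ch)
      sum(class_map$codes[[ch]] == code & class_map$callable01[[ch]]), 0L))
    insnp <- code_at == code
    rows[[cl]] <- data.frame(class = cl, sites = nsite, snps = sum(insnp),
                             pi = if (nsite > 0) sum(ps[insnp]) / nsite
                                  else NA_real_)
  }
  out <- do.call(rbind, rows)
  out$pi_pct <- 100 * out$pi
  rownames(out) <- NULL
  out
}
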