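# Format-boundary readers and writers. All conversion between the 1-based
# conventions of VCF/GFF3 and the internal 0-based half-open convention
# happens here and only here.

#' Read a reference genome from FASTA
#'
#' @param path path to a (possibly multi-record) FASTA file
#' @return \code{reference_genome}; sequences uppercased, record order kept
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate FASTA record name: ", dup[1L])
  x <- as.character(seqs)
  names(x) <- nm
  reference_genome(x)
}

#' Write a reference genome to FASTA
#' @param ref reference_genome
#' @param path output path
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$seq), path,
                              width = 70L)
  invisible(path)
}

#' Read haploid genotype calls from a VCF
#'
#' Accepts haploid (\code{GT=0}) or diploid genotypes; diploid homozygotes
#' are collapsed to a single allele, while heterozygous genotypes -- which
#' cannot occur in a haploid and are treated as call errors -- are loaded
#' with a flag so that \code{\link{filter_calls}} can mask them. Monomorphic
#' records (ALT ".") are retained so that an all-sites VCF can supply the
#' invariant-site denominators.
#'
#' @param path VCF path (plain text or bgzipped)
#' @param reference optional \code{reference_genome}; when given, positions
#'   are validated against chromosome lengths
#' @return \code{genotype_matrix} with 0-based positions
#' @export
read_variants <- function(path, reference = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"]) - 1L   # -> 0-based
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt) | alt == "."] <- ""
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  if (!is.null(reference)) {
    bad <- pos >= reference$lengths[chrom] | is.na(reference$lengths[chrom])
    if (any(bad))
      stop("VCF position beyond reference length at ", chrom[which(bad)[1L]],
           ":", pos[which(bad)[1L]] + 1L)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  # parse GT strings: haploid "0", diploid "0/0" or "0|1"
  gtv <- sub("\\|", "/", gt)
  a1 <- sub("/.*$", "", gtv)
  a2 <- sub("^[^/]*/?", "", gtv)
  a2[a2 == ""] <- a1[a2 == ""]
  miss <- is.na(gtv) | a1 == "." | a1 == ""
  call1 <- suppressWarnings(as.integer(a1))
  call2 <- suppressWarnings(as.integer(a2))
  het <- !miss & !is.na(call1) & !is.na(call2) & call1 != call2
  calls <- call1
  calls[miss] <- NA_integer_
  calls <- matrix(calls, nrow = nrow(gt), ncol = ncol(gt))
  hetm <- matrix(het, nrow = nrow(gt), ncol = ncol(gt))
  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  ord <- order(match(chrom, unique(chrom)), pos)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      qual = qual, stringsAsFactors = FALSE)[ord, ]
  rownames(sites) <- NULL
  calls <- t(calls[ord, , drop = FALSE])
  hetm <- t(hetm[ord, , drop = FALSE])
  depth <- if (!is.null(dp)) {
    m <- t(dp[ord, , drop = FALSE]); storage.mode(m) <- "integer"; m
  }
  genotype_matrix(samples, sites, calls, depth = depth, het = hetm)
}

#' Read a GFF3 feature annotation
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' internal 0-based half-open one. Feature types outside the known vocabulary
#' are kept and tagged as-is.
#'
#' @param path GFF3 path
#' @return \code{annotation_set}: data.frame with columns \code{type},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{id},
#'   \code{parent}
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GFF3 line ", i, ": expected 9 columns, got ", length(f))
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    if (e < s) stop("GFF3 line ", i, ": end < start")
  }
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  attr_field <- function(attr, key) {
    m <- regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]*"), attr))
    out <- rep(NA_character_, length(attr))
    hit <- lengths(regmatches(attr, gregexpr(paste0("(^|;)", key, "=[^;]*"),
                                             attr))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  ann <- data.frame(type = as.character(g$type),
                    chrom = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,  # -> 0-based half-open
                    end = as.integer(g$end),
                    strand = as.character(g$strand),
                    id = attr_field(as.character(g$attributes), "ID"),
                    parent = attr_field(as.character(g$attributes), "Parent"),
                    stringsAsFactors = FALSE)
  ann$strand[is.na(ann$strand)] <- "+"
  class(ann) <- c("annotation_set", "data.frame")
  ann
}

#' Read a genetic-map marker table
#'
#' @param path TSV with header \code{chrom\tbp\tcM}
#' @return data.frame of markers; at least 5 per chromosome are required for
#'   quartic map fitting, which is checked at fit time
#' @export
read_marker_table <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(m)))
    stop("marker table must have header chrom, bp, cM")
  if (any(m$cM < 0)) stop("negative cM positions in marker table")
  m[need]
}

#' Read a callable-sites BED track
#' @param path BED3 path (0-based half-open)
#' @return named list per chromosome of data.frames (start, end)
#' @export
read_callable_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  split(data.frame(start = as.integer(b$start), end = as.integer(b$end)),
        b$chrom)
}

#' Write stage outputs to a directory
#'
#' Window statistics become BED-compatible TSVs (0-based half-open), trees
#' newick files, matrices TSVs. Output is byte-stable for identical inputs.
#'
#' @param results named list; elements may be data.frames, matrices, or
#'   \code{phylo} trees
#' @param out_dir output directory (created if needed)
#' @return character vector of files written
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "phylo")) {
      f <- file.path(out_dir, paste0(nm, ".nwk"))
      ape::write.tree(x, file = f)
    } else if (is.matrix(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- as.data.frame(x)
      df <- cbind(data.frame(id = rownames(x) %||% seq_len(nrow(x))), df)
      data.table::fwrite(df, f, sep = "\t")
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      data.table::fwrite(x, f, sep = "\t")
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    files <- c(files, f)
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read FASTQ read pairs
#'
#' @param path1,path2 mate FASTQ files
#' @return list of pairs; each pair is a list of two reads, each a list with
#'   \code{seq} (character) and \code{qual} (integer phred vector)
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p) {
    x <- Biostrings::readQualityScaledDNAStringSet(p)
    q <- as(Biostrings::quality(x), "IntegerList")
    lapply(seq_along(x), function(i)
      list(seq = as.character(x[[i]]), qual = as.integer(q[[i]])))
  }
  r1 <- rd(path1); r2 <- rd(path2)
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  Map(function(a, b) list(a, b), r1, r2)
}

#' Write FASTQ read pairs
#' @param pairs list of read pairs as returned by \code{read_fastq_pairs}
#' @param path1,path2 output mate FASTQ files
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  wr <- function(reads, p) {
    lines <- unlist(lapply(seq_along(reads), function(i) {
      r <- reads[[i]]
      c(paste0("@read", i), r$seq, "+",
        intToUtf8(pmin(r$qual, 93L) + 33L, multiple = FALSE))
    }))
    writeLines(lines, p)
  }
  wr(lapply(pairs, `[[`, 1L), path1)
  wr(lapply(pairs, `[[`, 2L), path2)
  invisible(NULL)
}
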