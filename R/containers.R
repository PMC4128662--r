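# Internal coordinate convention: 0-based half-open everywhere. VCF and GFF3
# are converted at the format boundary and nowhere else.

MISSING_CALL <- NA_integer_

#' Construct a reference genome object
#'
#' @param sequences named character vector of chromosome sequences
#'   (A/C/G/T/N). Names must be unique; sequences are uppercased.
#' @return An object of class \code{reference_genome} with elements
#'   \code{names}, \code{seq} (named character vector) and \code{lengths}.
#' @export
reference_genome <- function(sequences) {
  if (length(sequences) == 0L) stop("reference has no sequences")
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "")) stop("all chromosomes must be named")
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate chromosome name: ", dup[1L])
  seqs <- toupper(as.character(sequences))
  names(seqs) <- nm
  structure(list(names = nm, seq = seqs,
                 lengths = stats::setNames(nchar(seqs), nm)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$names), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Construct a haploid genotype matrix
#'
#' Calls are integer allele indices (0 = reference allele) with \code{NA}
#' for missing. Positions are 0-based and must be strictly increasing within
#' each chromosome.
#'
#' @param samples character vector of sample IDs (n >= 2)
#' @param sites data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt} (comma-separated alternate alleles, "" if none)
#'   and \code{qual}
#' @param calls integer matrix, n samples x S sites
#' @param depth optional integer matrix of per-call read depth (n x S)
#' @param het optional logical matrix flagging calls loaded from heterozygous
#'   genotypes (treated as erroneous in a haploid and masked downstream)
#' @return object of class \code{genotype_matrix}
#' @export
genotype_matrix <- function(samples, sites, calls, depth = NULL, het = NULL) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  if (!is.matrix(calls) || nrow(calls) != n || ncol(calls) != nrow(sites))
    stop("calls must be an n x S matrix matching samples and sites")
  storage.mode(calls) <- "integer"
  rownames(calls) <- samples
  if (!is.null(depth)) rownames(depth) <- samples
  if (!is.null(het)) rownames(het) <- samples
  sites$chrom <- as.character(sites$chrom)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  structure(list(samples = samples, sites = sites, calls = calls,
                 depth = depth, het = het),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites on %d chromosome(s)\n",
              length(x$samples), nrow(x$sites), length(unique(x$sites$chrom))))
  invisible(x)
}

n_samples <- function(x) length(x$samples)
n_sites <- function(x) nrow(x$sites)

#' Alleles observed at a site
#'
#' @param gm genotype_matrix
#' @param i site index
#' @return character vector: reference allele followed by alternates
#' @export
site_alleles <- function(gm, i) {
  alt <- gm$sites$alt[i]
  if (is.na(alt) || alt == "" || alt == ".") return(gm$sites$ref[i])
  c(gm$sites$ref[i], strsplit(alt, ",", fixed = TRUE)[[1L]])
}

#' Construct an analysis matrix
#'
#' The complete-site matrix used by every downstream statistic: polymorphic
#' sites with a call in every sample, plus a callable track giving the
#' monomorphic called sites needed for per-site denominators.
#'
#' @param gm genotype_matrix restricted to complete polymorphic sites
#' @param callable named list (per chromosome) of data.frames with
#'   \code{start}, \code{end} (0-based half-open) giving the called-site
#'   intervals
#' @param chrom_lengths named integer vector of chromosome lengths
#' @return object of class \code{analysis_matrix} (also a
#'   \code{genotype_matrix})
#' @export
analysis_matrix <- function(gm, callable, chrom_lengths) {
  if (anyNA(gm$calls)) stop("analysis matrix must not contain missing calls")
  gm$callable <- lapply(callable, function(iv) {
    iv <- iv[order(iv$start), , drop = FALSE]
    data.frame(start = as.integer(iv$start), end = as.integer(iv$end))
  })
  gm$chrom_lengths <- chrom_lengths
  gm$called_sites <- vapply(gm$callable, function(iv) sum(iv$end - iv$start), 0)
  class(gm) <- c("analysis_matrix", "genotype_matrix")
  gm
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat(sprintf(
    "analysis_matrix: %d samples, %d SNPs, %s called sites on %d chromosome(s)\n",
    length(x$samples), nrow(x$sites),
    format(sum(x$called_sites), big.mark = ","), length(x$callable)))
  invisible(x)
}

#' Total called sites per chromosome (or overall)
#' @param am analysis_matrix
#' @param chrom optional chromosome name
#' @export
called_sites <- function(am, chrom = NULL) {
  if (is.null(chrom)) sum(am$called_sites) else am$called_sites[[chrom]]
}

# intersect a callable track (list of start/end data.frames) with a window
callable_in_window <- function(am, chrom, start, end) {
  iv <- am$callable[[chrom]]
  if (is.null(iv) || nrow(iv) == 0L) return(0L)
  s <- pmax(iv$start, start); e <- pmin(iv$end, end)
  sum(pmax(0L, e - s))
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
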