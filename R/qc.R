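# Read-level filters, genotype-call filters and site masks, ending in the
# complete-site analysis matrix.

#' Filter paired-end reads on base quality and composition
#'
#' Applies, in order: (1) trimming of both ends until a run of >= 10
#' consecutive bases with phred >= 30 begins; (2) removal of the 3' region
#' from position 150 (then 200) onward when that region holds >= 10\% bases
#' with phred < 20; (3) removal of reads with >= 10\% bases below phred 20
#' overall; (4) trimming of supplied adapter sequences; (5) removal of reads
#' shorter than \code{min_len}; (6) removal of single-base-composition reads,
#' reads with >= 3 consecutive undetermined bases, and pairs where one read
#' is the reverse complement of its mate; (7) removal of the surviving mate
#' when one read of a pair is dropped.
#'
#' @param pairs list of read pairs (see \code{\link{read_fastq_pairs}})
#' @param adapters character vector of adapter sequences to trim (exact
#'   match; the read is cut from the match start)
#' @param min_len minimum surviving read length (default 45)
#' @param trim_qual phred threshold for the end-trimming run (default 30)
#' @param trim_run run length required to stop end trimming (default 10)
#' @param region_cutoffs 3'-region start positions checked in turn
#' @param low_qual phred threshold counted as low quality (default 20)
#' @param low_frac fraction of low-quality bases that triggers removal
#' @return filtered list of read pairs
#' @export
filter_reads <- function(pairs, adapters = character(0), min_len = 45L,
                         trim_qual = 30L, trim_run = 10L,
                         region_cutoffs = c(150L, 200L),
                         low_qual = 20L, low_frac = 0.10) {
  keep <- logical(length(pairs))
  out <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    p <- lapply(pairs[[k]], filter_one_read,
                adapters = adapters, min_len = min_len,
                trim_qual = trim_qual, trim_run = trim_run,
                region_cutoffs = region_cutoffs,
                low_qual = low_qual, low_frac = low_frac)
    ok <- !vapply(p, is.null, TRUE)
    if (all(ok)) {
      # pair-level check: one read equal to the mate's reverse complement
      if (identical(p[[1L]]$seq, reverse_complement(p[[2L]]$seq))) next
      out[[k]] <- p
      keep[k] <- TRUE
    }
  }
  out[keep]
}

filter_one_read <- function(r, adapters, min_len, trim_qual, trim_run,
                            region_cutoffs, low_qual, low_frac) {
  q <- r$qual
  if (any(q < 0L) || any(q > 93L)) stop("phred scores outside 0..93: unknown encoding")
  # (1) end trimming to the first/last run of trim_run bases >= trim_qual
  ok <- q >= trim_qual
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  good <- which(runs$values & runs$lengths >= trim_run)
  if (length(good) == 0L) return(NULL)
  from <- ends[good[1L]] - runs$lengths[good[1L]] + 1L
  to <- ends[good[length(good)]]
  s <- substr(r$seq, from, to)
  q <- q[from:to]
  # (2) 3'-region rule at each cutoff in turn
  for (cut in sort(region_cutoffs)) {
    if (nchar(s) >= cut) {
      reg <- q[cut:length(q)]
      if (mean(reg < low_qual) >= low_frac) {
        s <- substr(s, 1L, cut - 1L)
        q <- q[seq_len(cut - 1L)]
      }
    }
  }
  # (3) whole-read low-quality fraction
  if (mean(q < low_qual) >= low_frac) return(NULL)
  # (4) adapter trimming: cut from the leftmost exact match to the read end
  for (ad in adapters) {
    if (nzchar(ad)) {
      i <- regexpr(ad, s, fixed = TRUE)
      if (i > 0L) {
        s <- substr(s, 1L, i - 1L)
        q <- q[seq_len(i - 1L)]
      }
    }
  }
  # (5) length
  if (nchar(s) < min_len) return(NULL)
  # (6) composition checks
  ch <- unique(strsplit(s, "")[[1L]])
  if (length(ch) == 1L) return(NULL)
  if (grepl("NNN", s, fixed = TRUE)) return(NULL)
  list(seq = s, qual = q)
}

#' Filter genotype calls on quality and depth
#'
#' A call becomes missing when the site quality is below \code{min_qual},
#' the per-call depth is below \code{min_depth} or above the per-sample
#' upper bound, or the call was loaded from a heterozygous genotype (treated
#' as an error in a haploid).
#'
#' The depth upper bound follows \code{depth_rule}: \code{"mean_plus_3sd"}
#' (default) uses mean + \code{depth_sd_factor} * SD of each sample's depth;
#' \code{"literal_3sd"} uses \code{depth_sd_factor} * SD as an absolute cap.
#'
#' @param gm genotype_matrix with qual and depth
#' @param min_qual minimum site quality (default 30)
#' @param min_depth minimum per-call depth (default 10)
#' @param depth_sd_factor multiplier on the per-sample depth SD (default 3)
#' @param depth_rule upper-bound rule, see Details
#' @return genotype_matrix with failing calls set to missing
#' @export
filter_calls <- function(gm, min_qual = 30, min_depth = 10,
                         depth_sd_factor = 3,
                         depth_rule = c("mean_plus_3sd", "literal_3sd")) {
  depth_rule <- match.arg(depth_rule)
  calls <- gm$calls
  badsite <- !is.na(gm$sites$qual) & gm$sites$qual < min_qual
  calls[, badsite] <- NA_integer_
  if (!is.null(gm$depth)) {
    d <- gm$depth
    calls[!is.na(d) & d < min_depth] <- NA_integer_
    mu <- rowMeans(d, na.rm = TRUE)
    sdv <- apply(d, 1L, stats::sd, na.rm = TRUE)
    bound <- switch(depth_rule,
                    mean_plus_3sd = mu + depth_sd_factor * sdv,
                    literal_3sd = depth_sd_factor * sdv)
    over <- !is.na(d) & d > bound[row(d)]
    calls[over] <- NA_integer_
  }
  if (!is.null(gm$het)) calls[gm$het] <- NA_integer_
  gm$calls <- calls
  gm
}

#' Build the site mask for repeats, indel flanks and masked features
#'
#' Masks maximal homopolymer runs longer than 9 bases, maximal di- and
#' trinucleotide tandem repeats of more than 5 units, each with
#' \code{flank} bp up- and downstream; \code{flank} bp around each indel
#' anchor; and all transposable-element, centromere and telomere features.
#'
#' @param reference reference_genome
#' @param annotation optional annotation_set supplying feature masks
#' @param indel_positions optional data.frame (chrom, pos) of 0-based indel
#'   anchor positions
#' @param flank flank width in bp (default 10)
#' @return \code{site_mask}: data.frame (chrom, start, end, reason)
#' @export
build_site_mask <- function(reference, annotation = NULL,
                            indel_positions = NULL, flank = 10L) {
  res <- list()
  for (ch in reference$names) {
    L <- reference$lengths[[ch]]
    x <- strsplit(reference$seq[[ch]], "")[[1L]]
    iv <- list()
    # (a) homopolymers: maximal runs of length > 9
    r <- rle(x)
    e <- cumsum(r$lengths); s <- e - r$lengths
    hp <- r$lengths > 9L
    if (any(hp))
      iv[["homopolymer"]] <- cbind(s[hp], e[hp])
    # (b,c) period-p tandem repeats with > 5 complete units
    for (p in c(2L, 3L)) {
      reason <- if (p == 2L) "dimer_repeat" else "trimer_repeat"
      if (L > p) {
        eq <- x[seq_len(L - p)] == x[(p + 1L):L]
        rr <- rle(eq)
        ee <- cumsum(rr$lengths); ss <- ee - rr$lengths
        run <- which(rr$values)
        if (length(run)) {
          reg_s <- ss[run]; reg_e <- ee[run] + p  # region length = run + p
          units <- (reg_e - reg_s) %/% p
          k <- units > 5L
          if (any(k)) iv[[reason]] <- cbind(reg_s[k], reg_e[k])
        }
      }
    }
    rows <- lapply(names(iv), function(rsn) {
      m <- iv[[rsn]]
      data.frame(chrom = ch,
                 start = pmax(0L, m[, 1L] - flank),
                 end = pmin(L, m[, 2L] + flank),
                 reason = rsn, stringsAsFactors = FALSE)
    })
    res[[ch]] <- do.call(rbind, rows)
  }
  mask <- do.call(rbind, res)
  if (!is.null(indel_positions) && nrow(indel_positions) > 0L) {
    L <- reference$lengths[as.character(indel_positions$chrom)]
    mask <- rbind(mask, data.frame(
      chrom = as.character(indel_positions$chrom),
      start = pmax(0L, indel_positions$pos - flank),
      end = pmin(as.integer(L), indel_positions$pos + flank + 1L),
      reason = "indel_flank", stringsAsFactors = FALSE))
  }
  if (!is.null(annotation)) {
    feat <- annotation[annotation$type %in%
                         c("transposable_element", "centromere", "telomere"), ]
    if (nrow(feat))
      mask <- rbind(mask, data.frame(chrom = feat$chrom, start = feat$start,
                                     end = feat$end, reason = feat$type,
                                     stringsAsFactors = FALSE))
  }
  if (is.null(mask))
    mask <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), reason = character(0))
  rownames(mask) <- NULL
  class(mask) <- c("site_mask", "data.frame")
  mask
}

#' Union of mask intervals per chromosome
#' @param mask site_mask
#' @return named list per chromosome of data.frames (start, end), disjoint
#'   and sorted
#' @export
mask_union <- function(mask) {
  if (nrow(mask) == 0L) return(list())
  lapply(split(mask, mask$chrom), function(m) {
    ir <- IRanges::reduce(IRanges::IRanges(start = m$start + 1L, end = m$end))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
}

subtract_intervals <- function(iv, sub) {
  # iv, sub: data.frames (start, end), 0-based half-open; returns iv \ sub
  a <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  b <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
  d <- IRanges::setdiff(a, b)
  data.frame(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

positions_in_intervals <- function(pos, iv) {
  # logical: which 0-based positions fall inside intervals (start,end)
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  IRanges::overlapsAny(q, ir)
}

#' Apply the site mask and restrict to complete sites
#'
#' Drops sites inside the mask union and sites where any sample is missing,
#' and assembles the callable track that supplies monomorphic-site
#' denominators. The callable track is taken from \code{callable} (a BED-style
#' list) when given; otherwise every record of \code{gm} with a full set of
#' calls counts as callable, which is the all-sites-VCF path.
#'
#' @param gm call-filtered genotype_matrix
#' @param mask site_mask (or NULL for no masking)
#' @param reference reference_genome (for chromosome lengths)
#' @param callable optional callable track, as from
#'   \code{\link{read_callable_bed}}
#' @return \code{analysis_matrix}
#' @export
apply_mask_and_complete <- function(gm, mask = NULL, reference,
                                    callable = NULL) {
  mu <- if (is.null(mask) || nrow(mask) == 0L) list() else mask_union(mask)
  if (length(mu) && !all(names(mu) %in% reference$names))
    stop("mask references unknown chromosome: ",
         setdiff(names(mu), reference$names)[1L])
  complete <- !matrixStats_colAnyNA(gm$calls)
  masked <- rep(FALSE, n_sites(gm))
  for (ch in names(mu)) {
    i <- gm$sites$chrom == ch
    masked[i] <- positions_in_intervals(gm$sites$pos[i], mu[[ch]])
  }
  keep <- complete & !masked
  # polymorphic among kept records: any call differing from the first sample
  diff1 <- colSums(gm$calls != gm$calls[rep(1L, nrow(gm$calls)), ,
                                        drop = FALSE], na.rm = TRUE)
  poly <- keep & diff1 > 0L
  if (is.null(callable)) {
    # callable = positions of complete unmasked records
    track <- lapply(split(gm$sites$pos[keep], gm$sites$chrom[keep]),
                    function(p) {
                      ir <- IRanges::reduce(IRanges::IRanges(start = p + 1L,
                                                             width = 1L))
                      data.frame(start = IRanges::start(ir) - 1L,
                                 end = IRanges::end(ir))
                    })
  } else {
    track <- lapply(names(callable), function(ch) {
      iv <- callable[[ch]]
      if (!is.null(mu[[ch]])) iv <- subtract_intervals(iv, mu[[ch]])
      # records failing completeness are not callable either
      badpos <- gm$sites$pos[gm$sites$chrom == ch & !complete]
      if (length(badpos))
        iv <- subtract_intervals(iv, data.frame(start = badpos,
                                                end = badpos + 1L))
      iv
    })
    names(track) <- names(callable)
  }
  sub <- genotype_matrix(gm$samples, gm$sites[poly, , drop = FALSE],
                         gm$calls[, poly, drop = FALSE],
                         depth = if (!is.null(gm$depth)) gm$depth[, poly, drop = FALSE],
                         het = NULL)
  am <- analysis_matrix(sub, track, reference$lengths)
  am$n_input_sites <- n_sites(gm)
  am$n_retained_sites <- sum(keep)
  am$n_monomorphic <- sum(keep & diff1 == 0L)
  am
}

matrixStats_colAnyNA <- function(m) colSums(is.na(m)) > 0L
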