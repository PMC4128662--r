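# Nucleotide diversity, Tajima's D, allele-frequency spectra, sliding-window
# scans and between-group divergence.

# per-site average pairwise difference proportion (general k-allele form)
pi_per_site <- function(calls) {
  n <- nrow(calls)
  if (ncol(calls) == 0L) return(numeric(0))
  npairs <- n * (n - 1) / 2
  vals <- sort(unique(as.vector(calls)))
  same <- 0
  for (a in vals) {
    ca <- colSums(calls == a)
    same <- same + ca * (ca - 1) / 2
  }
  1 - same / npairs
}

#' Nucleotide diversity
#'
#' Mean over called sites of the pairwise difference proportion. Monomorphic
#' called sites contribute zero to the numerator but count in the
#' denominator, so \code{n_called} must include them.
#'
#' @param calls haploid call matrix (samples x polymorphic sites), no missing
#' @param n_called total number of called sites (monomorphic + polymorphic);
#'   defaults to the number of columns of \code{calls}
#' @return per-site nucleotide diversity (a fraction)
#' @export
nucleotide_diversity <- function(calls, n_called = ncol(calls)) {
  if (n_called < 1L) stop("zero called sites")
  sum(pi_per_site(calls)) / n_called
}

# Window layout: full windows anchored at 0 advancing by `step`; when they
# do not reach the chromosome end, one final partial window with its true
# extent. A 100 kb chromosome at 20 kb/4 kb yields 21 windows (0..80 kb).
window_bounds <- function(L, size, step) {
  if (L <= size) return(data.frame(start = 0L, end = L))
  starts <- seq.int(0L, L - size, by = step)
  ends <- starts + size
  last <- starts[length(starts)]
  if (last + size < L) {
    starts <- c(starts, last + step)
    ends <- c(ends, L)
  }
  data.frame(start = starts, end = ends)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standardized difference of the pairwise-diversity and segregating-sites
#' estimators of the population mutation rate. Undefined (NA) when no site
#' segregates.
#'
#' @param calls haploid call matrix (samples x sites), no missing; columns
#'   may include monomorphic sites, which are ignored
#' @return Tajima's D, or NA when S = 0
#' @export
tajimas_d <- function(calls) {
  ps <- pi_per_site(calls)
  seg <- ps > 0
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  n <- nrow(calls)
  k <- tajima_constants(n)
  theta_pi <- sum(ps)          # mean pairwise differences
  theta_w <- S / k$a1
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (!is.finite(denom) || denom <= 0) return(NA_real_)  # degenerate at n = 3
  (theta_pi - theta_w) / denom
}

#' Sliding-window diversity scan
#'
#' Windows are anchored at position 0 of each chromosome and advanced by
#' \code{step}; the final partial window is emitted with its true extent.
#' Defaults follow the genome-scan scale of 20 kb windows with 4 kb steps.
#'
#' @param am analysis_matrix
#' @param size window size in bp (default 20000)
#' @param step window step in bp (default 4000)
#' @param site_filter optional logical vector over the SNP sites of \code{am}
#'   restricting which polymorphic sites enter the statistics
#' @return data.frame of class \code{window_stat}: chrom, start, end,
#'   n_called, n_snps, pi, tajimas_d
#' @export
window_scan <- function(am, size = 20000L, step = 4000L, site_filter = NULL) {
  stopifnot(size > 0L, step > 0L, step <= size)
  out <- list()
  keep <- site_filter %||% rep(TRUE, n_sites(am))
  for (ch in names(am$chrom_lengths)) {
    L <- am$chrom_lengths[[ch]]
    wb <- window_bounds(L, size, step)
    i_ch <- which(am$sites$chrom == ch & keep)
    pos <- am$sites$pos[i_ch]
    ps <- pi_per_site(am$calls[, i_ch, drop = FALSE])
    n <- length(am$samples)
    k <- tajima_constants(n)
    res <- lapply(seq_len(nrow(wb)), function(wi) {
      s <- wb$start[wi]; e <- wb$end[wi]
      inw <- i_ch[pos >= s & pos < e]
      psw <- ps[pos >= s & pos < e]
      ncall <- callable_in_window(am, ch, s, e)
      S <- sum(psw > 0)
      piw <- if (ncall > 0L) sum(psw) / ncall else NA_real_
      D <- if (S > 0L) {
        (sum(psw) - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
      } else NA_real_
      data.frame(chrom = ch, start = s, end = e, n_called = ncall,
                 n_snps = length(inw), pi = piw, tajimas_d = D,
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, res)
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  class(w) <- c("window_stat", "data.frame")
  w
}

#' Folded minor-allele-frequency spectrum
#'
#' Counts polymorphic sites by minor-allele count 1..floor(n/2). At
#' multiallelic sites the count of the most common non-major allele is used
#' and the site is flagged. With \code{collapse_group}, a set of samples is
#' treated as a single sample and sites varying within the set are dropped.
#'
#' @param am analysis_matrix
#' @param site_filter optional logical vector over SNP sites
#' @param collapse_group optional character or integer vector of samples to
#'   collapse into one
#' @return list with \code{counts} (named vector over 1..floor(n/2)),
#'   \code{n} (effective sample size) and \code{n_multiallelic}
#' @export
minor_allele_spectrum <- function(am, site_filter = NULL,
                                  collapse_group = NULL) {
  calls <- am$calls
  keep <- site_filter %||% rep(TRUE, ncol(calls))
  calls <- calls[, keep, drop = FALSE]
  if (!is.null(collapse_group)) {
    g <- if (is.character(collapse_group)) match(collapse_group, am$samples)
         else as.integer(collapse_group)
    if (anyNA(g)) stop("unknown sample in collapse_group")
    within_var <- colSums(calls[g, , drop = FALSE] !=
                          calls[rep(g[1L], length(g)), , drop = FALSE]) > 0L
    calls <- rbind(calls[g[1L], !within_var, drop = FALSE],
                   calls[-g, !within_var, drop = FALSE])
  }
  n <- nrow(calls)
  nmax <- n %/% 2L
  counts <- stats::setNames(integer(nmax), seq_len(nmax))
  n_multi <- 0L
  for (j in seq_len(ncol(calls))) {
    tab <- sort(table(calls[, j]), decreasing = TRUE)
    if (length(tab) < 2L) next
    if (length(tab) > 2L) n_multi <- n_multi + 1L
    mac <- min(as.integer(tab[2L]), nmax)
    counts[mac] <- counts[mac] + 1L
  }
  list(counts = counts, n = n, n_multiallelic = n_multi)
}

#' Between-group divergence scan (Dxy)
#'
#' Per window, Dxy is the mean over cross-group sample pairs of the per-site
#' difference proportion; within-group diversity of \code{group_b} is
#' reported as a control.
#'
#' @param am analysis_matrix
#' @param group_a,group_b disjoint sample sets (names or indices)
#' @param size,step window size and step in bp (defaults 200/40, the
#'   fine-scale divergence scan)
#' @return window_stat data.frame with added \code{dxy} and \code{pi_b}
#' @export
group_divergence <- function(am, group_a, group_b, size = 200L, step = 40L) {
  ia <- resolve_samples(am, group_a)
  ib <- resolve_samples(am, group_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty group")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  calls <- am$calls
  vals <- sort(unique(as.vector(calls)))
  match_ab <- 0
  for (a in vals) {
    ca <- colSums(calls[ia, , drop = FALSE] == a)
    cb <- colSums(calls[ib, , drop = FALSE] == a)
    match_ab <- match_ab + ca * cb
  }
  dxy_site <- 1 - match_ab / (length(ia) * length(ib))
  pib_site <- pi_per_site(calls[ib, , drop = FALSE])
  out <- list()
  for (ch in names(am$chrom_lengths)) {
    L <- am$chrom_lengths[[ch]]
    wb <- window_bounds(L, size, step)
    i_ch <- which(am$sites$chrom == ch)
    pos <- am$sites$pos[i_ch]
    res <- lapply(seq_len(nrow(wb)), function(wi) {
      s <- wb$start[wi]; e <- wb$end[wi]
      inw <- pos >= s & pos < e
      ncall <- callable_in_window(am, ch, s, e)
      data.frame(chrom = ch, start = s, end = e, n_called = ncall,
                 n_snps = sum(inw),
                 dxy = if (ncall > 0L) sum(dxy_site[i_ch][inw]) / ncall else NA_real_,
                 pi_b = if (ncall > 0L) sum(pib_site[i_ch][inw]) / ncall else NA_real_,
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, res)
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  class(w) <- c("window_stat", "data.frame")
  w
}

resolve_samples <- function(am, g) {
  if (is.character(g)) {
    i <- match(g, am$samples)
    if (anyNA(i)) stop("unknown sample: ", g[which(is.na(i))[1L]])
    i
  } else as.integer(g)
}

#' Per-gene synonymous and nonsynonymous diversity
#'
#' Nei-Gojobori gene-level summary: fractional synonymous/nonsynonymous site
#' counts averaged over samples, pathway-averaged pairwise difference counts
#' averaged over sample pairs, and Tajima's D over the gene's called CDS
#' sites. Genes are flagged eligible when more than
#' \code{min_syn_sites} synonymous sites could be analyzed.
#'
#' @param gene_id gene identifier present in \code{class_map}
#' @param am analysis_matrix
#' @param class_map site_class_map from \code{\link{classify_sites}}
#' @param min_syn_sites eligibility threshold on synonymous sites (default
#'   200)
#' @return data.frame row: gene, chrom, start, end, syn_sites, nonsyn_sites,
#'   pi_s, pi_n, ratio, tajimas_d, eligible
#' @export
gene_diversity <- function(gene_id, am, class_map, min_syn_sites = 200) {
  gd <- gene_codon_summary(gene_id, am, class_map)
  if (is.null(gd)) stop("gene has no analyzable codons: ", gene_id)
  pi_s <- if (gd$syn_sites > 0) gd$syn_diffs / gd$syn_sites else NA_real_
  pi_n <- if (gd$nonsyn_sites > 0) gd$nonsyn_diffs / gd$nonsyn_sites else NA_real_
  ratio <- if (!is.na(pi_s) && pi_s > 0) pi_n / pi_s else NA_real_
  D <- tajimas_d(am$calls[, gd$cds_snp_idx, drop = FALSE])
  data.frame(gene = gene_id, chrom = gd$chrom, start = gd$start, end = gd$end,
             syn_sites = gd$syn_sites, nonsyn_sites = gd$nonsyn_sites,
             pi_s = pi_s, pi_n = pi_n, ratio = ratio, tajimas_d = D,
             eligible = gd$syn_sites > min_syn_sites,
             stringsAsFactors = FALSE)
}
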