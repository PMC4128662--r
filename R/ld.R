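# Pairwise r^2, LD-decay binning, the expected decay curve and least-squares
# estimation of the population recombination rate rho = 4Nr.

#' Pairwise r-squared between SNPs
#'
#' For every within-chromosome SNP pair with both minor-allele frequencies
#' at least \code{maf_min} and separation at most \code{max_dist}:
#' r^2 = D^2 / (pA(1-pA) pB(1-pB)) with D = pAB - pA pB. Multiallelic sites
#' are reduced to major-vs-rest and flagged.
#'
#' @param am analysis_matrix
#' @param maf_min minimum minor-allele frequency (default 0.10)
#' @param max_dist maximum pair separation in bp (default 500000)
#' @param chunk internal column chunk size
#' @return data.frame: chrom, dist, r2, multiallelic (logical: either member)
#' @export
pairwise_r2 <- function(am, maf_min = 0.10, max_dist = 500000L,
                        chunk = 512L) {
  out <- list()
  for (ch in unique(am$sites$chrom)) {
    i_ch <- which(am$sites$chrom == ch)
    calls <- am$calls[, i_ch, drop = FALSE]
    pos <- am$sites$pos[i_ch]
    n <- nrow(calls)
    X <- matrix(0, n, ncol(calls))
    multi <- logical(ncol(calls))
    for (j in seq_len(ncol(calls))) {
      tab <- table(calls[, j])
      multi[j] <- length(tab) > 2L
      major <- as.integer(names(tab)[which.max(tab)])
      X[, j] <- as.numeric(calls[, j] != major)
    }
    f <- colMeans(X)
    okmaf <- pmin(f, 1 - f) >= maf_min
    X <- X[, okmaf, drop = FALSE]
    pos <- pos[okmaf]
    multi <- multi[okmaf]
    S <- ncol(X)
    if (S < 2L) next
    dist_l <- list(); r2_l <- list(); multi_l <- list()
    for (s0 in seq.int(1L, S, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, S)
      aa <- s0:s1
      jmax <- pmin(findInterval(pos[aa] + max_dist, pos), S)
      npart <- pmax(0L, jmax - aa)
      if (sum(npart) == 0L) next
      hi <- max(jmax)
      cc <- suppressWarnings(stats::cor(X[, aa, drop = FALSE],
                                        X[, s0:hi, drop = FALSE]))
      a_rep <- rep.int(aa, npart)
      jj <- sequence(npart, from = aa + 1L)
      r <- cc[cbind(a_rep - s0 + 1L, jj - s0 + 1L)]
      k <- length(dist_l) + 1L
      dist_l[[k]] <- pos[jj] - pos[a_rep]
      r2_l[[k]] <- r^2
      multi_l[[k]] <- multi[a_rep] | multi[jj]
    }
    if (length(dist_l))
      out[[ch]] <- data.frame(chrom = ch, dist = unlist(dist_l),
                              r2 = unlist(r2_l),
                              multiallelic = unlist(multi_l))
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), dist = integer(0),
                      r2 = numeric(0), multiallelic = logical(0)))
  if (length(out) == 1L) {
    r <- out[[1L]]
  } else {
    r <- data.frame(chrom = rep(names(out), vapply(out, nrow, 0L)),
                    dist = unlist(lapply(out, `[[`, "dist")),
                    r2 = unlist(lapply(out, `[[`, "r2")),
                    multiallelic = unlist(lapply(out, `[[`, "multiallelic")))
  }
  rownames(r) <- NULL
  r
}

#' Bin LD decay by distance
#'
#' @param pairs data.frame from \code{\link{pairwise_r2}}
#' @param bin_size bin width in bp (default 1000); bins are half-open
#'   [k*bin, (k+1)*bin)
#' @return data.frame of class \code{ld_decay}: bin_start, bin_mid,
#'   mean_r2, n_pairs
#' @export
bin_ld_decay <- function(pairs, bin_size = 1000L) {
  if (nrow(pairs) == 0L) stop("no SNP pairs to bin")
  b <- as.integer(pairs$dist %/% bin_size)
  nb <- max(b) + 1L
  cnt_all <- tabulate(b + 1L, nbins = nb)
  sums_all <- as.vector(rowsum(pairs$r2, b, reorder = TRUE))
  bk <- sort(unique(b))
  cnt <- cnt_all[bk + 1L]
  out <- data.frame(bin_start = bk * bin_size,
                    bin_mid = bk * bin_size + bin_size / 2,
                    mean_r2 = sums_all / cnt, n_pairs = cnt)
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' Expected r-squared decay with scaled recombination distance
#'
#' The drift expectation sigma_d^2(C) = (10 + C) / (22 + 13 C + C^2) for
#' C = rho * distance. The optional finite-sample adjustment adds 1/n.
#'
#' @param C non-negative scaled recombination distance rho * d
#' @param n sample size for the finite-sample adjustment (used only when
#'   \code{adjust = TRUE})
#' @param adjust apply the 1/n adjustment (default FALSE)
#' @return expected r^2
#' @export
expected_r2 <- function(C, n = NULL, adjust = FALSE) {
  if (any(C < 0)) stop("C must be non-negative")
  v <- (10 + C) / (22 + 13 * C + C^2)
  if (adjust) {
    if (is.null(n)) stop("n required when adjust = TRUE")
    v <- v + 1 / n
  }
  v
}

#' Estimate the population recombination rate from LD decay
#'
#' Least squares of per-bin mean r^2 against \code{expected_r2(rho * mid)}
#' over bins whose midpoint lies within the fit range, weighting bins by
#' pair count (the default). One-dimensional bounded minimization over
#' rho >= 0 on a log scale.
#'
#' @param decay ld_decay data.frame
#' @param fit_min,fit_max fit range in bp (defaults 1000 and 100000)
#' @param weighted weight bins by pair count (default TRUE)
#' @param n,adjust passed to \code{\link{expected_r2}}
#' @return list of class \code{rho_estimate}: rho (per bp), fit range,
#'   rss, n_pairs, n_bins
#' @export
estimate_rho <- function(decay, fit_min = 1000, fit_max = 100000,
                         weighted = TRUE, n = NULL, adjust = FALSE) {
  use <- decay$bin_mid >= fit_min & decay$bin_mid <= fit_max
  if (sum(use) < 3L) stop("fewer than 3 decay bins in the fit range")
  mid <- decay$bin_mid[use]
  obs <- decay$mean_r2[use]
  w <- if (weighted) decay$n_pairs[use] else rep(1, sum(use))
  obj <- function(log10rho) {
    rho <- 10^log10rho
    sum(w * (obs - expected_r2(rho * mid, n = n, adjust = adjust))^2)
  }
  opt <- stats::optimize(obj, interval = c(-12, 0), tol = 1e-10)
  rho <- 10^opt$minimum
  structure(list(rho = rho, fit_min = fit_min, fit_max = fit_max,
                 rss = opt$objective, n_pairs = sum(decay$n_pairs[use]),
                 n_bins = sum(use)),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho_estimate: 4Nr = %.3g per bp (fit %g-%g bp, %d bins, %d pairs)\n",
              x$rho, x$fit_min, x$fit_max, x$n_bins, x$n_pairs))
  invisible(x)
}
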