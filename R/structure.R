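# Population structure: p-distances, neighbor-joining, distance-thinned SNP
# subsetting, PCA.

#' Pairwise p-distance matrix
#'
#' Proportion of called sites at which two samples differ; monomorphic
#' called sites contribute to the denominator only.
#'
#' @param am analysis_matrix
#' @return symmetric n x n matrix with zero diagonal, sample labels as
#'   dimnames
#' @export
p_distance_matrix <- function(am) {
  calls <- am$calls
  n <- nrow(calls)
  vals <- sort(unique(as.vector(calls)))
  same <- matrix(0, n, n)
  for (a in vals) {
    ind <- (calls == a) * 1
    same <- same + tcrossprod(ind)
  }
  mism <- ncol(calls) - same
  d <- mism / called_sites(am)
  diag(d) <- 0
  dimnames(d) <- list(am$samples, am$samples)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration as implemented in \pkg{ape}; branch lengths are
#' reported as computed (negative NJ branch lengths are possible).
#'
#' @param d symmetric distance matrix with sample labels
#' @return \code{phylo} tree (unrooted)
#' @export
neighbor_joining <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  ape::nj(stats::as.dist(d))
}

#' Whether a sample set forms a clan of an unrooted tree
#'
#' A clan is a monophyletic group under some rooting; equivalently the set
#' is one side of an edge bipartition.
#'
#' @param tree phylo
#' @param samples tip labels
#' @return logical
#' @export
is_clan <- function(tree, samples) {
  out <- setdiff(tree$tip.label, samples)
  if (length(out) == 0L || length(samples) < 2L) return(TRUE)
  rooted <- ape::root(tree, outgroup = out[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, samples)
}

#' Distance-thinned SNP subset
#'
#' Per chromosome: the first SNP is drawn uniformly among SNPs within
#' \code{spacing} bp of the 5'-most SNP; thereafter the closest SNP at least
#' \code{spacing} bp downstream of the previous pick is taken, until the
#' chromosome end.
#'
#' @param am analysis_matrix
#' @param spacing minimum spacing in bp (default 50000)
#' @param seed RNG seed (picking the first SNP is the only random step)
#' @return integer indices into the SNP sites of \code{am}
#' @export
thin_snps <- function(am, spacing = 50000L, seed = 1L) {
  set.seed(seed)
  picks <- integer(0)
  for (ch in unique(am$sites$chrom)) {
    i_ch <- which(am$sites$chrom == ch)
    if (length(i_ch) == 0L) next
    pos <- am$sites$pos[i_ch]
    first_window <- which(pos <= pos[1L] + spacing)
    cur <- first_window[sample.int(length(first_window), 1L)]
    picks <- c(picks, i_ch[cur])
    repeat {
      nxt <- which(pos >= pos[cur] + spacing)
      if (length(nxt) == 0L) break
      cur <- nxt[1L]
      picks <- c(picks, i_ch[cur])
    }
  }
  picks
}

#' Principal component analysis of haploid genotypes
#'
#' Genotypes are encoded 0/1 as major/non-major allele per SNP, columns are
#' centered (no variance scaling by default) and the sample covariance is
#' eigendecomposed. Component signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param am analysis_matrix
#' @param snp_idx optional SNP index subset (e.g. from
#'   \code{\link{thin_snps}})
#' @param scale. logical: divide each SNP column by its standard deviation
#'   (default FALSE)
#' @return list with \code{eigenvalues}, \code{coords} (samples x
#'   components) and \code{var_explained}
#' @export
pca_genotypes <- function(am, snp_idx = NULL, scale. = FALSE) {
  idx <- snp_idx %||% seq_len(n_sites(am))
  if (length(idx) < 2L) stop("need at least 2 SNPs")
  calls <- am$calls[, idx, drop = FALSE]
  X <- matrix(0, nrow(calls), ncol(calls))
  for (j in seq_len(ncol(calls))) {
    tab <- table(calls[, j])
    major <- as.integer(names(tab)[which.max(tab)])
    X[, j] <- as.numeric(calls[, j] != major)
  }
  const <- apply(X, 2L, function(v) length(unique(v)) == 1L)
  if (all(const)) {
    ev <- rep(0, min(dim(X)))
    coords <- matrix(0, nrow(X), length(ev),
                     dimnames = list(am$samples, NULL))
    return(list(eigenvalues = ev, coords = coords,
                var_explained = rep(NA_real_, length(ev))))
  }
  if (any(const)) {
    warning(sum(const), " constant SNP column(s) dropped")
    X <- X[, !const, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  for (k in seq_len(ncol(p$rotation))) {
    s <- sign(p$rotation[which.max(abs(p$rotation[, k])), k])
    if (s < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  ev <- p$sdev^2
  rownames(p$x) <- am$samples
  list(eigenvalues = ev, coords = p$x, var_explained = ev / sum(ev))
}
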