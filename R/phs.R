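# Pairwise haplotype sharing (PHS) test: genetic-map fitting, identity-tract
# extraction, per-pair tract-length moments, the PHS statistic and candidate
# selection.
#
# For an allele A carried by n_A samples at position x,
#   PHS_A(x) = sum_{carrier pairs} Z_ijx / C(n_A,2)
#            - sum_{all pairs}     Z_ijx / C(n,2),
# where Z_ijx = (d_ijx - dbar_ij) / sigma_ij, d_ijx is the genetic length
# (cM) of the identity tract of pair (i,j) spanning x, and dbar_ij, sigma_ij
# are the genome-wide mean and standard deviation of that pair's tract
# lengths. Long shared haplotypes among carriers give PHS > 0.

#' Fit a per-chromosome genetic map
#'
#' Least-squares polynomial (degree 4 by default) of genetic position (cM)
#' against physical position (bp) per chromosome. Evaluation outside the
#' marker range clamps to the boundary values; a fit that decreases anywhere
#' on a 1-kb grid within range is repaired to its running maximum and
#' flagged.
#'
#' @param markers data.frame (chrom, bp, cM), at least degree+1 markers per
#'   chromosome
#' @param degree polynomial degree (default 4)
#' @param grid_bp monotonicity-check grid spacing (default 1000)
#' @return object of class \code{genetic_map}
#' @export
fit_genetic_map <- function(markers, degree = 4L, grid_bp = 1000L) {
  maps <- lapply(split(markers, markers$chrom), function(m) {
    if (nrow(m) < degree + 1L)
      stop("need at least ", degree + 1L, " markers per chromosome")
    rng <- range(m$bp)
    span <- max(rng[2L] - rng[1L], 1)
    # fit on unit-scaled coordinates: raw bp powers are numerically
    # rank-deficient for megabase chromosomes
    u <- (m$bp - rng[1L]) / span
    fit <- stats::lm(m$cM ~ stats::poly(u, degree, raw = TRUE))
    cf <- unname(stats::coef(fit))
    cf[is.na(cf)] <- 0
    grid <- unique(c(seq(rng[1L], rng[2L], by = grid_bp), rng[2L]))
    vals <- polyval(cf, (grid - rng[1L]) / span)
    repaired <- any(diff(vals) < -1e-9)
    list(coef = cf, range = rng, span = span, repaired = repaired,
         grid = if (repaired) grid, grid_cM = if (repaired) cummax(vals))
  })
  structure(maps, class = "genetic_map")
}

polyval <- function(cf, x) {
  v <- 0
  for (k in rev(seq_along(cf))) v <- v * x + cf[k]
  v
}

#' Evaluate a genetic map
#'
#' @param map genetic_map
#' @param chrom chromosome name
#' @param bp physical positions (clamped to the marker range)
#' @return genetic positions in cM
#' @export
map_position <- function(map, chrom, bp) {
  m <- map[[chrom]]
  if (is.null(m)) stop("no genetic map for chromosome ", chrom)
  x <- pmin(pmax(bp, m$range[1L]), m$range[2L])
  if (m$repaired)
    stats::approx(m$grid, m$grid_cM, xout = x, rule = 2)$y
  else polyval(m$coef, (x - m$range[1L]) / m$span)
}

# Gap cut pairs (>= miss_cluster_bp with no called site) per chromosome:
# each row (left, right) = last called position before the gap, first called
# position after it.
missing_cluster_cuts <- function(am, chrom, miss_cluster_bp) {
  iv <- am$callable[[chrom]]
  if (is.null(iv) || nrow(iv) < 2L)
    return(matrix(numeric(0), ncol = 2L))
  gl <- iv$end[-nrow(iv)] - 1L
  gr <- iv$start[-1L]
  big <- (gr - gl - 1L) >= miss_cluster_bp
  cbind(gl[big], gr[big])
}

# Tracts of one pair on one chromosome. disc: sorted discordant positions.
# Returns data.frame(start, end) of tract bounds (exclusive boundary
# positions; chromosome bounds 0 and L).
build_tracts <- function(disc, gaps, L) {
  bounds <- sort(unique(c(0, disc, as.vector(gaps), L)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  if (nrow(gaps)) {
    ingap <- paste(starts, ends) %in% paste(gaps[, 1L], gaps[, 2L])
    starts <- starts[!ingap]; ends <- ends[!ingap]
  }
  data.frame(start = starts, end = ends)
}

#' Identity tracts of a sample pair
#'
#' Maximal intervals over which the pair's calls agree at every compared
#' site. Tract boundaries are the flanking discordant positions (exclusive)
#' or the chromosome ends; any stretch of \code{miss_cluster_bp} or more
#' without a called site also terminates tracts at its edges.
#'
#' @param am analysis_matrix
#' @param pair two sample names or indices
#' @param map genetic_map for tract genetic lengths
#' @param miss_cluster_bp missing-cluster termination threshold (default
#'   30000)
#' @return data.frame: chrom, start, end, genetic_length (cM)
#' @export
pairwise_identity_tracts <- function(am, pair, map,
                                     miss_cluster_bp = 30000L) {
  ij <- resolve_samples(am, pair)
  if (length(ij) != 2L) stop("pair must name exactly 2 samples")
  out <- list()
  for (ch in names(am$chrom_lengths)) {
    i_ch <- which(am$sites$chrom == ch)
    disc <- am$sites$pos[i_ch][am$calls[ij[1L], i_ch] != am$calls[ij[2L], i_ch]]
    gaps <- missing_cluster_cuts(am, ch, miss_cluster_bp)
    tr <- build_tracts(disc, gaps, am$chrom_lengths[[ch]])
    tr$genetic_length <- map_position(map, ch, tr$end) -
      map_position(map, ch, tr$start)
    tr <- cbind(chrom = ch, tr)
    out[[ch]] <- tr
  }
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Genome-wide tract-length moments of a pair
#'
#' @param tracts data.frame from \code{\link{pairwise_identity_tracts}} (or
#'   a numeric vector of genetic lengths)
#' @return list: mean, sd (population SD), n_tracts, flagged (TRUE when the
#'   pair has fewer than 2 tracts or zero variance; its Z contributions are
#'   taken as 0)
#' @export
pair_tract_moments <- function(tracts) {
  d <- if (is.data.frame(tracts)) tracts$genetic_length else as.numeric(tracts)
  m <- length(d)
  if (m < 2L)
    return(list(mean = if (m) mean(d) else NA_real_, sd = NA_real_,
                n_tracts = m, flagged = TRUE))
  mu <- mean(d)
  sdv <- sqrt(mean((d - mu)^2))
  list(mean = mu, sd = sdv, n_tracts = m, flagged = sdv == 0)
}

# Internal: per-pair standardized tract length at every SNP site.
# Returns list(Z = npairs x S matrix, pairs = 2-column index matrix).
phs_z_matrix <- function(am, map, miss_cluster_bp = 30000L) {
  n <- length(am$samples)
  pr <- t(utils::combn(n, 2L))
  npairs <- nrow(pr)
  S <- n_sites(am)
  Z <- matrix(0, npairs, S)
  chroms <- names(am$chrom_lengths)
  chrom_idx <- lapply(chroms, function(ch) which(am$sites$chrom == ch))
  names(chrom_idx) <- chroms
  gaps_by_ch <- lapply(chroms, missing_cluster_cuts, am = am,
                       miss_cluster_bp = miss_cluster_bp)
  names(gaps_by_ch) <- chroms
  for (r in seq_len(npairs)) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    tl_all <- numeric(0)
    per_ch <- list()
    for (ch in chroms) {
      idx <- chrom_idx[[ch]]
      pos <- am$sites$pos[idx]
      disc <- pos[am$calls[i, idx] != am$calls[j, idx]]
      tr <- build_tracts(disc, gaps_by_ch[[ch]], am$chrom_lengths[[ch]])
      gl <- map_position(map, ch, tr$end) - map_position(map, ch, tr$start)
      tl_all <- c(tl_all, gl)
      ti <- findInterval(pos, tr$start)
      d_x <- gl[ti]
      d_x[pos %in% disc] <- 0
      per_ch[[ch]] <- d_x
    }
    mom <- pair_tract_moments(tl_all)
    if (!mom$flagged)
      for (ch in chroms)
        Z[r, chrom_idx[[ch]]] <- (per_ch[[ch]] - mom$mean) / mom$sd
  }
  list(Z = Z, pairs = pr)
}

#' PHS statistic for one allele at one site
#'
#' Computed from scratch: tracts of every pair spanning the site, genome-wide
#' moments, standardization, and the difference of carrier-pair and all-pair
#' means. For a pair discordant at the site, the spanning tract has genetic
#' length 0.
#'
#' @param chrom,pos focal site (0-based position, must be a site of
#'   \code{am})
#' @param allele allele index at the site (0 = reference)
#' @param am analysis_matrix
#' @param map genetic_map
#' @param miss_cluster_bp missing-cluster threshold (default 30000)
#' @return PHS value
#' @export
phs_statistic <- function(chrom, pos, allele, am, map,
                          miss_cluster_bp = 30000L) {
  s <- which(am$sites$chrom == chrom & am$sites$pos == pos)
  if (length(s) != 1L) stop("site not found: ", chrom, ":", pos)
  carriers <- which(am$calls[, s] == allele)
  if (length(carriers) < 2L) stop("allele needs at least 2 carriers")
  zx <- phs_z_matrix(am, map, miss_cluster_bp)
  z <- zx$Z[, s]
  in_carrier <- zx$pairs[, 1L] %in% carriers & zx$pairs[, 2L] %in% carriers
  mean(z[in_carrier]) - mean(z)
}

#' Genome scan of the PHS statistic
#'
#' Computes PHS for every allele with at least \code{min_carriers} carriers
#' at every SNP, and flags candidates in the top \code{top_fraction} of PHS
#' values. With \code{ranking = "frequency"} (default) candidates are ranked
#' within carrier-count classes, since allele frequency strongly shapes the
#' null distribution of PHS; \code{"global"} ranks all records together.
#'
#' @param am analysis_matrix
#' @param map genetic_map
#' @param top_fraction candidate fraction (default 0.001)
#' @param min_carriers minimum carriers per scored allele (default 2)
#' @param miss_cluster_bp missing-cluster threshold (default 30000)
#' @param ranking "frequency" or "global"
#' @return data.frame of class \code{phs_scan}: chrom, pos (0-based),
#'   pos1 (1-based output convention), allele (index), base, n_carriers, p,
#'   phs, candidate
#' @export
phs_scan <- function(am, map, top_fraction = 0.001, min_carriers = 2L,
                     miss_cluster_bp = 30000L,
                     ranking = c("frequency", "global")) {
  ranking <- match.arg(ranking)
  n <- length(am$samples)
  zx <- phs_z_matrix(am, map, miss_cluster_bp)
  Z <- zx$Z
  # pair-row lookup by sample pair
  rowof <- matrix(0L, n, n)
  rowof[zx$pairs] <- seq_len(nrow(zx$pairs))
  rowof[zx$pairs[, c(2L, 1L)]] <- seq_len(nrow(zx$pairs))
  zbar <- colMeans(Z)
  recs <- vector("list", n_sites(am))
  for (s in seq_len(n_sites(am))) {
    g <- am$calls[, s]
    tab <- table(g)
    vals <- as.integer(names(tab))[tab >= min_carriers]
    if (length(vals) == 0L) next
    alle <- site_alleles(am, s)
    rs <- lapply(vals, function(a) {
      carriers <- which(g == a)
      cp <- utils::combn(carriers, 2L)
      pr <- rowof[cbind(cp[1L, ], cp[2L, ])]
      data.frame(chrom = am$sites$chrom[s], pos = am$sites$pos[s],
                 allele = a,
                 base = if (a + 1L <= length(alle)) alle[a + 1L] else NA_character_,
                 n_carriers = length(carriers), p = length(carriers) / n,
                 phs = mean(Z[pr, s]) - zbar[s],
                 stringsAsFactors = FALSE)
    })
    recs[[s]] <- do.call(rbind, rs)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no allele with enough carriers")
  grp <- if (ranking == "frequency") out$n_carriers else rep(1L, nrow(out))
  out$candidate <- FALSE
  for (gval in unique(grp)) {
    k <- which(grp == gval)
    rk <- rank(-out$phs[k], ties.method = "first")
    out$candidate[k] <- rk <= ceiling(top_fraction * length(k))
  }
  out$pos1 <- out$pos + 1L
  rownames(out) <- NULL
  class(out) <- c("phs_scan", "data.frame")
  out
}
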