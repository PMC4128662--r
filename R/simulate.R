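# Block-coalescent simulator: haploid populations, references, annotations
# and marker tables with known truth.
#
# Chromosomes are partitioned into linkage blocks whose boundaries arise as
# a Poisson process with rate rho/2 per bp; each block carries one
# independent coalescent genealogy, optionally with a designated clade
# forced monophyletic below a deep split. Mutations are placed as a Poisson
# process of rate theta/2 per site per unit branch length, so that
# E(pi) = theta and E(S) = theta * a1 * L under neutrality.
#
# The turnover rate is proportional to rho; the constant 1/2 reflects that
# a block boundary decorrelates genealogies completely while a single
# ancestral recombination event does so only partially: matching the
# exponential block-survival decay of r^2 to the drift expectation
# sigma_d^2(rho * d) over the 1-100 kb fit range fixes the constant near
# one half.

#' Simulation configuration
#'
#' @param n sample size (default 32)
#' @param chrom_lengths named integer vector of chromosome lengths (default
#'   one 1 Mb chromosome)
#' @param theta per-site population mutation rate (default 0.003, echoing a
#'   genome-wide diversity of about 0.3\%)
#' @param rho per-site population recombination rate (default theta/100)
#' @param clade optional integer vector of samples forced monophyletic
#' @param clade_depth coalescent-time depth of the clade split (default 4;
#'   roughly twice the expected neutral TMRCA)
#' @param seed RNG seed
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n = 32L, chrom_lengths = c(chr1 = 1000000L),
                       theta = 0.003, rho = theta / 100, clade = NULL,
                       clade_depth = 4, seed = 1L) {
  stopifnot(theta >= 0, rho >= 0, n >= 2L)
  if (!is.null(clade)) {
    clade <- as.integer(clade)
    stopifnot(all(clade >= 1L), all(clade <= n), length(clade) >= 2L)
  }
  structure(list(n = as.integer(n), chrom_lengths = chrom_lengths,
                 theta = theta, rho = rho, clade = clade,
                 clade_depth = clade_depth, seed = as.integer(seed)),
            class = "sim_config")
}

# One Kingman coalescent for the tip set `tips`; returns list(branches =
# list of (tips, len), height). Times in units where a pair coalesces at
# rate 1 (E[T2] = 1, E[pairwise branch path] = 2).
coalesce_tips <- function(tips) {
  k <- length(tips)
  active <- lapply(tips, identity)
  born <- rep(0, k)
  t <- 0
  branches <- list()
  while (length(active) > 1L) {
    m <- length(active)
    t <- t + stats::rexp(1L, m * (m - 1) / 2)
    pick <- sample.int(m, 2L)
    for (q in pick)
      branches[[length(branches) + 1L]] <-
        list(tips = active[[q]], len = t - born[q])
    merged <- c(active[[pick[1L]]], active[[pick[2L]]])
    active <- c(active[-pick], list(merged))
    born <- c(born[-pick], t)
  }
  list(branches = branches, height = t, root_tips = active[[1L]])
}

# Coalescent genealogy for n samples, optionally with a forced clade split.
sim_genealogy <- function(n, clade = NULL, clade_depth = 4) {
  if (is.null(clade)) return(coalesce_tips(seq_len(n))$branches)
  a <- coalesce_tips(clade)
  b <- coalesce_tips(setdiff(seq_len(n), clade))
  tj <- max(clade_depth, a$height + 0.1, b$height + 0.1)
  c(a$branches, b$branches,
    list(list(tips = a$root_tips, len = tj - a$height),
         list(tips = b$root_tips, len = tj - b$height)))
}

#' Simulate a haploid population with known truth
#'
#' @param config sim_config
#' @param reference optional reference_genome to mutate on; generated as
#'   random sequence when absent
#' @return list: reference, matrix (genotype_matrix), truth (list with
#'   per-chromosome realized pi, S, block boundaries, clade)
#' @export
simulate_population <- function(config, reference = NULL) {
  set.seed(config$seed)
  n <- config$n
  samples <- sprintf("s%02d", seq_len(n))
  if (is.null(reference)) {
    seqs <- vapply(config$chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1L))
    reference <- reference_genome(seqs)
  }
  sites_l <- list(); calls_l <- list()
  truth <- list(clade = config$clade, blocks = list(), S = integer(0),
                pi = numeric(0))
  for (ch in names(config$chrom_lengths)) {
    L <- as.integer(config$chrom_lengths[[ch]])
    nbreak <- stats::rpois(1L, config$rho / 2 * L)
    breaks <- sort(sample.int(L - 1L, min(nbreak, L - 1L)))
    bounds <- c(0L, breaks, L)
    pos_all <- integer(0); der_all <- list()
    for (b in seq_len(length(bounds) - 1L)) {
      blen <- bounds[b + 1L] - bounds[b]
      if (blen == 0L) next
      branches <- sim_genealogy(n, config$clade, config$clade_depth)
      lens <- vapply(branches, `[[`, 0, "len")
      tot <- sum(lens)
      nmut <- stats::rpois(1L, config$theta / 2 * blen * tot)
      if (nmut == 0L) next
      bidx <- sample.int(length(branches), nmut, replace = TRUE,
                         prob = lens)
      mpos <- bounds[b] + sample.int(blen, nmut, replace = TRUE) - 1L
      pos_all <- c(pos_all, mpos)
      der_all <- c(der_all, lapply(bidx, function(q) branches[[q]]$tips))
    }
    ord <- order(pos_all)
    pos_all <- pos_all[ord]; der_all <- der_all[ord]
    refbases <- strsplit(reference$seq[[ch]], "")[[1L]]
    upos <- unique(pos_all)
    calls <- matrix(0L, n, length(upos))
    alts <- vector("list", length(upos))
    jv <- match(pos_all, upos)
    for (k in seq_along(pos_all)) {
      j <- jv[k]
      # each mutation introduces a new derived allele for its carriers;
      # when all four bases are in use the mutation reuses an existing one
      avail <- setdiff(c("A", "C", "G", "T"),
                       c(refbases[pos_all[k] + 1L], alts[[j]]))
      if (length(avail)) {
        alts[[j]] <- c(alts[[j]], avail[sample.int(length(avail), 1L)])
        newallele <- length(alts[[j]])
      } else {
        newallele <- sample.int(length(alts[[j]]), 1L)
      }
      calls[der_all[[k]], j] <- newallele
    }
    # drop sites that ended monomorphic (overwritten to one allele)
    poly <- apply(calls, 2L, function(v) length(unique(v)) > 1L)
    upos <- upos[poly]; calls <- calls[, poly, drop = FALSE]
    alts <- alts[poly]
    sites_l[[ch]] <- data.frame(
      chrom = rep(ch, length(upos)), pos = upos,
      ref = refbases[upos + 1L],
      alt = vapply(alts, paste, character(1L), collapse = ","),
      qual = rep(99, length(upos)), stringsAsFactors = FALSE)
    calls_l[[ch]] <- calls
    truth$blocks[[ch]] <- bounds
    truth$S[[ch]] <- length(upos)
  }
  sites <- do.call(rbind, sites_l)
  rownames(sites) <- NULL
  calls <- do.call(cbind, calls_l)
  gm <- genotype_matrix(samples, sites, calls)
  truth$pi <- sum(pi_per_site(calls)) / sum(config$chrom_lengths)
  list(reference = reference, matrix = gm, truth = truth)
}

#' Convert a simulated genotype matrix to an analysis matrix
#'
#' Every position of every chromosome counts as callable (the simulator
#' emits complete calls).
#'
#' @param sim output of \code{\link{simulate_population}} (or a list with
#'   \code{reference} and \code{matrix})
#' @return analysis_matrix
#' @export
as_analysis_matrix <- function(sim) {
  ref <- sim$reference
  callable <- lapply(ref$names, function(ch)
    data.frame(start = 0L, end = ref$lengths[[ch]]))
  names(callable) <- ref$names
  analysis_matrix(sim$matrix, callable, ref$lengths)
}

#' Inject a partial selective sweep
#'
#' Replaces the calls of all carriers inside the interval by the first
#' carrier's haplotype, creating a shared identical haplotype block.
#'
#' @param gm genotype_matrix
#' @param carriers sample indices (>= 2)
#' @param interval list or vector (chrom, start, end), 0-based half-open
#' @return genotype_matrix with an attached \code{sweep} attribute
#' @export
inject_partial_sweep <- function(gm, carriers, interval) {
  carriers <- as.integer(carriers)
  if (length(carriers) < 1L) stop("empty carrier set")
  ch <- as.character(interval[[1L]])
  s <- as.numeric(interval[[2L]]); e <- as.numeric(interval[[3L]])
  in_iv <- gm$sites$chrom == ch & gm$sites$pos >= s & gm$sites$pos < e
  gm$calls[carriers, in_iv] <-
    gm$calls[rep(carriers[1L], length(carriers)), in_iv]
  attr(gm, "sweep") <- list(carriers = carriers, chrom = ch, start = s, end = e)
  gm
}

#' Inject a locally divergent segment
#'
#' Each position in the interval acquires, with probability
#' \code{divergence}, a new derived allele shared by every clade member,
#' emulating a region of elevated between-group divergence.
#'
#' @param gm genotype_matrix
#' @param clade sample indices (a strict, non-empty subset)
#' @param interval (chrom, start, end), 0-based half-open
#' @param divergence per-site substitution probability in (0,1)
#' @param reference reference_genome (for new-site reference bases)
#' @param seed RNG seed
#' @return genotype_matrix with attached \code{divergent} attribute holding
#'   the realized between-group dxy over the interval
#' @export
inject_divergent_segment <- function(gm, clade, interval, divergence,
                                     reference, seed = 1L) {
  stopifnot(divergence > 0, divergence < 1)
  clade <- as.integer(clade)
  n <- length(gm$samples)
  if (length(clade) == 0L || length(clade) == n)
    stop("clade must be a strict, non-empty subset of samples")
  set.seed(seed)
  ch <- as.character(interval[[1L]])
  s <- as.integer(interval[[2L]]); e <- as.integer(interval[[3L]])
  hit <- s + which(stats::runif(e - s) < divergence) - 1L
  refbases <- strsplit(reference$seq[[ch]], "")[[1L]]
  for (p in hit) {
    j <- which(gm$sites$chrom == ch & gm$sites$pos == p)
    if (length(j) == 1L) {
      alts <- site_alleles(gm, j)[-1L]
      newb <- sample(setdiff(c("A", "C", "G", "T"),
                             c(gm$sites$ref[j], alts)), 1L)
      gm$sites$alt[j] <- paste(c(alts, newb), collapse = ",")
      gm$calls[clade, j] <- length(alts) + 1L
    } else {
      refb <- refbases[p + 1L]
      newb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      newsite <- data.frame(chrom = ch, pos = p, ref = refb, alt = newb,
                            qual = 99, stringsAsFactors = FALSE)
      newcall <- rep(0L, n); newcall[clade] <- 1L
      ins <- findInterval(p, gm$sites$pos[gm$sites$chrom == ch])
      ci <- which(gm$sites$chrom == ch)
      at <- if (ins == 0L) min(ci) - 1L else ci[ins]
      gm$sites <- rbind(gm$sites[seq_len(at), , drop = FALSE], newsite,
                        gm$sites[seq_len(nrow(gm$sites)) > at, , drop = FALSE])
      rownames(gm$sites) <- NULL
      gm$calls <- cbind(gm$calls[, seq_len(at), drop = FALSE], newcall,
                        gm$calls[, seq_len(ncol(gm$calls)) > at, drop = FALSE])
    }
  }
  dimnames(gm$calls) <- list(gm$samples, NULL)
  # realized dxy over the interval (denominator = interval length)
  in_iv <- gm$sites$chrom == ch & gm$sites$pos >= s & gm$sites$pos < e
  other <- setdiff(seq_len(n), clade)
  sub <- gm$calls[, in_iv, drop = FALSE]
  diffs <- 0
  for (a in sort(unique(as.vector(sub)))) {
    ca <- colSums(sub[clade, , drop = FALSE] == a)
    cb <- colSums(sub[other, , drop = FALSE] == a)
    diffs <- diffs + sum(ca * cb)
  }
  dxy <- 1 - diffs / (length(clade) * length(other) * (e - s)) -
    (1 - sum(in_iv) / (e - s))  # monomorphic interval sites match fully
  attr(gm, "divergent") <- list(clade = clade, chrom = ch, start = s, end = e,
                                target = divergence,
                                realized_dxy = dxy, n_injected = length(hit))
  gm
}
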