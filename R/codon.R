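# Nei-Gojobori (1986) synonymous/nonsynonymous site counting and
# pathway-averaged difference counting between codons.

GENETIC_CODE_TABLE <- {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  # T,C,A,G nested order: first base slowest, third fastest
  codons <- as.vector(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  stats::setNames(aa, codons)
}

translate_codon <- function(codon) unname(GENETIC_CODE_TABLE[codon])

is_stop_codon <- function(codon) translate_codon(codon) == "*"

#' Synonymous and nonsynonymous site counts for a codon
#'
#' Nei-Gojobori counting: at each codon position the synonymous fraction is
#' the share of the three possible single-base changes that preserve the
#' amino acid. Changes creating a stop codon count as nonsynonymous, so the
#' fractions at each position sum to 1 and the two site counts sum to 3.
#'
#' @param codon 3-base character string of unambiguous bases, not a stop
#' @return named numeric vector \code{c(syn, nonsyn)} with \code{syn + nonsyn
#'   = 3}
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% names(GENETIC_CODE_TABLE))
    stop("not an unambiguous codon: ", codon)
  if (is_stop_codon(codon)) stop("stop codon has no site counts: ", codon)
  codon_sites_lookup(codon)
}

# lazy per-codon cache of c(syn, nonsyn); NULL for stop codons
codon_sites_lookup <- function(codon) {
  hit <- .ng_env$sites[[codon]]
  if (is.null(hit)) {
    if (!codon %in% names(GENETIC_CODE_TABLE) || is_stop_codon(codon))
      return(NULL)
    hit <- compute_codon_sites(codon)
    .ng_env$sites[[codon]] <- hit
  }
  hit
}

.ng_env <- new.env(parent = emptyenv())
.ng_env$sites <- list()
.ng_env$fracs <- list()
.ng_env$diffs <- list()

compute_codon_sites <- function(codon) {
  aa <- translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (translate_codon(mut) == aa) syn <- syn + 1 / 3
      # stops and other amino acids are nonsynonymous
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

sense_codons <- function()
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Codons differing at d positions are compared along all d! single-step
#' mutational pathways; pathways passing through a stop codon are excluded
#' and the remainder re-weighted. If every pathway passes through a stop,
#' the d nucleotide differences are split equally between the two classes.
#'
#' @param codonA,codonB sense codons
#' @return list with \code{syn_diffs}, \code{nonsyn_diffs} (summing to the
#'   number of differing positions) and \code{n_pathways} used
#' @export
codon_pair_differences <- function(codonA, codonB) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  for (cd in c(codonA, codonB)) {
    if (!cd %in% names(GENETIC_CODE_TABLE)) stop("not a codon: ", cd)
    if (is_stop_codon(cd)) stop("stop codon not allowed: ", cd)
  }
  key <- paste0(codonA, codonB)
  hit <- .ng_env$diffs[[key]]
  if (!is.null(hit)) return(hit)
  diff_pos <- which(strsplit(codonA, "")[[1L]] != strsplit(codonB, "")[[1L]])
  d <- length(diff_pos)
  if (d == 0L) {
    res <- list(syn_diffs = 0, nonsyn_diffs = 0, n_pathways = 1L)
  } else {
    perms <- permutations_of(diff_pos)
    syn_tot <- 0; nonsyn_tot <- 0; used <- 0L
    for (ord in perms) {
      cur <- codonA
      syn <- 0; nonsyn <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(codonB, pos, pos)
        if (is_stop_codon(nxt)) { ok <- FALSE; break }
        if (translate_codon(nxt) == translate_codon(cur)) syn <- syn + 1
        else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      if (ok) {
        syn_tot <- syn_tot + syn
        nonsyn_tot <- nonsyn_tot + nonsyn
        used <- used + 1L
      }
    }
    if (used == 0L) {
      # all pathways blocked by stops: split the raw differences equally
      res <- list(syn_diffs = d / 2, nonsyn_diffs = d / 2, n_pathways = 0L)
    } else {
      res <- list(syn_diffs = syn_tot / used, nonsyn_diffs = nonsyn_tot / used,
                  n_pathways = used)
    }
  }
  .ng_env$diffs[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}
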