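# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals: the genetic
# code comes from Biostrings, and all statistics are direct summations.

oracle_pi <- function(calls, n_called = ncol(calls)) {
  n <- nrow(calls)
  tot <- 0
  for (s in seq_len(ncol(calls))) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (calls[i, s] != calls[j, s]) tot <- tot + 1
    }
  }
  tot / choose(n, 2) / n_called
}

oracle_tajimas_d <- function(calls) {
  n <- nrow(calls)
  seg <- apply(calls, 2L, function(v) length(unique(v)) > 1L)
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  k <- 0
  for (s in which(seg)) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (calls[i, s] != calls[j, s]) k <- k + 1
  }
  k <- k / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1L)); a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

oracle_ng_sites <- function(codon) {
  aa <- oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, pos, pos))) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (oracle_translate(mut) == aa) syn <- syn + 1 / 3
  }
  c(syn = syn, nonsyn = 3 - syn)
}

oracle_ng_pathways <- function(cA, cB) {
  dp <- which(strsplit(cA, "")[[1]] != strsplit(cB, "")[[1]])
  if (length(dp) == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(dp) == 1L) list(dp) else {
    pm <- list()
    rec <- function(left, acc) {
      if (!length(left)) pm[[length(pm) + 1L]] <<- acc
      for (q in seq_along(left)) rec(left[-q], c(acc, left[q]))
    }
    rec(dp, integer(0))
    pm
  }
  syn_t <- 0; non_t <- 0; used <- 0
  for (ord in perms) {
    cur <- cA; syn <- 0; non <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cB, p, p)
      if (oracle_translate(nxt) == "*") { ok <- FALSE; break }
      if (oracle_translate(nxt) == oracle_translate(cur)) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    if (ok) { syn_t <- syn_t + syn; non_t <- non_t + non; used <- used + 1 }
  }
  if (used == 0) return(c(syn = length(dp) / 2, nonsyn = length(dp) / 2))
  c(syn = syn_t / used, nonsyn = non_t / used)
}

oracle_sense_codons <- function() {
  cods <- names(Biostrings::GENETIC_CODE)
  cods[Biostrings::GENETIC_CODE != "*"]
}

# random complete haploid matrix with at least one segregating site
random_calls <- function(n, S, k_alleles = 2L) {
  repeat {
    m <- matrix(sample.int(k_alleles, n * S, replace = TRUE) - 1L, n, S)
    if (any(apply(m, 2L, function(v) length(unique(v)) > 1L))) return(m)
  }
}

# analysis matrix over one chromosome with every position callable
toy_analysis_matrix <- function(calls, pos, L, chrom = "chr1",
                                samples = sprintf("s%02d", seq_len(nrow(calls)))) {
  alt <- vapply(seq_along(pos), function(j) {
    k <- max(calls[, j])
    if (k == 0L) "" else paste(c("C", "G", "T")[seq_len(k)], collapse = ",")
  }, character(1L))
  sites <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A",
                      alt = alt, qual = 99, stringsAsFactors = FALSE)
  gm <- genotype_matrix(samples, sites, calls)
  callable <- stats::setNames(list(data.frame(start = 0L, end = as.integer(L))),
                              chrom)
  analysis_matrix(gm, callable, stats::setNames(as.integer(L), chrom))
}

# Naive PHS at one site: recompute every pair's tract from scratch by
# outward scans from the focal site, and moments by walking the full
# discordance list per pair.
oracle_phs <- function(am, map, chrom, pos, allele,
                       miss_cluster_bp = 30000L) {
  n <- length(am$samples)
  i_ch_all <- split(seq_len(nrow(am$sites)), am$sites$chrom)
  cuts_of <- function(i, j, ch) {
    idx <- i_ch_all[[ch]]
    p <- am$sites$pos[idx]
    p[am$calls[i, idx] != am$calls[j, idx]]
  }
  gap_edges <- function(ch) {
    iv <- am$callable[[ch]]
    if (is.null(iv) || nrow(iv) < 2L) return(NULL)
    gl <- iv$end[-nrow(iv)] - 1L; gr <- iv$start[-1L]
    keep <- (gr - gl - 1L) >= miss_cluster_bp
    if (!any(keep)) return(NULL)
    cbind(gl[keep], gr[keep])
  }
  tract_lengths <- function(i, j) {
    lens <- numeric(0)
    for (ch in names(am$chrom_lengths)) {
      L <- am$chrom_lengths[[ch]]
      b <- sort(unique(c(0, cuts_of(i, j, ch), L)))
      ge <- gap_edges(ch)
      if (!is.null(ge)) b <- sort(unique(c(b, as.vector(ge))))
      ss <- b[-length(b)]; ee <- b[-1L]
      if (!is.null(ge)) {
        drop <- paste(ss, ee) %in% paste(ge[, 1L], ge[, 2L])
        ss <- ss[!drop]; ee <- ee[!drop]
      }
      lens <- c(lens, map_position(map, ch, ee) - map_position(map, ch, ss))
    }
    lens
  }
  tract_at <- function(i, j, ch, x) {
    d <- cuts_of(i, j, ch)
    if (x %in% d) return(0)
    L <- am$chrom_lengths[[ch]]
    b <- sort(unique(c(0, d, L)))
    ge <- gap_edges(ch)
    if (!is.null(ge)) b <- sort(unique(c(b, as.vector(ge))))
    lo <- max(b[b <= x]); hi <- min(b[b > x])
    map_position(map, ch, hi) - map_position(map, ch, lo)
  }
  s <- which(am$sites$chrom == chrom & am$sites$pos == pos)
  carriers <- which(am$calls[, s] == allele)
  zsum_all <- 0; zsum_car <- 0; np_car <- 0; np_all <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    lens <- tract_lengths(i, j)
    mu <- mean(lens); sdv <- sqrt(mean((lens - mu)^2))
    z <- if (length(lens) < 2L || sdv == 0) 0
         else (tract_at(i, j, chrom, pos) - mu) / sdv
    zsum_all <- zsum_all + z; np_all <- np_all + 1L
    if (i %in% carriers && j %in% carriers) {
      zsum_car <- zsum_car + z; np_car <- np_car + 1L
    }
  }
  zsum_car / np_car - zsum_all / np_all
}
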