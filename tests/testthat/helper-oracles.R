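# Independent oracles, implemented separately from the package internals.

# --- NG86 difference counting by depth-first path enumeration ----------
# Recursively walks every mutational path between two codons (choosing
# any remaining differing position at each step), discarding paths that
# visit a stop codon at an intermediate state, and averages the
# synonymous/nonsynonymous step counts over surviving paths.
oracle_codon_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  walk <- function(cur, allow_stop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && nxt %in% stops && nxt != c2) next
      syn <- if (nxt %in% stops || cur %in% stops) FALSE else
        code[[nxt]] == code[[cur]]
      for (rest in walk(nxt, allow_stop))
        out[[length(out) + 1L]] <-
          rest + if (syn) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
    }
    out
  }
  paths <- walk(c1, allow_stop = FALSE)
  if (!length(paths)) paths <- walk(c1, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

# --- Fisher exact p by enumeration over fixed margins ------------------
oracle_fisher_p <- function(tab) {
  r <- rowSums(tab); c <- colSums(tab); n <- sum(tab)
  p_obs <- stats::dhyper(tab[1, 1], c[1], c[2], r[1])
  x <- 0:min(r[1], c[1])
  probs <- stats::dhyper(x, c[1], c[2], r[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- One-sided two-sample KS p by exhaustive label enumeration ---------
# Alternative: x stochastically smaller than y (CDF of x above that of y).
oracle_ks_p <- function(x, y) {
  dplus <- function(a, b) {
    t <- sort(unique(c(a, b)))
    max(stats::ecdf(a)(t) - stats::ecdf(b)(t))
  }
  d_obs <- dplus(x, y)
  z <- c(x, y)
  picks <- utils::combn(length(z), length(x))
  ds <- apply(picks, 2, function(ix) dplus(z[ix], z[-ix]))
  mean(ds >= d_obs - 1e-12)
}

# --- naive unique-mapping expression counter ---------------------------
# Counts, per gene, the reads that occur as a perfect substring (either
# strand) of exactly that one gene among all genes.
oracle_unique_counts <- function(reads, genes) {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  vapply(seq_along(genes), function(gi) {
    sum(vapply(reads, function(r) {
      hit <- vapply(genes, function(g)
        grepl(r, g, fixed = TRUE) || grepl(rc(r), g, fixed = TRUE), TRUE)
      sum(hit) == 1 && hit[gi]
    }, TRUE))
  }, 0L)
}

# --- exhaustive terminal inverted repeat scan --------------------------
oracle_itr <- function(s, min_len = 5) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  n <- nchar(s)
  best <- 0L
  for (L in seq(min_len, n %/% 2))
    if (rc(substr(s, 1, L)) == substr(s, n - L + 1, n)) best <- L
  best
}
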