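# Nei-Gojobori (1986) pairwise synonymous/nonsynonymous divergence with
# Jukes-Cantor correction. Counting conventions: changes creating a stop
# codon count as nonsynonymous when counting sites (so S + N = 3 x codons
# exactly); evolutionary paths passing through a stop codon are excluded
# when averaging multi-difference codons.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

codon_aa <- function(codon) unname(GENETIC_CODE_TABLE[codon])

# Synonymous site count of one codon (sum over the 3 positions of the
# fraction of the 3 possible changes that preserve the amino acid).
codon_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in setdiff(BASES, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!mut %in% STOP_CODONS && codon_aa(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# Observed synonymous/nonsynonymous differences between two codons,
# averaged over all orderings of the single-base steps; orderings whose
# intermediate codons are stops are excluded (if every ordering is
# blocked, all are used).
codon_diff_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- all_permutations(pos)
  tally <- function(path, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && p != path[length(path)] && nxt %in% STOP_CODONS)
        return(NULL)
      if (nxt %in% STOP_CODONS || cur %in% STOP_CODONS) nd <- nd + 1
      else if (codon_aa(nxt) == codon_aa(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  if (p == 0) return(0)
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS between two aligned coding sequences (Nei-Gojobori 1986)
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (averaged
#' over the two sequences) and observed synonymous/nonsynonymous
#' differences (Sd, Nd), averaging multi-difference codons over all
#' orderings of single-base steps that avoid stop-codon intermediates.
#' Proportions pS = Sd/S and pN = Nd/N are Jukes-Cantor corrected to dS
#' and dN; a proportion at or above 3/4 is saturated and the corrected
#' rate is undefined (`NA` with the corresponding flag set).
#'
#' Inputs may contain alignment gaps (`-`); any codon with a gap in
#' either sequence is removed, and codons that are stop codons in either
#' sequence are skipped and counted in `n_skipped_codons`.
#'
#' @param cds_a,cds_b Aligned nucleotide sequences of equal length
#'   (divisible by 3 after gap removal).
#' @return Object of class `divergence_pair`: S, N, Sd, Nd, pS, pN, dS,
#'   dN, saturated_s, saturated_n, n_codons, n_skipped_codons.
#' @export
pairwise_dnds <- function(cds_a, cds_b) {
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned to equal length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  gap <- ca == "-" | cb == "-"
  # drop whole codons containing a gap in either sequence
  if (nchar(a) %% 3 != 0) stop("aligned length must be divisible by 3")
  codon_idx <- rep(seq_len(nchar(a) / 3), each = 3)
  bad <- unique(codon_idx[gap])
  keep <- !codon_idx %in% bad
  a <- paste(ca[keep], collapse = ""); b <- paste(cb[keep], collapse = "")
  if (!nchar(a)) stop("no ungapped codons to compare")
  cods_a <- split_codons(a); cods_b <- split_codons(b)
  skip <- cods_a %in% STOP_CODONS | cods_b %in% STOP_CODONS
  # a shared terminal stop is the normal CDS ending, not an internal stop
  n_skipped <- sum(skip[-length(skip)])
  cods_a <- cods_a[!skip]; cods_b <- cods_b[!skip]
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(cods_a)) {
    S <- S + (codon_syn_sites(cods_a[i]) + codon_syn_sites(cods_b[i])) / 2
    d <- codon_diff_counts(cods_a[i], cods_b[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  N <- 3 * length(cods_a) - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = jc_correct(pS), dN = jc_correct(pN),
                 saturated_s = pS >= 0.75, saturated_n = pN >= 0.75,
                 n_codons = length(cods_a), n_skipped_codons = n_skipped),
            class = "divergence_pair")
}

#' @export
print.divergence_pair <- function(x, ...) {
  cat(sprintf("NG86 divergence over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS=%.4f pN=%.4f dS=%s dN=%s%s\n", x$pS, x$pN,
              ifelse(is.na(x$dS), "saturated", sprintf("%.4f", x$dS)),
              ifelse(is.na(x$dN), "saturated", sprintf("%.4f", x$dN)),
              if (x$n_skipped_codons > 0)
                sprintf(" (%d stop codon(s) skipped)", x$n_skipped_codons)
              else ""))
  invisible(x)
}

#' All within-cluster pairwise divergence estimates
#'
#' @param cds Named character vector of (unaligned but equal-length or
#'   pre-aligned) coding sequences.
#' @param members Data frame (gene_id, cluster_id or family) restricting
#'   pairs to co-clustered genes; `NULL` compares all pairs.
#' @return Data frame with one row per pair and the `divergence_pair`
#'   fields as columns.
#' @export
pairwise_dnds_table <- function(cds, members = NULL) {
  ids <- names(cds)
  key <- if (!is.null(members)) {
    col <- if ("cluster_id" %in% names(members)) "cluster_id" else "family"
    stats::setNames(members[[col]], members$gene_id)[ids]
  } else rep("all", length(ids))
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    if (is.na(key[i]) || is.na(key[j]) || key[i] != key[j]) next
    dp <- pairwise_dnds(cds[[ids[j]]], cds[[ids[i]]])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids[j], gene_b = ids[i], S = dp$S, N = dp$N, Sd = dp$Sd,
      Nd = dp$Nd, pS = dp$pS, pN = dp$pN, dS = dp$dS, dN = dp$dN,
      saturated_s = dp$saturated_s, saturated_n = dp$saturated_n,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      S = numeric(0), N = numeric(0), Sd = numeric(0),
                      Nd = numeric(0), pS = numeric(0), pN = numeric(0),
                      dS = numeric(0), dN = numeric(0),
                      saturated_s = logical(0), saturated_n = logical(0)))
  do.call(rbind, rows)
}
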